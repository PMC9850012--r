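make_vcf <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  vcf <- file.path(dir, "toy.vcf")
  pop <- file.path(dir, "toy.pop")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("1", "100", "v1", "A", "T", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "./."), collapse = "\t"),
    paste(c("1", "200", "v2", "G", "C", ".", "PASS", ".", "GT",
            "0|1", "1|1", "0/.", "0/0"), collapse = "\t")), vcf)
  writeLines(paste(c("s1", "s2", "s3", "s4"),
                   c("N", "N", "S", "S"), sep = "\t"), pop)
  list(vcf = vcf, pop = pop, dir = dir)
}

test_that("VCF genotypes map to dosages with missing and half-calls handled", {
  fx <- make_vcf()
  g <- read_vcf(fx$vcf, fx$pop)
  expect_equal(unname(g$calls[, "v1"]), c(0L, 1L, 2L, NA))
  expect_equal(unname(g$calls[, "v2"]), c(1L, 2L, NA, 0L))  # phased + half-call
  expect_identical(g$samples, c("s1", "s2", "s3", "s4"))
  expect_identical(unname(g$populations), c("N", "N", "S", "S"))
})

test_that("a VCF with no variant records yields a zero-locus matrix", {
  fx <- make_vcf()
  lines <- readLines(fx$vcf)[1:3]
  empty <- file.path(fx$dir, "empty.vcf")
  writeLines(lines, empty)
  g <- read_vcf(empty, fx$pop)
  expect_equal(dim(g), c(4L, 0L))
  f <- filter_missingness(g)  # still filterable
  expect_equal(dim(f), c(4L, 0L))
})

test_that("multi-allelic records are rejected unless first_alt is requested", {
  fx <- make_vcf()
  lines <- readLines(fx$vcf)
  lines[5] <- gsub("\tC\t", "\tC,G\t", lines[5])
  lines[5] <- sub("1\\|1", "1/2", lines[5])
  multi <- file.path(fx$dir, "multi.vcf")
  writeLines(lines, multi)
  expect_error(read_vcf(multi, fx$pop), "multi-allelic")
  g <- read_vcf(multi, fx$pop, multiallelic = "first_alt")
  expect_equal(unname(g$calls[, "v2"]), c(1L, NA, NA, 0L))  # 1/2 -> missing
})

test_that("a sample missing from the population file is reported", {
  fx <- make_vcf()
  writeLines("s1\tN", fx$pop)
  expect_error(read_vcf(fx$vcf, fx$pop), "s2")
})

test_that("write -> read round-trips simulated genotypes exactly", {
  fr <- draw_cluster_frequencies(runif(80, 0.1, 0.9), 0.05, 3, seed = 21)
  g <- simulate_genotypes(fr, 15, missing_rate = 0.15, seed = 22)
  d <- tempfile(); dir.create(d)
  write_vcf(g, file.path(d, "g.vcf"), file.path(d, "g.pop"))
  g2 <- read_vcf(file.path(d, "g.vcf"), file.path(d, "g.pop"))
  expect_identical(g$calls, g2$calls)
  expect_identical(unname(g$populations), unname(g2$populations))
})

test_that("genotype-class filter matches the brute-force predicate and the printed rule", {
  ## (10, 7, 5) kept; (10, 7, 4) removed
  calls <- cbind(rep(c(0L, 1L, 2L), c(10, 7, 5)),
                 rep(c(0L, 1L, 2L), c(10, 8, 4)))
  loci <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "T")
  G <- genotype_matrix(calls, loci)
  out <- filter_genotype_class_count(G, 5)
  expect_equal(ncol(out$calls), 1L)
  expect_equal(out$loci$pos, 1L)

  ## monomorphic locus removed
  G2 <- genotype_matrix(matrix(0L, 20, 1),
                        data.frame(chrom = "1", pos = 1, ref = "A", alt = "T"))
  expect_equal(ncol(filter_genotype_class_count(G2)$calls), 0L)

  ## randomized MAF sweep vs brute force
  set.seed(31)
  p <- runif(300, 0.01, 0.99)
  calls <- sapply(p, function(q) rbinom(40, 2, q))
  calls[sample(length(calls), 400)] <- NA
  G3 <- genotype_matrix(calls, data.frame(chrom = "1", pos = 1:300,
                                          ref = "A", alt = "T"))
  out3 <- filter_genotype_class_count(G3, 5)
  expect_identical(out3$loci$pos, which(oracle_class_keep(calls, 5)))
  rep3 <- attr(out3, "report")
  expect_equal(rep3$n_loci_in - rep3$n_loci_removed, rep3$n_loci_out)
})

test_that("missingness filter removes samples first, strictly above threshold", {
  set.seed(41)
  calls <- matrix(rbinom(100 * 60, 2, 0.4), 100, 60)
  ## one sample at exactly 70% missing (kept), one at 71.7% (removed)
  calls[1, 1:42] <- NA
  calls[2, 1:43] <- NA
  calls[sample(which(row(calls) > 2), 900)] <- NA
  G <- genotype_matrix(calls, data.frame(chrom = "1", pos = 1:60,
                                         ref = "A", alt = "T"))
  out <- filter_missingness(G, 0.7, 0.7)
  expect_true(G$samples[1] %in% out$samples)   # exactly 0.70: kept
  expect_false(G$samples[2] %in% out$samples)  # 0.716...: removed
  oracle <- oracle_missing_filter(calls, 0.7, 0.7)
  expect_identical(out$samples, G$samples[oracle$samples])
  expect_identical(out$loci$pos, G$loci$pos[oracle$loci])

  ## complete matrix untouched; filters idempotent
  full <- genotype_matrix(matrix(1L, 10, 5),
                          data.frame(chrom = "1", pos = 1:5, ref = "A", alt = "T"))
  expect_identical(filter_missingness(full)$calls, full$calls)
  twice <- filter_missingness(out, 0.7, 0.7)
  expect_identical(twice$calls, out$calls)
})

test_that("genotype PCA separates fixed clusters and matches dense eigendecomposition", {
  ## two clusters fixed for alternate alleles at every locus
  calls <- rbind(matrix(0L, 10, 30), matrix(2L, 10, 30))
  G <- genotype_matrix(calls, data.frame(chrom = "1", pos = 1:30,
                                         ref = "A", alt = "T"),
                       populations = rep(c("A", "B"), each = 10))
  p <- pca_genotypes(G, 2)
  expect_gt(p$pve[1], 99.9)
  expect_equal(length(unique(sign(p$scores[, 1]))), 2L)
  expect_true(all(sign(p$scores[1:10, 1]) != sign(p$scores[11:20, 1])))

  ## constant locus changes nothing
  G2 <- genotype_matrix(cbind(calls, 1L),
                        data.frame(chrom = "1", pos = 1:31, ref = "A", alt = "T"))
  p2 <- pca_genotypes(G2, 2)
  expect_equal(abs(p2$scores), abs(p$scores), tolerance = 1e-8,
               ignore_attr = TRUE)

  ## eigenvalues equal eigen() of the covariance of the imputed centered matrix
  set.seed(51)
  fr <- draw_cluster_frequencies(runif(40, 0.2, 0.8), 0.05, 6, seed = 52)
  g <- simulate_genotypes(fr, 8, missing_rate = 0.1, seed = 53)
  pp <- pca_genotypes(g, 5)
  X <- g$calls; storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, colMeans(X))
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pp$sdev^2, ev[seq_along(pp$sdev)], tolerance = 1e-8)
  expect_lte(sum(pp$pve), 100 + 1e-8)

  ## scores invariant (up to sign) to sample permutation
  set.seed(54)
  perm <- sample(nrow(g$calls))
  gperm <- genotype_matrix(g$calls[perm, ], g$loci,
                           g$populations[perm])
  p3 <- pca_genotypes(gperm, 2)
  expect_equal(abs(p3$scores[order(perm), ]), abs(pp$scores[, 1:2]),
               tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(pca_genotypes(genotype_matrix(matrix(1L, 5, 4),
    data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "T"))), "zero variance")
})
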
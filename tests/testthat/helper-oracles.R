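## Independent oracles used across the suite. Each is a deliberately plain,
## loop-based transcription kept separate from the package's vectorized code.

## Weir & Cockerham (1984) theta for ONE locus and two population samples,
## written scalar-by-scalar from the component definitions.
oracle_wc_locus <- function(geno_a, geno_b) {
  geno_a <- geno_a[!is.na(geno_a)]
  geno_b <- geno_b[!is.na(geno_b)]
  n1 <- length(geno_a); n2 <- length(geno_b)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  r <- 2
  p1 <- sum(geno_a) / (2 * n1)
  p2 <- sum(geno_b) / (2 * n2)
  h1 <- sum(geno_a == 1) / n1
  h2 <- sum(geno_b == 1) / n2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) * (s2 - (1 / (n_bar - 1)) *
        (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) -
        ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

## Closed-form balanced one-way ANOVA variance-component estimators:
## k groups times n replicates, interior solution assumed (MSB > MSW).
oracle_oneway_anova <- function(y, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  n <- length(y) / k
  means <- tapply(y, group, mean)
  grand <- mean(y)
  msb <- n * sum((means - grand)^2) / (k - 1)
  msw <- sum((y - means[group])^2) / (k * (n - 1))
  c(sigma2_F = (msb - msw) / n, sigma2_resid = msw)
}

## Brute-force genotype-class filter predicate, per locus.
oracle_class_keep <- function(calls, min_per_class) {
  vapply(seq_len(ncol(calls)), function(j) {
    g <- calls[, j]
    all(sapply(0:2, function(v) sum(g == v, na.rm = TRUE) >= min_per_class))
  }, logical(1))
}

## Brute-force two-pass missingness filter (samples first, then loci).
oracle_missing_filter <- function(calls, max_s, max_l) {
  keep_s <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls)))
    if (mean(is.na(calls[i, ])) > max_s) keep_s[i] <- FALSE
  sub <- calls[keep_s, , drop = FALSE]
  keep_l <- rep(TRUE, ncol(sub))
  for (j in seq_len(ncol(sub)))
    if (mean(is.na(sub[, j])) > max_l) keep_l[j] <- FALSE
  list(samples = keep_s, loci = keep_l)
}

## Small helper: a fit-ready one-ring phenotype frame with known components.
make_vc_data <- function(n_cluster = 4, n_fam_per_cluster = 10, n_off = 6,
                         n_block = 5, sA = 0, sF = 0.2, sB = 0.05,
                         sE = 0.65, abh_sd = 1, seed = 1) {
  set.seed(seed)
  n_fam <- n_cluster * n_fam_per_cluster
  fam <- sprintf("F%03d", seq_len(n_fam))
  clu <- rep(sprintf("C%d", seq_len(n_cluster)), each = n_fam_per_cluster)
  d <- data.frame(family = rep(fam, each = n_off),
                  cluster = rep(clu, each = n_off),
                  site = "S1", ring = 1L, stringsAsFactors = FALSE)
  d$tree_id <- sprintf("T%05d", seq_len(nrow(d)))
  d$block <- sprintf("B%d", sample.int(n_block, nrow(d), replace = TRUE))
  d$abh <- rnorm(nrow(d), 0, abh_sd)
  g <- rnorm(n_cluster, 0, sqrt(sA))
  f <- rnorm(n_fam, 0, sqrt(sF))
  b <- rnorm(n_block, 0, sqrt(sB))
  e <- rnorm(nrow(d), 0, sqrt(sE))
  d$y <- g[match(d$cluster, unique(clu))] + f[match(d$family, fam)] +
    b[as.integer(sub("B", "", d$block))] + e
  ## realized variances of the drawn effect vectors: with few levels (6
  ## clusters, a handful of blocks) the fit estimates these, not the
  ## parametric values, so recovery is judged against them
  attr(d, "realized") <- c(sigma2_A = var(g), sigma2_F = var(f),
                           sigma2_B = var(b), sigma2_resid = var(e))
  d
}
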
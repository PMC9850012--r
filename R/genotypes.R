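#' Construct a genotype matrix
#'
#' The container for diploid biallelic genotype data: an integer matrix of
#' allele dosages (0, 1, 2 or `NA` for missing) with samples in rows and loci
#' in columns, a locus table, and a cluster (population) label per sample.
#'
#' @param calls Integer matrix, samples x loci, values in `{0, 1, 2, NA}`.
#' @param loci `data.frame` with one row per locus; columns `chrom`, `pos`,
#'   `ref`, `alt` (an `id` column is added if absent).
#' @param populations Named character vector or factor mapping sample ->
#'   cluster label; may be `NULL` for unlabelled data (FST and cluster PCA
#'   summaries then refuse to run).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, populations = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (nrow(loci) != ncol(calls))
    stop("locus table and call matrix disagree on the number of loci")
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%04d", seq_len(nrow(calls)))
  if (is.null(loci$id))
    loci$id <- paste(loci$chrom, loci$pos, sep = "_")
  colnames(calls) <- loci$id
  samples <- rownames(calls)
  if (!is.null(populations)) {
    populations <- stats::setNames(as.character(populations),
                                   names(populations) %||% samples)
    miss <- setdiff(samples, names(populations))
    if (length(miss))
      stop("samples without a population label: ",
           paste(utils::head(miss, 5), collapse = ", "))
    populations <- populations[samples]
  }
  structure(list(calls = calls, samples = samples, loci = loci,
                 populations = populations),
            class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci", nrow(x$calls), ncol(x$calls)))
  miss <- mean(is.na(x$calls))
  cat(sprintf(", %.1f%% missing", 100 * miss))
  if (!is.null(x$populations))
    cat(sprintf(", %d clusters", length(unique(x$populations))))
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read a VCF file and population file into a genotype matrix
#'
#' Parses a VCF (v4.2, via the vcfR package), converts GT calls to allele
#' dosages (`0/0` -> 0, `0/1` -> 1, `1/1` -> 2; `./.` and half-calls ->
#' missing), and attaches cluster labels from a two-column population file
#' (sample_id, cluster; tab-separated, no header required). Multi-allelic
#' records are rejected by default.
#'
#' @param path Path to the VCF file (plain or gzipped).
#' @param popfile Path to the population file, or `NULL` to skip labels.
#' @param multiallelic `"error"` (default) to reject records with more than one
#'   ALT allele, or `"first_alt"` to keep them counting only the first ALT
#'   allele (genotypes carrying other ALT alleles become missing).
#' @return A [genotype_matrix].
#' @export
read_vcf <- function(path, popfile = NULL, multiallelic = c("error", "first_alt")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)[-1] %||% character()
    calls <- matrix(NA_integer_, nrow = length(samples), ncol = 0,
                    dimnames = list(samples, NULL))
    loci <- data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       stringsAsFactors = FALSE)
    pops <- if (!is.null(popfile)) read_popfile(popfile, samples) else NULL
    return(genotype_matrix(calls, loci, pops))
  }
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " multi-allelic record(s) found (e.g. ",
           fix$CHROM[which(multi)[1]], ":", fix$POS[which(multi)[1]],
           "); use multiallelic = \"first_alt\" to keep them")
    fix$ALT <- sub(",.*", "", fix$ALT)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ## strip phasing, map allele pairs to dosage of the first ALT allele
  a1 <- substr(gsub("\\|", "/", gt), 1, 1)
  a2 <- substr(gsub("\\|", "/", gt), 3, 3)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[ok] <- (a1 == "1")[ok] + (a2 == "1")[ok]
  calls <- t(dos)  # vcfR is loci x samples
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                 paste(fix$CHROM, fix$POS, sep = "_"), fix$ID),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  pops <- if (!is.null(popfile)) read_popfile(popfile, rownames(calls)) else NULL
  genotype_matrix(calls, loci, pops)
}

read_popfile <- function(popfile, samples) {
  pop <- utils::read.table(popfile, header = FALSE, sep = "\t",
                           col.names = c("sample_id", "cluster"),
                           stringsAsFactors = FALSE)
  if (pop$sample_id[1] == "sample_id") pop <- pop[-1, ]  # tolerate a header
  missing <- setdiff(samples, pop$sample_id)
  if (length(missing))
    stop("samples in VCF absent from population file: ",
         paste(utils::head(missing, 10), collapse = ", "))
  stats::setNames(pop$cluster, pop$sample_id)[samples]
}

#' Write a genotype matrix as VCF v4.2 plus a population file
#'
#' Emits a minimal GT-only VCF v4.2 (`0/0`, `0/1`, `1/1`, `./.`) and, when
#' population labels are present, a two-column tab-separated population file.
#'
#' @param G A [genotype_matrix].
#' @param vcf_path Output VCF path.
#' @param pop_path Optional output path for the population file.
#' @return Invisibly, `vcf_path`.
#' @export
write_vcf <- function(G, vcf_path, pop_path = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", G$samples), collapse = "\t"))
  L <- ncol(G$calls)
  body <- character(L)
  if (L > 0) {
    gt <- matrix("./.", nrow = nrow(G$calls), ncol = L)
    obs <- !is.na(G$calls)
    gt[obs] <- gt_code[G$calls[obs] + 1L]
    for (j in seq_len(L)) {
      body[j] <- paste(c(G$loci$chrom[j], G$loci$pos[j], G$loci$id[j],
                         G$loci$ref[j], G$loci$alt[j], ".", "PASS", ".", "GT",
                         gt[, j]), collapse = "\t")
    }
  }
  writeLines(c(header, body), vcf_path)
  if (!is.null(pop_path)) {
    if (is.null(G$populations)) stop("no population labels to write")
    utils::write.table(data.frame(G$samples, G$populations),
                       pop_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(vcf_path)
}

new_filter_report <- function(step, n_samples_in, n_samples_out,
                              n_loci_in, n_loci_out, detail = list()) {
  structure(list(step = step,
                 n_samples_in = n_samples_in, n_samples_out = n_samples_out,
                 n_samples_removed = n_samples_in - n_samples_out,
                 n_loci_in = n_loci_in, n_loci_out = n_loci_out,
                 n_loci_removed = n_loci_in - n_loci_out,
                 detail = detail),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter '%s': samples %d -> %d, loci %d -> %d\n",
              x$step, x$n_samples_in, x$n_samples_out,
              x$n_loci_in, x$n_loci_out))
  invisible(x)
}

#' Filter SNPs by minimum genotype-class count
#'
#' Retains a locus only if each of the three genotype classes (0, 1 and 2
#' copies of the alternate allele) is carried by at least `min_per_class`
#' non-missing individuals. This guards mixed-model and FST estimates against
#' leverage from near-monomorphic loci, and doubles as a minor-allele filter:
#' monomorphic loci always fail.
#'
#' @param G A [genotype_matrix].
#' @param min_per_class Minimum carriers per genotype class (default 5).
#' @return The filtered [genotype_matrix], with a `filter_report` attached as
#'   attribute `"report"`.
#' @export
filter_genotype_class_count <- function(G, min_per_class = 5L) {
  stopifnot(inherits(G, "genotype_matrix"))
  n0 <- colSums(G$calls == 0L, na.rm = TRUE)
  n1 <- colSums(G$calls == 1L, na.rm = TRUE)
  n2 <- colSums(G$calls == 2L, na.rm = TRUE)
  keep <- n0 >= min_per_class & n1 >= min_per_class & n2 >= min_per_class
  out <- genotype_matrix(G$calls[, keep, drop = FALSE],
                         G$loci[keep, , drop = FALSE], G$populations)
  attr(out, "report") <- new_filter_report(
    "genotype_class_count", nrow(G$calls), nrow(out$calls),
    ncol(G$calls), ncol(out$calls),
    list(min_per_class = min_per_class))
  out
}

#' Filter samples and SNPs by missingness
#'
#' Two-pass call-rate filter: samples whose fraction of missing calls is
#' strictly greater than `max_sample_missing` are removed first, then loci
#' whose missing fraction (over the surviving samples) is strictly greater
#' than `max_locus_missing`. The order (individuals, then SNPs) is fixed and
#' recorded in the report.
#'
#' @param G A [genotype_matrix].
#' @param max_sample_missing,max_locus_missing Thresholds in `[0, 1]`
#'   (default 0.7 each); strictly greater fractions are removed.
#' @return The filtered [genotype_matrix] with attribute `"report"`.
#' @export
filter_missingness <- function(G, max_sample_missing = 0.7,
                               max_locus_missing = 0.7) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (max_sample_missing < 0 || max_sample_missing > 1 ||
      max_locus_missing < 0 || max_locus_missing > 1)
    stop("missingness thresholds must lie in [0, 1]")
  n_loci <- ncol(G$calls)
  samp_miss <- if (n_loci) rowMeans(is.na(G$calls)) else rep(0, nrow(G$calls))
  keep_s <- samp_miss <= max_sample_missing
  calls <- G$calls[keep_s, , drop = FALSE]
  loc_miss <- if (nrow(calls)) colMeans(is.na(calls)) else rep(0, n_loci)
  keep_l <- loc_miss <= max_locus_missing
  out <- genotype_matrix(calls[, keep_l, drop = FALSE],
                         G$loci[keep_l, , drop = FALSE],
                         if (is.null(G$populations)) NULL else G$populations[keep_s])
  attr(out, "report") <- new_filter_report(
    "missingness", nrow(G$calls), nrow(out$calls), n_loci, ncol(out$calls),
    list(order = c("samples", "loci"),
         max_sample_missing = max_sample_missing,
         max_locus_missing = max_locus_missing))
  out
}

#' Principal component analysis of genotypes
#'
#' Mean-imputes missing dosages per locus, centers each locus at its mean
#' (no variance scaling by default, the usual convention for genotype PCA so
#' that low-frequency loci are not inflated), and returns sample scores and
#' the percentage of variance explained per component.
#'
#' @param G A [genotype_matrix].
#' @param n_components Number of components to return.
#' @param scale Logical; also divide each locus by its standard deviation.
#' @return A list of class `genotype_pca`: `scores` (samples x components),
#'   `pve` (percent variance explained), `sdev`, and the sample populations.
#' @export
pca_genotypes <- function(G, n_components = 2L, scale = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$calls) < 2 || ncol(G$calls) < 2)
    stop("PCA needs at least 2 samples and 2 loci")
  X <- G$calls
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, mu)
  if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    X <- sweep(X, 2, s, "/")
  }
  total_var <- sum(X^2) / (nrow(X) - 1)
  if (total_var == 0) stop("genotype matrix has zero variance")
  n_components <- min(n_components, nrow(X) - 1, ncol(X))
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = n_components)
  pve <- 100 * pc$sdev^2 / total_var
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 pve = pve[seq_len(n_components)],
                 sdev = pc$sdev,
                 populations = G$populations),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("Genotype PCA:", nrow(x$scores), "samples\n")
  cat("  PVE (%):", paste(sprintf("%.2f", x$pve), collapse = ", "), "\n")
  invisible(x)
}
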
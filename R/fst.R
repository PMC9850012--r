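## Weir & Cockerham (1984) variance components for one pair of populations,
## vectorized over loci. Works from dosage counts: at each locus and population
## we need the sample size n_i, the alternate-allele frequency p_i, and the
## observed heterozygote frequency h_i.

wc_components_pair <- function(calls_a, calls_b) {
  n_a <- colSums(!is.na(calls_a)); n_b <- colSums(!is.na(calls_b))
  p_a <- colMeans(calls_a, na.rm = TRUE) / 2
  p_b <- colMeans(calls_b, na.rm = TRUE) / 2
  h_a <- colMeans(calls_a == 1L, na.rm = TRUE)
  h_b <- colMeans(calls_b == 1L, na.rm = TRUE)

  r <- 2
  nbar <- (n_a + n_b) / r
  pbar <- (n_a * p_a + n_b * p_b) / (r * nbar)
  s2 <- (n_a * (p_a - pbar)^2 + n_b * (p_b - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n_a * h_a + n_b * h_b) / (r * nbar)
  nc <- (r * nbar - (n_a^2 + n_b^2) / (r * nbar)) / (r - 1)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2

  evaluable <- n_a >= 2 & n_b >= 2
  a[!evaluable] <- NA_real_; b[!evaluable] <- NA_real_; c_[!evaluable] <- NA_real_
  list(a = a, b = b, c = c_, evaluable = evaluable)
}

#' Per-SNP Weir-Cockerham FST for one pair of populations
#'
#' Computes the Weir & Cockerham (1984) estimator theta = a / (a + b + c) at
#' each locus for two population samples, from allele dosages: `a` is the
#' among-population variance component, `b` the among-individuals-within-
#' population component, and `c` the within-individual component, all using
#' observed heterozygosity and sample-size weighting. Loci where `a + b + c`
#' is zero (e.g. both samples fixed for the same allele), or where either
#' population has fewer than two genotyped individuals, are returned as `NA`.
#' Negative estimates are possible and preserved.
#'
#' @param G A [genotype_matrix] with population labels.
#' @param popA,popB Cluster labels present in `G$populations`.
#' @return Numeric vector of per-locus FST (named by locus id), with the
#'   summed components attached as attributes `"a"`, `"b"`, `"c"` for
#'   ratio-of-sums summaries.
#' @export
wc_fst_pair <- function(G, popA, popB) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(G$populations)) stop("genotype matrix has no population labels")
  labs <- unique(G$populations)
  for (p in c(popA, popB))
    if (!p %in% labs) stop("unknown population label: ", p)
  rows_a <- which(G$populations == popA)
  rows_b <- which(G$populations == popB)
  calls_a <- G$calls[rows_a, , drop = FALSE]
  calls_b <- G$calls[rows_b, , drop = FALSE]
  cmp <- wc_components_pair(calls_a, calls_b)
  if (!any(cmp$evaluable))
    stop("populations '", popA, "' and '", popB,
         "' have no locus with >= 2 genotyped samples in each")
  denom <- cmp$a + cmp$b + cmp$c
  theta <- ifelse(!is.na(denom) & denom != 0, cmp$a / denom, NA_real_)
  names(theta) <- G$loci$id
  attr(theta, "a") <- cmp$a
  attr(theta, "b") <- cmp$b
  attr(theta, "c") <- cmp$c
  theta
}

#' Pairwise-averaged genome-wide FST distribution
#'
#' Computes per-SNP Weir-Cockerham FST for every pair of clusters and averages
#' each locus over the pairs where the estimate is defined, yielding the
#' empirical genome-wide distribution used as the neutral reference for QST.
#' The genome-wide mean is reported both as the mean of per-locus pair-averaged
#' values (mean of ratios) and as the ratio of summed variance components
#' averaged over pairs (ratio of sums).
#'
#' @param G A [genotype_matrix] with cluster labels.
#' @param clusters Optional subset of cluster labels to use (default: all).
#' @return An object of class `fst_dist`: list with `per_snp` (pair-averaged
#'   FST per locus, `NA` where undefined), `mean_fst` (mean of ratios),
#'   `mean_fst_ratio_of_sums` with its delta-method Monte-Carlo standard
#'   error `se_ratio_of_sums`, `positive_part` (sorted positive values),
#'   `q95`, `n_pairs_used` per locus, `loci`, and `n_clusters`.
#' @export
fst_distribution <- function(G, clusters = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(G$populations)) stop("genotype matrix has no population labels")
  labs <- sort(unique(as.character(G$populations)))
  if (!is.null(clusters)) {
    bad <- setdiff(clusters, labs)
    if (length(bad)) stop("unknown cluster label(s): ", paste(bad, collapse = ", "))
    labs <- sort(clusters)
  }
  if (length(labs) < 2) stop("need at least 2 clusters for FST")
  pairs <- utils::combn(labs, 2)
  L <- ncol(G$calls)
  sum_theta <- numeric(L); n_def <- integer(L)
  sum_a <- numeric(L); sum_bc <- numeric(L)
  for (j in seq_len(ncol(pairs))) {
    theta <- wc_fst_pair(G, pairs[1, j], pairs[2, j])
    ok <- !is.na(theta)
    sum_theta[ok] <- sum_theta[ok] + theta[ok]
    n_def <- n_def + ok
    a <- attr(theta, "a"); b <- attr(theta, "b"); c_ <- attr(theta, "c")
    okc <- !is.na(a)
    sum_a[okc] <- sum_a[okc] + a[okc]
    sum_bc[okc] <- sum_bc[okc] + b[okc] + c_[okc]
  }
  per_snp <- ifelse(n_def > 0, sum_theta / pmax(n_def, 1L), NA_real_)
  names(per_snp) <- G$loci$id
  if (all(is.na(per_snp))) stop("FST undefined at every locus")
  positive <- sort(per_snp[!is.na(per_snp) & per_snp > 0])
  def <- n_def > 0
  A <- sum_a[def]; D <- sum_a[def] + sum_bc[def]
  R <- sum(A) / sum(D)
  ## delta-method Monte-Carlo s.e. of the ratio of sums over loci
  se_R <- sqrt(sum((A - R * D)^2)) / sum(D)
  structure(list(per_snp = per_snp,
                 mean_fst = mean(per_snp, na.rm = TRUE),
                 mean_fst_ratio_of_sums = R,
                 se_ratio_of_sums = se_R,
                 mean_method = "mean_of_ratios",
                 positive_part = unname(positive),
                 q95 = if (length(positive))
                   unname(stats::quantile(positive, 0.95, type = 7)) else NA_real_,
                 n_pairs_used = n_def,
                 loci = G$loci,
                 n_clusters = length(labs)),
            class = "fst_dist")
}

#' Quantile of the positive part of an FST distribution
#'
#' Empirical quantile (type-7 linear interpolation) of the strictly positive
#' per-SNP FST values, the null reference against which QST is compared.
#'
#' @param dist An [fst_distribution()] result.
#' @param q Probability in `[0, 1]`.
#' @return The quantile value.
#' @export
fst_quantile <- function(dist, q) {
  stopifnot(inherits(dist, "fst_dist"))
  if (length(dist$positive_part) == 0)
    stop("positive part of the FST distribution is empty")
  unname(stats::quantile(dist$positive_part, q, type = 7))
}

#' @export
print.fst_dist <- function(x, ...) {
  cat(sprintf("Pairwise-averaged Weir-Cockerham FST over %d loci (%d clusters)\n",
              sum(!is.na(x$per_snp)), x$n_clusters))
  cat(sprintf("  mean FST: %.4f (mean of ratios), %.4f (ratio of sums)\n",
              x$mean_fst, x$mean_fst_ratio_of_sums))
  cat(sprintf("  positive part: %d loci, 95th percentile %.4f\n",
              length(x$positive_part), x$q95))
  invisible(x)
}
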
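#' Test a trait's QST against the empirical FST null
#'
#' The divergence decision layer: a trait's (ring-averaged) QST is compared
#' with the positive part of the genome-wide per-SNP FST distribution. The
#' empirical p-value is the fraction of positive FST values greater than or
#' equal to the QST (no continuity correction: the null is a genome-wide SNP
#' set, not a permutation sample), and the trait is called divergent when its
#' QST exceeds the 95th percentile of the positive part.
#'
#' @param qst QST value in `[0, 1]`.
#' @param dist An [fst_distribution()] result.
#' @param trait Optional trait name carried into the verdict.
#' @param include_nonpositive Use all defined per-SNP values instead of the
#'   positive part only (off by default).
#' @return An object of class `divergence_verdict`: one-row `data.frame` with
#'   columns `trait`, `qst`, `fst_q95`, `p_empirical`, `verdict`
#'   (`"divergent"` or `"not-distinguishable"`).
#' @export
qst_fst_test <- function(qst, dist, trait = NA_character_,
                         include_nonpositive = FALSE) {
  stopifnot(inherits(dist, "fst_dist"))
  if (is.na(qst) || qst < 0 || qst > 1)
    stop("'qst' must lie in [0, 1]")
  null_values <- if (include_nonpositive)
    dist$per_snp[!is.na(dist$per_snp)] else dist$positive_part
  if (!length(null_values)) stop("empty FST null distribution")
  q95 <- unname(stats::quantile(null_values, 0.95, type = 7))
  p_emp <- sum(null_values >= qst) / length(null_values)
  out <- data.frame(trait = trait, qst = qst, fst_q95 = q95,
                    p_empirical = p_emp,
                    verdict = if (qst > q95) "divergent" else "not-distinguishable",
                    stringsAsFactors = FALSE)
  class(out) <- c("divergence_verdict", "data.frame")
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / n_tests`; with the standard battery of 6 traits over 11 rings
#' (66 tests) at `alpha = 0.05` this is 7.6e-4.
#'
#' @param alpha Familywise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("'n_tests' must be >= 1")
  alpha / n_tests
}
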
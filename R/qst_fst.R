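#' Fit the QST-FST divergence analysis
#'
#' The package's central fitting function. Given a prepared long-format
#' phenotype table of half-sib progeny and the genotypes of the maternal
#' trees, it (i) fits the cluster-as-random mixed model (model 3) by REML for
#' every trait x cambial-ring combination, (ii) converts the cluster and
#' family variance components to QST per ring and averages across rings
#' (unweighted), (iii) builds the genome-wide pairwise-averaged
#' Weir-Cockerham FST distribution from the genotypes, and (iv) compares each
#' trait's mean QST with the positive part of that distribution: the
#' empirical p-value and the 95th-percentile divergence rule.
#'
#' @param phenotypes Long-format phenotype `data.frame` (columns `tree_id`,
#'   `family`, `cluster`, `site`, `block`, `abh`, `ring`, and the traits);
#'   typically already passed through [prepare_rings()], [filter_families()]
#'   and [normalize_traits()].
#' @param genotypes A [genotype_matrix] of the mothers with cluster labels,
#'   or a ready-made `fst_dist` object.
#' @param traits Trait columns to analyse.
#' @param rings Cambial rings to analyse (default: all present).
#' @param qst_method `"printed"` or `"spitze"`, see [qst()].
#' @param include_abh Also analyse ABH as a whole-tree trait.
#' @return An object of class `qst_fst`: list with `verdicts` (one row per
#'   trait: mean QST, FST q95, empirical p, verdict), `qst_per_ring`,
#'   `battery` (the model-3 [ring_battery()]), `fst` (the `fst_dist`), and
#'   the call. Methods: `print`, `summary`, `coef` (mean QST per trait),
#'   `plot` (FST histogram with QST markers).
#' @examples
#' cfg <- sim_config(n_snps = 300, families_per_cluster = 8,
#'                   offspring_per_family_per_site = 4, seed = 42)
#' sim <- simulate_study(cfg)
#' ph <- normalize_traits(sim$phenotypes)
#' fit <- qst_fst(ph, sim$genotypes, traits = c("dbh", "wd"), rings = 5:7)
#' print(fit)
#' @export
qst_fst <- function(phenotypes, genotypes,
                    traits = c("dbh", "rw", "wd", "trw", "ttw", "twt"),
                    rings = NULL, qst_method = c("printed", "spitze"),
                    include_abh = FALSE) {
  qst_method <- match.arg(qst_method)
  traits <- intersect(traits, names(phenotypes))
  if (!length(traits)) stop("no trait columns found in 'phenotypes'")

  fst <- if (inherits(genotypes, "fst_dist")) genotypes
         else fst_distribution(genotypes)

  battery <- ring_battery(phenotypes, model = 3L, traits = traits,
                          rings = rings, include_abh = include_abh)
  res <- battery$results
  res$qst <- vapply(seq_len(nrow(res)), function(i) {
    vc <- c(sigma2_A = res$sigma2_A[i], sigma2_F = res$sigma2_F[i])
    tryCatch(qst(vc, method = qst_method), error = function(e) NA_real_)
  }, numeric(1))

  all_traits <- c(traits, if (include_abh) "abh")
  verdicts <- list()
  qst_per_ring <- res[c("trait", "ring", "qst", "sigma2_A", "sigma2_F")]
  for (tr in all_traits) {
    qs <- res$qst[res$trait == tr]
    mean_qst <- mean(qs, na.rm = TRUE)
    if (!is.finite(mean_qst)) next
    v <- qst_fst_test(min(max(mean_qst, 0), 1), fst, trait = tr)
    v$mean_qst <- mean_qst
    v$n_rings <- sum(is.finite(qs))
    verdicts[[tr]] <- v
  }
  verdicts <- do.call(rbind, verdicts)
  rownames(verdicts) <- NULL

  structure(list(verdicts = verdicts, qst_per_ring = qst_per_ring,
                 battery = battery, fst = fst, qst_method = qst_method,
                 call = match.call()),
            class = "qst_fst")
}

#' @export
print.qst_fst <- function(x, ...) {
  cat("QST-FST divergence analysis\n")
  cat(sprintf("  FST null: %d positive loci, mean %.4f, q95 %.4f\n",
              length(x$fst$positive_part), x$fst$mean_fst, x$fst$q95))
  cat(sprintf("  QST (%s form), averaged over rings:\n", x$qst_method))
  v <- x$verdicts
  for (i in seq_len(nrow(v)))
    cat(sprintf("    %-5s QST = %.4f  p = %.4f  %s\n",
                v$trait[i], v$qst[i], v$p_empirical[i], v$verdict[i]))
  invisible(x)
}

#' @export
summary.qst_fst <- function(object, ...) {
  out <- list(verdicts = object$verdicts,
              n_divergent = sum(object$verdicts$verdict == "divergent"),
              fst_mean = object$fst$mean_fst,
              fst_q95 = object$fst$q95,
              n_fits = length(object$battery$fits),
              n_failed = length(object$battery$failed),
              n_singular = sum(object$battery$results$singular))
  class(out) <- "summary.qst_fst"
  out
}

#' @export
print.summary.qst_fst <- function(x, ...) {
  cat("QST-FST divergence analysis summary\n")
  cat(sprintf("  %d of %d traits divergent beyond the FST q95 (%.4f)\n",
              x$n_divergent, nrow(x$verdicts), x$fst_q95))
  cat(sprintf("  genome-wide mean FST %.4f\n", x$fst_mean))
  cat(sprintf("  %d model fits (%d singular, %d failed)\n",
              x$n_fits, x$n_singular, x$n_failed))
  print(x$verdicts, digits = 4)
  invisible(x)
}

#' @export
coef.qst_fst <- function(object, ...) {
  stats::setNames(object$verdicts$qst, object$verdicts$trait)
}

#' @export
plot.qst_fst <- function(x, ...) {
  graphics::hist(x$fst$positive_part, breaks = 50, freq = FALSE,
                 main = "Positive part of genome-wide FST",
                 xlab = "per-SNP pairwise-averaged FST",
                 xlim = c(0, max(c(x$fst$positive_part, x$verdicts$qst)) * 1.05),
                 col = "grey85", border = "grey60", ...)
  graphics::abline(v = x$fst$q95, lty = 2)
  cols <- grDevices::hcl.colors(nrow(x$verdicts), "Dark 3")
  for (i in seq_len(nrow(x$verdicts)))
    graphics::abline(v = x$verdicts$qst[i], col = cols[i], lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("FST q95",
                              sprintf("%s (QST %.3f)", x$verdicts$trait,
                                      x$verdicts$qst)),
                   col = c("black", cols), lty = c(2, rep(1, nrow(x$verdicts))),
                   lwd = c(1, rep(2, nrow(x$verdicts))))
  invisible(x)
}

#' Published variance components for seven Norway spruce wood traits
#'
#' Returns the model-1 variance components (family variance `sigma2_F` and
#' environmental variance `sigma2_B + sigma2` pooled) and the published
#' heritability estimates, in percent, for the seven traits of the Norway
#' spruce progeny-trial study this package's analysis reproduces: age at
#' breast height (ABH, years), diameter at breast height (DBH, mm), ring
#' width (RW, mm), wood density (WD, kg/m3), tracheid radial width (TRW,
#' um), tracheid tangential width (TTW, um) and tracheid wall thickness
#' (TWT, um). Ring traits are on the mean-normalized scale. Shipped as a
#' plain-text table in `inst/extdata/spruce_trial_components.tsv`.
#'
#' @return `data.frame` with columns `trait`, `sigma2_F`, `sigma2_env`
#'   (= `sigma2_B + sigma2_resid`), `h2_published_pct`.
#' @export
spruce_trial_components <- function() {
  path <- system.file("extdata", "spruce_trial_components.tsv",
                      package = "qstfst", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
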
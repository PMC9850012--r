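#' Restrict a phenotype table to usable cambial rings
#'
#' Applies the standard ring-selection rules for increment-core data: the
#' innermost rings are dropped (the strongly curved xylem near the pith cannot
#' be measured reliably), rings beyond `max_ring` are dropped (only
#' fast-growing offspring reach high cambial ages, which would bias
#' comparisons), and, when a formation-year column is present, rings formed
#' after `last_calendar_year` are dropped (to avoid post-thinning growth).
#'
#' @param raw Long-format phenotype `data.frame` with a `ring` column and
#'   optionally a `year` (ring formation year) column.
#' @param max_ring Highest cambial ring kept (default 13).
#' @param drop_innermost Number of innermost rings removed (default 2, i.e.
#'   rings 1 and 2).
#' @param last_calendar_year Optional cutoff year; rows with `year` greater
#'   than it are removed (requires a `year` column).
#' @return The filtered table, with a removal report in attribute `"report"`.
#' @export
prepare_rings <- function(raw, max_ring = 13L, drop_innermost = 2L,
                          last_calendar_year = NULL) {
  if (!"ring" %in% names(raw)) stop("no 'ring' column")
  n_in <- nrow(raw)
  keep <- raw$ring > drop_innermost & raw$ring <= max_ring
  n_inner <- sum(raw$ring <= drop_innermost)
  n_outer <- sum(raw$ring > max_ring)
  n_late <- 0L
  if (!is.null(last_calendar_year)) {
    if (!"year" %in% names(raw))
      stop("'last_calendar_year' given but no 'year' column present")
    late <- !is.na(raw$year) & raw$year > last_calendar_year
    n_late <- sum(late & keep)
    keep <- keep & !late
  }
  out <- raw[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no rings left after preparation")
  attr(out, "report") <- list(n_in = n_in, n_out = nrow(out),
                              removed_innermost = n_inner,
                              removed_beyond_max = n_outer,
                              removed_after_cutoff = n_late)
  attr(out, "normalized") <- isTRUE(attr(raw, "normalized"))
  out
}

#' Keep only adequately replicated half-sib families
#'
#' Removes families that do not have at least `min_offspring_per_site`
#' distinct offspring at every site where the trial was planted, which
#' protects the variance-component estimates from the imbalance caused by the
#' upstream filters. When a `stand` column is present, stands contributing
#' fewer than `min_families_per_stand` families are removed first.
#'
#' @param table Phenotype `data.frame` with `tree_id`, `family`, `site`
#'   columns (optionally `stand`).
#' @param min_offspring_per_site Minimum offspring per family per site
#'   (default 4).
#' @param min_families_per_stand Minimum families per stand (default 3; only
#'   used when a `stand` column exists).
#' @return The filtered table with a report attribute.
#' @export
filter_families <- function(table, min_offspring_per_site = 4L,
                            min_families_per_stand = 3L) {
  stopifnot(all(c("tree_id", "family", "site") %in% names(table)))
  n_fam_in <- length(unique(table$family))
  out <- table
  if ("stand" %in% names(out)) {
    fam_per_stand <- tapply(out$family, out$stand,
                            function(f) length(unique(f)))
    good_stands <- names(fam_per_stand)[fam_per_stand >= min_families_per_stand]
    out <- out[out$stand %in% good_stands, , drop = FALSE]
  }
  trees <- unique(out[c("tree_id", "family", "site")])
  counts <- table(trees$family, trees$site)
  sites <- colnames(counts)
  ok_fam <- rownames(counts)[apply(counts >= min_offspring_per_site, 1, all)]
  out <- out[out$family %in% ok_fam, , drop = FALSE]
  attr(out, "report") <- list(n_families_in = n_fam_in,
                              n_families_out = length(unique(out$family)),
                              n_trees_out = length(unique(out$tree_id)),
                              sites = sites,
                              min_offspring_per_site = min_offspring_per_site)
  attr(out, "normalized") <- isTRUE(attr(table, "normalized"))
  out
}

#' Normalize ring traits by their grand means
#'
#' Divides each trait by its overall mean across all retained trees and rings
#' so that traits of different units become comparable; after normalization
#' each trait has grand mean exactly 1. ABH is left on its raw scale (years).
#'
#' @param table Prepared phenotype `data.frame`.
#' @param traits Trait columns to normalize (default the six ring traits).
#' @return The normalized table (attribute `"normalized"` set to `TRUE`, and
#'   the grand means recorded in attribute `"grand_means"`).
#' @export
normalize_traits <- function(table,
                             traits = c("dbh", "rw", "wd", "trw", "ttw", "twt")) {
  traits <- intersect(traits, names(table))
  if (!length(traits)) stop("none of the trait columns are present")
  gm <- numeric(0)
  for (tr in traits) {
    m <- mean(table[[tr]], na.rm = TRUE)
    if (!is.finite(m) || m == 0)
      stop("grand mean of '", tr, "' is zero or undefined; cannot normalize")
    table[[tr]] <- table[[tr]] / m
    gm[tr] <- m
  }
  attr(table, "normalized") <- TRUE
  attr(table, "grand_means") <- gm
  table
}

#' Narrow-sense heritability from half-sib variance components
#'
#' Computes the intraclass-correlation estimate of narrow-sense heritability
#' for open-pollinated half-sib families,
#' `h2 = 4 sigma_F^2 / (sigma_F^2 + sigma_B^2 + sigma^2)`: with ideal
#' half-sibs the family variance is one quarter of the additive variance,
#' hence the factor 4. Values above 1 are possible (e.g. if relatives are
#' more related than half-sibs) and are flagged with a warning.
#'
#' @param vc A `ring_lmm` fit or a named numeric vector containing
#'   `sigma2_F`, `sigma2_B` and `sigma2_resid`.
#' @return Heritability as a fraction (not percent).
#' @export
heritability <- function(vc) {
  if (inherits(vc, "ring_lmm")) vc <- vc$vc
  need <- c("sigma2_F", "sigma2_B", "sigma2_resid")
  if (!all(need %in% names(vc)))
    stop("need components ", paste(need, collapse = ", "))
  if (any(vc[need] < 0)) stop("variance components must be >= 0")
  denom <- sum(vc[need])
  if (denom <= 0) stop("phenotypic variance is zero; heritability undefined")
  h2 <- unname(4 * vc[["sigma2_F"]] / denom)
  if (h2 > 1) warning(sprintf("heritability %.3f exceeds 1", h2))
  h2
}

#' QST from cluster and family variance components
#'
#' Computes the among-cluster differentiation of a trait from the model-3
#' variance components. The default (`method = "printed"`) is
#' `QST = sigma_A^2 / (sigma_A^2 + 2 sigma_F^2)`, the form used in the
#' analysis this package reproduces. `method = "spitze"` substitutes the
#' additive variance implied by ideal half-sib families
#' (`V_A = 4 sigma_F^2`), giving Spitze's definition
#' `QST = sigma_A^2 / (sigma_A^2 + 2 V_A) = sigma_A^2 / (sigma_A^2 + 8
#' sigma_F^2)`, which is the version whose neutral expectation equals FST.
#'
#' @param vc A model-3 `ring_lmm` fit or named numeric vector with `sigma2_A`
#'   and `sigma2_F`.
#' @param method `"printed"` (default) or `"spitze"`; see Details.
#' @return QST as a fraction in `[0, 1]`.
#' @export
qst <- function(vc, method = c("printed", "spitze")) {
  method <- match.arg(method)
  if (inherits(vc, "ring_lmm")) vc <- vc$vc
  if (!all(c("sigma2_A", "sigma2_F") %in% names(vc)))
    stop("need components sigma2_A and sigma2_F (a model-3 fit)")
  sA <- vc[["sigma2_A"]]; sF <- vc[["sigma2_F"]]
  if (is.na(sA) || is.na(sF) || sA < 0 || sF < 0)
    stop("variance components must be non-missing and >= 0")
  k <- if (method == "printed") 2 else 8
  denom <- sA + k * sF
  if (denom == 0) stop("sigma2_A and sigma2_F are both zero; QST undefined")
  unname(sA / denom)
}

#' Fit the per-ring model battery for all traits
#'
#' Fits the chosen mixed model separately for every trait x cambial-ring
#' combination (the per-ring analysis: six ring traits over rings 3-13 gives
#' 66 fits) and collects variance components, heritability or QST, and the
#' type-II Wald tests, with a Bonferroni threshold across the battery. ABH
#' can be included as an extra whole-tree response (`include_abh`), fitted
#' once on the tree-level data.
#'
#' @param table Prepared (and, for comparability, normalized) phenotype table.
#' @param model Mixed model id (1, 2 or 3), see [fit_ring_model()].
#' @param traits Trait columns to fit.
#' @param rings Cambial rings to fit (default: all rings present).
#' @param site_split Optional site label for model 2.
#' @param include_abh Also fit ABH (one record per tree) with the same model.
#' @param alpha Familywise error rate for the Bonferroni threshold.
#' @return An object of class `ring_battery`: `results` (one row per
#'   trait x ring: components, h2 or QST, Wald statistics for each fixed
#'   term), `fits` (list of `ring_lmm`), `failed` (character vector of failed
#'   trait x ring labels), `bonferroni` (threshold), `model`.
#' @export
ring_battery <- function(table, model = 1L,
                         traits = c("dbh", "rw", "wd", "trw", "ttw", "twt"),
                         rings = NULL, site_split = NULL,
                         include_abh = FALSE, alpha = 0.05) {
  traits <- intersect(traits, names(table))
  if (is.null(rings)) rings <- sort(unique(table$ring))
  combos <- expand.grid(trait = traits, ring = rings,
                        stringsAsFactors = FALSE)
  fits <- list(); rows <- list(); failed <- character()
  for (i in seq_len(nrow(combos))) {
    tr <- combos$trait[i]; rg <- combos$ring[i]
    key <- paste0(tr, ":ring", rg)
    d <- table[table$ring == rg, , drop = FALSE]
    f <- tryCatch(fit_ring_model(d, response = tr, model = model,
                                 site_split = site_split),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failed <- c(failed, key)
      next
    }
    fits[[key]] <- f
    rows[[key]] <- battery_row(f, tr, rg)
  }
  if (include_abh) {
    d <- table[!duplicated(table$tree_id), , drop = FALSE]
    f <- tryCatch(fit_ring_model(d, response = "abh",
                                 model = if (model == 3L) 3L else 1L),
                  error = function(e) e)
    if (inherits(f, "error")) failed <- c(failed, "abh") else {
      fits[["abh"]] <- f
      rows[["abh"]] <- battery_row(f, "abh", NA_integer_)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  n_tests <- nrow(combos)
  structure(list(results = results, fits = fits, failed = failed,
                 model = model, alpha = alpha, n_tests = n_tests,
                 bonferroni = bonferroni_threshold(alpha, n_tests)),
            class = "ring_battery")
}

battery_row <- function(f, trait, ring) {
  vc <- f$vc
  row <- data.frame(trait = trait, ring = ring,
                    sigma2_F = vc[["sigma2_F"]],
                    sigma2_B = vc[["sigma2_B"]],
                    sigma2_resid = vc[["sigma2_resid"]],
                    sigma2_A = if ("sigma2_A" %in% names(vc))
                      vc[["sigma2_A"]] else NA_real_,
                    singular = f$singular, converged = f$converged,
                    n_obs = f$n_obs, stringsAsFactors = FALSE)
  row$h2 <- tryCatch(suppressWarnings(heritability(vc)),
                     error = function(e) NA_real_)
  row$qst <- if (f$model == 3L)
    tryCatch(qst(vc), error = function(e) NA_real_) else NA_real_
  if (!is.null(f$wald)) {
    for (k in seq_len(nrow(f$wald))) {
      tm <- gsub("[^a-zA-Z0-9]", "_", f$wald$term[k])
      row[[paste0("chisq_", tm)]] <- f$wald$chisq[k]
      row[[paste0("df_", tm)]] <- f$wald$df[k]
      row[[paste0("p_", tm)]] <- f$wald$p[k]
    }
  }
  row
}

#' @export
print.ring_battery <- function(x, ...) {
  cat(sprintf("Per-ring mixed-model battery (model %d): %d fits, %d failed\n",
              x$model, length(x$fits), length(x$failed)))
  cat(sprintf("  Bonferroni threshold: alpha %.3g / %d tests = %.3g\n",
              x$alpha, x$n_tests, x$bonferroni))
  invisible(x)
}

#' Trend of a per-ring statistic over cambial age
#'
#' Ordinary least-squares regression of a per-ring statistic (a Wald
#' chi-square, a coefficient, a coefficient of variation, ...) on ring
#' number, with the two-sided Student's t-test of the slope. Used to ask
#' whether, e.g., the cluster effect strengthens as trees age.
#'
#' @param stat Numeric vector of the statistic, one value per ring.
#' @param ring Integer vector of cambial ages (same length).
#' @return A list with `slope`, `t`, `p`, `df`; for a constant series, `t`
#'   and `p` are `NA` with a note.
#' @export
trend_test <- function(stat, ring) {
  ok <- is.finite(stat) & is.finite(ring)
  stat <- stat[ok]; ring <- ring[ok]
  if (length(stat) < 3) stop("need at least 3 cambial ages")
  if (stats::sd(stat) == 0)
    return(list(slope = 0, t = NA_real_, p = NA_real_,
                df = length(stat) - 2L, note = "constant series"))
  fit <- stats::lm(stat ~ ring)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["ring", "Estimate"]),
       t = unname(sm["ring", "t value"]),
       p = unname(sm["ring", "Pr(>|t|)"]),
       df = fit$df.residual)
}

#' Coefficient of variation of a trait per ring
#'
#' `sd / mean` of the trait across trees, at each cambial ring; the input for
#' trend tests of dispersion over ontogeny.
#'
#' @param table Phenotype table.
#' @param trait Trait column name.
#' @return `data.frame` with columns `ring` and `cv`.
#' @export
cv_per_ring <- function(table, trait) {
  rings <- sort(unique(table$ring))
  cv <- vapply(rings, function(r) {
    v <- table[[trait]][table$ring == r]
    stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(ring = rings, cv = cv)
}

#' PCA of predicted family effects (or residuals) across traits
#'
#' Builds the family x trait matrix of best linear unbiased predictions
#' (BLUPs) of the family random effect from a battery of fits, averaging each
#' trait's BLUPs across rings, and runs a PCA on it. The latitudinal ordering
#' of cluster centroids along PC1 is the hallmark of population structure in
#' the phenotypes. Residual mode (`what = "residuals"`) instead averages
#' model residuals per family.
#'
#' @param battery A `ring_battery` (or a list of `ring_lmm` fits).
#' @param what `"family_blup"` (default) or `"residuals"`.
#' @param cluster_map Optional named vector family -> cluster, used to attach
#'   cluster labels and centroids to the result.
#' @return A list of class `family_pca`: `scores` (family x PC), `pve`,
#'   `matrix` (the family x trait input), optionally `clusters` and
#'   `centroids`.
#' @export
family_effect_pca <- function(battery, what = c("family_blup", "residuals"),
                              cluster_map = NULL) {
  what <- match.arg(what)
  fits <- if (inherits(battery, "ring_battery")) battery$fits else battery
  if (!length(fits)) stop("no fits supplied")
  traits <- unique(vapply(fits, function(f) f$response, ""))
  cols <- list()
  for (tr in traits) {
    fs <- Filter(function(f) f$response == tr, fits)
    per_fit <- lapply(fs, function(f) {
      if (what == "family_blup") {
        re <- lme4::ranef(f$fit)$family
        stats::setNames(re[[1]], rownames(re))
      } else {
        r <- stats::residuals(f$fit)
        fam <- f$fit@frame$family
        tapply(r, fam, mean)
      }
    })
    fams <- sort(unique(unlist(lapply(per_fit, names))))
    m <- vapply(per_fit, function(v) v[fams], numeric(length(fams)))
    cols[[tr]] <- rowMeans(matrix(m, nrow = length(fams),
                                  dimnames = list(fams, NULL)), na.rm = TRUE)
  }
  fams <- sort(unique(unlist(lapply(cols, names))))
  M <- vapply(cols, function(v) v[fams], numeric(length(fams)))
  rownames(M) <- fams
  if (nrow(M) < length(traits))
    warning("fewer families than traits; PCA is rank-deficient")
  if (all(abs(M) < .Machine$double.eps))
    stop("all family effects are zero; PCA degenerate")
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  pve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  out <- list(scores = pc$x, pve = pve, matrix = M, rotation = pc$rotation)
  if (!is.null(cluster_map)) {
    cl <- cluster_map[rownames(M)]
    out$clusters <- cl
    out$centroids <- do.call(rbind, lapply(split(as.data.frame(pc$x), cl),
                                           colMeans))
  }
  class(out) <- "family_pca"
  out
}

#' @export
print.family_pca <- function(x, ...) {
  cat(sprintf("Family-effect PCA: %d families x %d traits\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  PVE (%):", paste(sprintf("%.1f", utils::head(x$pve, 4)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Label-shuffling test of within-group trait variance
#'
#' Tests whether trees within a family (or genetic cluster) resemble each
#' other more than random groups of trees: the statistic is the mean
#' within-group variance of the trait (groups with fewer than two members
#' excluded), and the null distribution is built by permuting group labels
#' across trees. The one-sided p-value is the fraction of permutations whose
#' statistic is less than or equal to the observed one (with the +1
#' correction), i.e. small p means the real grouping has *smaller* internal
#' variance than shuffled groupings.
#'
#' @param table Phenotype table (one row per tree, or tree x ring rows --
#'   values are averaged per tree first).
#' @param trait Trait column.
#' @param level `"family"` or `"cluster"`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @return List with `observed`, `perm` (null statistics), `p`.
#' @export
shuffle_variance_test <- function(table, trait, level = c("family", "cluster"),
                                  n_perm = 199L, seed = NULL) {
  level <- match.arg(level)
  if (n_perm < 100) stop("'n_perm' must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  per_tree <- tapply(table[[trait]], table$tree_id, mean, na.rm = TRUE)
  grp_map <- table[[level]][match(names(per_tree), table$tree_id)]
  ok <- is.finite(per_tree)
  y <- per_tree[ok]; g <- as.character(grp_map[ok])

  stat <- function(y, g) {
    v <- tapply(y, g, function(z) if (length(z) >= 2) stats::var(z) else NA_real_)
    mean(v, na.rm = TRUE)
  }
  obs <- stat(y, g)
  perm <- vapply(seq_len(n_perm), function(i) stat(y, sample(g)), numeric(1))
  p <- (1 + sum(perm <= obs)) / (n_perm + 1)
  list(observed = obs, perm = perm, p = p, level = level, n_perm = n_perm)
}
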
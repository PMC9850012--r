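#' Fit one of the three common-garden mixed models by REML
#'
#' Fits, for a single trait at a single cambial ring, one of the three
#' Gaussian mixed models used throughout the analysis (restricted maximum
#' likelihood, via lme4):
#'
#' * **Model 1** (`model = 1`): `y = mu + site + (1 | site:block) + (1 | family)`.
#'   The family variance from this model feeds the half-sib heritability.
#' * **Model 2** (`model = 2`): adds fixed ABH, genetic cluster, and the
#'   ABH x cluster and ABH x site interactions to model 1. With
#'   `site_split` set to a site label, the data are restricted to that site
#'   and all site terms drop (the recommended analysis when the ABH x site
#'   interaction is significant).
#' * **Model 3** (`model = 3`): `y = mu + abh + (1 | cluster) + (1 | site:block)
#'   + (1 | family)`; the cluster is a *random* effect whose variance
#'   (sigma_A^2), together with the family variance (sigma_F^2), yields QST.
#'
#' Rows with a missing response or missing ABH are dropped (listwise, per
#' fit). Blocks are always nested in sites via a composite `site:block`
#' factor. Variance components are returned on the response scale; singular
#' fits (a component estimated at the zero boundary) and non-convergence are
#' flagged, not hidden.
#'
#' @param data A phenotype `data.frame` with columns `family`, `cluster`,
#'   `site`, `block`, `abh`, and the response; typically one ring of a
#'   prepared [simulate_phenotypes()]-style table.
#' @param response Name of the trait column to model.
#' @param model Integer 1, 2 or 3.
#' @param site_split Optional site label: fit model 2 within that site only.
#' @return An object of class `ring_lmm`: list with `model`, `response`,
#'   `vc` (named vector `sigma2_F`, `sigma2_B`, `sigma2_resid` and, for model
#'   3, `sigma2_A`), `fixed` (coefficient table), `vcov_fixed`,
#'   `reml_loglik`, `n_obs`, `n_groups`, `singular`, `converged`, `wald`
#'   (type-II Wald chi-square table), and the underlying `lme4` fit as `fit`.
#' @export
fit_ring_model <- function(data, response, model = 1L, site_split = NULL) {
  stopifnot(response %in% names(data))
  model <- as.integer(model)
  if (!model %in% 1:3) stop("'model' must be 1, 2 or 3")
  d <- data
  if (!is.null(site_split)) {
    if (model != 2L) stop("'site_split' applies to model 2 only")
    d <- d[d$site == site_split, , drop = FALSE]
    if (nrow(d) == 0) stop("no rows for site '", site_split, "'")
  }
  d$y <- d[[response]]
  needed <- c("y", if (model >= 2L) "abh")
  keep <- stats::complete.cases(d[, needed, drop = FALSE])
  d <- d[keep, , drop = FALSE]
  for (col in c("family", "cluster", "site", "block"))
    if (col %in% names(d)) d[[col]] <- factor(d[[col]])
  d$site_block <- interaction(d$site, d$block, drop = TRUE)
  one_site <- nlevels(d$site) < 2

  fixed <- switch(model,
    `1` = if (one_site) "y ~ 1" else "y ~ site",
    `2` = if (!is.null(site_split) || one_site)
            "y ~ abh + cluster + abh:cluster"
          else "y ~ abh + cluster + site + abh:cluster + abh:site",
    `3` = "y ~ abh")
  if (model == 2L && stats::var(d$abh) == 0)
    stop("ABH is constant; model 2 is not identifiable")
  if (model == 3L && stats::var(d$abh) == 0)  # ABH carries no information
    fixed <- "y ~ 1"
  random <- c(if (model == 3L) "(1 | cluster)", "(1 | site_block)", "(1 | family)")
  ## a random factor needs >= 2 sampled levels; a single block is treated as
  ## part of the intercept (its variance is inestimable and set to 0)
  dropped <- character()
  if (nlevels(d$site_block) < 2) {
    random <- setdiff(random, "(1 | site_block)")
    dropped <- c(dropped, "site_block")
  }
  if (nlevels(d$family) < 2) stop("need at least 2 families")
  if (model == 3L && nlevels(d$cluster) < 2)
    stop("need at least 2 clusters for the cluster variance component")
  form <- stats::as.formula(paste(fixed, "+", paste(random, collapse = " + ")))

  converged <- TRUE
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })

  vc_tab <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) {
    i <- match(g, vc_tab$grp)
    if (is.na(i)) NA_real_ else vc_tab$vcov[i]
  }
  vc <- c(sigma2_F = get_vc("family"),
          sigma2_B = if ("site_block" %in% dropped) 0 else get_vc("site_block"),
          sigma2_resid = get_vc("Residual"))
  if (model == 3L) vc <- c(vc, sigma2_A = get_vc("cluster"))
  if (length(dropped))
    msgs <- c(msgs, paste("random term(s) dropped (single level):",
                          paste(dropped, collapse = ", ")))

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  fixed_tab <- data.frame(term = names(beta), estimate = unname(beta),
                          se = sqrt(diag(V)), stringsAsFactors = FALSE)

  out <- structure(list(model = model, response = response,
                        site_split = site_split,
                        vc = vc,
                        fixed = fixed_tab, vcov_fixed = V,
                        reml_loglik = as.numeric(stats::logLik(fit)),
                        n_obs = nrow(d),
                        n_groups = vapply(lme4::ngrps(fit), as.integer, 1L),
                        singular = lme4::isSingular(fit),
                        converged = converged,
                        messages = msgs,
                        fit = fit),
                   class = "ring_lmm")
  out$wald <- tryCatch(wald_type2(out), error = function(e) NULL)
  out
}

#' Type-II Wald chi-square tests of the fixed effects
#'
#' For each fixed term, tests its coefficients against zero with a Wald
#' chi-square statistic respecting type-II marginality (each term tested
#' after every other term except the higher-order relatives that contain
#' it), using the REML fixed-effect covariance. Computed with `car::Anova`.
#'
#' @param fit A `ring_lmm` object from [fit_ring_model()], or an `lmerMod`.
#' @return `data.frame` with columns `term`, `chisq`, `df`, `p`.
#' @export
wald_type2 <- function(fit) {
  mod <- if (inherits(fit, "ring_lmm")) fit$fit else fit
  a <- car::Anova(mod, type = "II", test.statistic = "Chisq")
  data.frame(term = rownames(a),
             chisq = a[["Chisq"]],
             df = a[["Df"]],
             p = a[["Pr(>Chisq)"]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.ring_lmm <- function(x, ...) {
  cat(sprintf("Common-garden mixed model %d for '%s' (REML), %d obs\n",
              x$model, x$response, x$n_obs))
  vc <- x$vc
  cat("  variance components:\n")
  for (nm in names(vc))
    cat(sprintf("    %-12s %.5g\n", nm, vc[[nm]]))
  if (x$singular) cat("  note: singular fit (a component at the zero boundary)\n")
  if (!x$converged) cat("  warning: convergence not confirmed\n")
  if (!is.null(x$wald)) {
    cat("  type-II Wald tests:\n")
    print(x$wald, digits = 4)
  }
  invisible(x)
}
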
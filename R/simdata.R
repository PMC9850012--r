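#' Configuration for a synthetic half-sib progeny trial
#'
#' Bundles every parameter of the synthetic-data generator: the population
#' structure (number of genetic clusters and their Balding-Nichols divergence),
#' the trial design (families, offspring per family per site, sites, randomized
#' incomplete blocks), the marker panel, and the variance components of the
#' trait model. Defaults emulate a Norway spruce progeny-trial design: six
#' genetic clusters, two sites with 20 and 23 blocks, six offspring per family
#' per site, cambial rings 3 to 13, cluster trait means ordered by latitude,
#' and variance components on the mean-normalized trait scale.
#'
#' @param n_clusters Number of genetic clusters (populations).
#' @param families_per_cluster Half-sib families sampled per cluster (>= 3).
#' @param offspring_per_family_per_site Offspring planted per family at each site.
#' @param n_sites Number of trial sites.
#' @param blocks_per_site Integer vector (recycled to `n_sites`) of block counts.
#' @param n_snps Number of biallelic SNPs to simulate for the mothers.
#' @param ancestral_freq Length-2 numeric: uniform bounds for ancestral allele
#'   frequencies, strictly inside (0, 1).
#' @param fst_target Balding-Nichols divergence parameter F in `[0, 1)`; the
#'   expected genome-wide FST among clusters.
#' @param var_cluster Among-cluster trait variance (sigma_A^2).
#' @param var_family Among-family trait variance (sigma_F^2); for ideal
#'   half-sibs this is one quarter of the additive genetic variance.
#' @param var_block Among-block-within-site variance (sigma_B^2).
#' @param var_resid Residual variance (sigma^2).
#' @param grand_mean Grand mean of the ring traits (1 on the normalized scale).
#' @param cluster_means Per-cluster relative trait offsets, ordered by
#'   decreasing latitude (cluster 1 = northernmost). Default is a linear
#'   latitudinal gradient of +/- 10 percent.
#' @param ring_range Length-2 integer vector, first and last cambial ring kept.
#' @param ontogeny_slopes Named per-trait linear trend (relative change of the
#'   mean per ring of cambial age).
#' @param abh_mean,abh_var_family,abh_var_block,abh_var_resid Mean and variance
#'   components of age at breast height (ABH, years), generated once per tree.
#' @param missing_rate_geno Fraction of genotype calls set to missing.
#' @param seed Integer seed driving the whole simulation.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_study()]
#' @export
sim_config <- function(n_clusters = 6L,
                       families_per_cluster = 20L,
                       offspring_per_family_per_site = 6L,
                       n_sites = 2L,
                       blocks_per_site = c(20L, 23L),
                       n_snps = 2000L,
                       ancestral_freq = c(0.05, 0.95),
                       fst_target = 0.05,
                       var_cluster = 0.02,
                       var_family = 0.03,
                       var_block = 0.05,
                       var_resid = 0.165,
                       grand_mean = 1,
                       cluster_means = NULL,
                       ring_range = c(3L, 13L),
                       ontogeny_slopes = c(dbh = 0.15, rw = 0.02, wd = 0.01,
                                           trw = 0.02, ttw = 0.01, twt = 0.02),
                       abh_mean = 5,
                       abh_var_family = 0.0744,
                       abh_var_block = 0.2,
                       abh_var_resid = 1.45,
                       missing_rate_geno = 0.1,
                       seed = 1L) {
  if (is.null(cluster_means))
    cluster_means <- seq(-0.1, 0.1, length.out = n_clusters)
  cfg <- list(n_clusters = as.integer(n_clusters),
              families_per_cluster = as.integer(families_per_cluster),
              offspring_per_family_per_site = as.integer(offspring_per_family_per_site),
              n_sites = as.integer(n_sites),
              blocks_per_site = rep_len(as.integer(blocks_per_site), n_sites),
              n_snps = as.integer(n_snps),
              ancestral_freq = as.numeric(ancestral_freq),
              fst_target = fst_target,
              var_cluster = var_cluster, var_family = var_family,
              var_block = var_block, var_resid = var_resid,
              grand_mean = grand_mean,
              cluster_means = as.numeric(cluster_means),
              ring_range = as.integer(ring_range),
              ontogeny_slopes = ontogeny_slopes,
              abh_mean = abh_mean, abh_var_family = abh_var_family,
              abh_var_block = abh_var_block, abh_var_resid = abh_var_resid,
              missing_rate_geno = missing_rate_geno,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  vars <- c("var_cluster", "var_family", "var_block", "var_resid",
            "abh_var_family", "abh_var_block", "abh_var_resid")
  for (v in vars)
    if (cfg[[v]] < 0) stop("variance component '", v, "' must be >= 0")
  if (cfg$fst_target < 0 || cfg$fst_target >= 1)
    stop("'fst_target' must lie in [0, 1)")
  if (cfg$families_per_cluster < 3L)
    stop("'families_per_cluster' must be >= 3 (stands with fewer half-sib families are excluded from this design)")
  if (cfg$ring_range[1] < 1L || cfg$ring_range[2] > 13L ||
      cfg$ring_range[1] > cfg$ring_range[2])
    stop("'ring_range' must be a non-empty range within [1, 13]")
  if (any(cfg$ancestral_freq <= 0) || any(cfg$ancestral_freq >= 1))
    stop("'ancestral_freq' bounds must lie strictly inside (0, 1)")
  if (cfg$missing_rate_geno < 0 || cfg$missing_rate_geno >= 1)
    stop("'missing_rate_geno' must lie in [0, 1)")
  if (length(cfg$cluster_means) != cfg$n_clusters)
    stop("'cluster_means' must have one entry per cluster")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic half-sib trial configuration\n")
  cat(sprintf("  %d clusters x %d families x %d offspring/site, %d site(s)\n",
              x$n_clusters, x$families_per_cluster,
              x$offspring_per_family_per_site, x$n_sites))
  cat(sprintf("  %d SNPs, Balding-Nichols F = %.3g, genotype missingness %.2g\n",
              x$n_snps, x$fst_target, x$missing_rate_geno))
  cat(sprintf("  variances: cluster %.3g, family %.3g, block %.3g, residual %.3g\n",
              x$var_cluster, x$var_family, x$var_block, x$var_resid))
  cat(sprintf("  rings %d..%d, seed %d\n", x$ring_range[1], x$ring_range[2], x$seed))
  invisible(x)
}

#' Draw per-cluster allele frequencies under the Balding-Nichols model
#'
#' Each cluster's frequency at a locus is drawn independently from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`, so that
#' the expected among-cluster variance is `F p (1-p)`. With `fst_target = 0`
#' the Beta degenerates and every cluster inherits the ancestral frequency.
#' Boundary values 0 and 1 (fixation) are allowed in the output.
#'
#' @param p_anc Numeric vector of ancestral allele frequencies, all in (0, 1).
#' @param fst_target Divergence parameter F in `[0, 1)`.
#' @param n_clusters Number of clusters to draw.
#' @param seed Optional integer seed.
#' @return A `n_clusters x length(p_anc)` matrix of allele frequencies.
#' @export
draw_cluster_frequencies <- function(p_anc, fst_target, n_clusters, seed = NULL) {
  if (any(p_anc <= 0) || any(p_anc >= 1))
    stop("ancestral frequencies must lie strictly in (0, 1)")
  if (fst_target < 0 || fst_target >= 1)
    stop("'fst_target' must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  L <- length(p_anc)
  if (fst_target == 0)
    return(matrix(p_anc, nrow = n_clusters, ncol = L, byrow = TRUE))
  k <- (1 - fst_target) / fst_target
  freqs <- matrix(stats::rbeta(n_clusters * L,
                               shape1 = rep(p_anc * k, each = n_clusters),
                               shape2 = rep((1 - p_anc) * k, each = n_clusters)),
                  nrow = n_clusters, ncol = L)
  freqs
}

#' Simulate maternal genotypes from cluster allele frequencies
#'
#' Mothers are drawn in Hardy-Weinberg proportions within their cluster:
#' the allele dosage at each locus is `Binomial(2, p)` with the cluster's
#' frequency. Missing calls are then injected independently at `missing_rate`.
#'
#' @param freqs Cluster-by-locus matrix of allele frequencies, as returned by
#'   [draw_cluster_frequencies()].
#' @param mothers_per_cluster Number of mothers to draw per cluster.
#' @param missing_rate Fraction of calls set to missing, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param cluster_names Optional cluster labels (default "C1", "C2", ...).
#' @return A [genotype_matrix] with population labels attached.
#' @export
simulate_genotypes <- function(freqs, mothers_per_cluster, missing_rate = 0,
                               seed = NULL, cluster_names = NULL) {
  if (any(freqs < 0 | freqs > 1)) stop("allele frequencies must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(freqs); L <- ncol(freqs)
  if (is.null(cluster_names)) cluster_names <- paste0("C", seq_len(K))
  n <- K * mothers_per_cluster
  calls <- matrix(NA_integer_, nrow = n, ncol = L)
  pops <- character(n)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * mothers_per_cluster + seq_len(mothers_per_cluster)
    calls[rows, ] <- stats::rbinom(mothers_per_cluster * L, 2L,
                                   rep(freqs[k, ], each = mothers_per_cluster))
    pops[rows] <- cluster_names[k]
  }
  if (missing_rate > 0)
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  samples <- sprintf("M%04d", seq_len(n))
  rownames(calls) <- samples
  loci <- data.frame(chrom = "1", pos = seq_len(L),
                     id = sprintf("snp%05d", seq_len(L)),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(calls, loci, stats::setNames(pops, samples))
}

## Internal: design skeleton (one row per offspring) for a sim_config
sim_design <- function(cfg) {
  K <- cfg$n_clusters; Fam <- cfg$families_per_cluster
  n_fam <- K * Fam
  family <- sprintf("F%04d", seq_len(n_fam))
  fam_cluster <- rep(paste0("C", seq_len(K)), each = Fam)
  rows <- list()
  for (s in seq_len(cfg$n_sites)) {
    site <- paste0("S", s)
    off <- cfg$offspring_per_family_per_site
    d <- data.frame(
      family = rep(family, each = off),
      cluster = rep(fam_cluster, each = off),
      site = site,
      stringsAsFactors = FALSE)
    d$block <- paste0("B", sample.int(cfg$blocks_per_site[s], nrow(d), replace = TRUE))
    rows[[s]] <- d
  }
  d <- do.call(rbind, rows)
  d$tree_id <- sprintf("T%05d", seq_len(nrow(d)))
  d[c("tree_id", "family", "cluster", "site", "block")]
}

#' Simulate ring-level phenotypes from the variance-component trait model
#'
#' Generates the long-format phenotype table of a half-sib progeny trial from
#' the additive variance-component model underlying the common-garden mixed
#' models: for each tree, ring and trait,
#' `Y = mu * (1 + cluster offset + ontogeny) + G + B + F + e`, where `G`, `B`
#' and `F` are cluster, block-within-site and family random effects (drawn once
#' per trait and shared across rings) and `e` is a per-observation Gaussian
#' residual. Family effects are shared by a family's offspring at both sites.
#' ABH (age at breast height, years) is generated once per tree from its own
#' family/block/residual components.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return A long-format `data.frame` (one row per tree x ring) with columns
#'   `tree_id, family, cluster, site, block, abh, ring, dbh, rw, wd, trw, ttw,
#'   twt`.
#' @export
simulate_phenotypes <- function(config, seed = NULL) {
  cfg <- validate_sim_config(config)
  set.seed(if (is.null(seed)) cfg$seed else seed)
  design <- sim_design(cfg)
  rings <- seq(cfg$ring_range[1], cfg$ring_range[2])
  if (length(rings) == 0) stop("empty ring range")
  traits <- names(cfg$ontogeny_slopes)

  fams <- sort(unique(design$family))
  blocks <- sort(unique(paste(design$site, design$block, sep = ":")))
  clus <- sort(unique(design$cluster))
  i_fam <- match(design$family, fams)
  i_blk <- match(paste(design$site, design$block, sep = ":"), blocks)
  i_clu <- match(design$cluster, clus)

  ## ABH: one value per tree
  abh_fam <- stats::rnorm(length(fams), 0, sqrt(cfg$abh_var_family))
  abh_blk <- stats::rnorm(length(blocks), 0, sqrt(cfg$abh_var_block))
  abh <- cfg$abh_mean + cfg$cluster_means[i_clu] * cfg$abh_mean +
    abh_fam[i_fam] + abh_blk[i_blk] +
    stats::rnorm(nrow(design), 0, sqrt(cfg$abh_var_resid))

  n_ring <- length(rings)
  out <- design[rep(seq_len(nrow(design)), each = n_ring), ]
  out$abh <- rep(abh, each = n_ring)
  out$ring <- rep(rings, times = nrow(design))
  rownames(out) <- NULL

  for (tr in traits) {
    g <- stats::rnorm(length(clus), 0, sqrt(cfg$var_cluster))
    b <- stats::rnorm(length(blocks), 0, sqrt(cfg$var_block))
    f <- stats::rnorm(length(fams), 0, sqrt(cfg$var_family))
    base <- cfg$grand_mean *
      (1 + cfg$cluster_means[i_clu] +
         outer(rep(1, nrow(design)), cfg$ontogeny_slopes[[tr]] * (rings - rings[1])))
    eff <- g[i_clu] + b[i_blk] + f[i_fam]
    vals <- base + eff + matrix(stats::rnorm(nrow(design) * n_ring, 0,
                                             sqrt(cfg$var_resid)),
                                nrow = nrow(design))
    out[[tr]] <- as.vector(t(vals))
  }
  attr(out, "normalized") <- FALSE
  out
}

#' Simulate a complete synthetic study (genotypes + phenotypes + truth)
#'
#' Runs the whole generator under a single RNG stream seeded from
#' `config$seed`: ancestral frequencies, Balding-Nichols cluster frequencies,
#' maternal genotypes with missingness, and the ring-level phenotype table.
#' The same configuration and seed always reproduce the identical output.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_output`: a list with elements `genotypes`
#'   (a [genotype_matrix] of the mothers), `phenotypes` (long-format
#'   `data.frame` of offspring rings), `freqs` (true cluster allele
#'   frequencies) and `truth` (the generating configuration).
#' @export
simulate_study <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  p_anc <- stats::runif(cfg$n_snps, cfg$ancestral_freq[1], cfg$ancestral_freq[2])
  freqs <- draw_cluster_frequencies(p_anc, cfg$fst_target, cfg$n_clusters)
  geno <- simulate_genotypes(freqs, cfg$families_per_cluster,
                             missing_rate = cfg$missing_rate_geno)
  ## one mother per family: relabel samples so each maps to a family
  pheno <- simulate_phenotypes(cfg, seed = sample.int(.Machine$integer.max, 1))
  out <- list(genotypes = geno, phenotypes = pheno, freqs = freqs,
              p_anc = p_anc, truth = cfg)
  class(out) <- "sim_output"
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat("Synthetic study:\n")
  print(x$genotypes)
  cat(sprintf("Phenotypes: %d rows (%d trees x %d rings)\n",
              nrow(x$phenotypes), length(unique(x$phenotypes$tree_id)),
              length(unique(x$phenotypes$ring))))
  invisible(x)
}

#' Simulate a neutral additive polygenic trait from genotypes
#'
#' Draws `n_causal` causal loci at random, assigns i.i.d. `N(0, effect_sd^2)`
#' allelic effects, and returns each individual's breeding value
#' `sum(dosage * effect)`. Missing dosages contribute the locus mean dosage of
#' the individual's cluster. Used to verify the neutral expectation QST = FST
#' end to end.
#'
#' @param genotypes A [genotype_matrix].
#' @param n_causal Number of causal loci (>= 1).
#' @param effect_sd Standard deviation of allelic effects.
#' @param seed Optional integer seed.
#' @return Numeric vector of breeding values, named by sample, with the chosen
#'   loci and effects attached as attributes `"loci"` and `"effects"`.
#' @export
simulate_polygenic_trait <- function(genotypes, n_causal, effect_sd, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  L <- ncol(genotypes$calls)
  if (n_causal < 1) stop("'n_causal' must be >= 1")
  if (n_causal > L) stop("'n_causal' exceeds the number of loci")
  if (!is.null(seed)) set.seed(seed)
  loci <- sort(sample.int(L, n_causal))
  beta <- stats::rnorm(n_causal, 0, effect_sd)
  X <- genotypes$calls[, loci, drop = FALSE]
  if (anyNA(X)) {
    for (cl in unique(genotypes$populations)) {
      rows <- which(genotypes$populations == cl)
      sub <- X[rows, , drop = FALSE]
      mu <- colMeans(sub, na.rm = TRUE)
      mu[is.nan(mu)] <- 1  # locus entirely missing in the cluster
      na_idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(na_idx)) sub[na_idx] <- mu[na_idx[, 2]]
      X[rows, ] <- sub
    }
  }
  bv <- as.numeric(X %*% beta)
  names(bv) <- genotypes$samples
  attr(bv, "loci") <- loci
  attr(bv, "effects") <- beta
  bv
}

#' Simulate an explicit-locus neutral half-sib study
#'
#' The explicit-locus mode of the generator: cluster differentiation of the
#' trait arises solely from drifted allele frequencies at causal loci, not from
#' an imposed cluster variance component. Mothers receive Balding-Nichols
#' genotypes; each offspring inherits one allele per locus from its mother and
#' one from the cluster pollen cloud; the trait is the offspring breeding value
#' plus Gaussian environmental noise. Under this model the expected QST
#' (Spitze's additive-variance form) equals the expected FST of the markers.
#'
#' @param n_clusters,mothers_per_cluster,offspring_per_family Design sizes.
#' @param n_snps Number of marker loci simulated for the mothers.
#' @param fst_target Balding-Nichols divergence parameter.
#' @param n_causal Number of causal loci (sampled among the `n_snps` markers).
#' @param effect_sd Allelic effect standard deviation.
#' @param env_sd Environmental (residual) standard deviation of the trait.
#' @param n_traits Number of independent neutral traits to generate on the same
#'   genotypes (independent causal sets and effects).
#' @param ancestral_freq Uniform bounds for ancestral frequencies.
#' @param seed Integer seed.
#' @return A list with `genotypes` (mothers), `phenotypes` (offspring
#'   `data.frame` with `family`, `cluster` and trait columns `y1..y<n_traits>`)
#'   and the causal metadata.
#' @export
simulate_neutral_study <- function(n_clusters = 6L, mothers_per_cluster = 50L,
                                   offspring_per_family = 10L, n_snps = 2000L,
                                   fst_target = 0.10, n_causal = 200L,
                                   effect_sd = 1, env_sd = 1, n_traits = 1L,
                                   ancestral_freq = c(0.1, 0.9), seed = 1L) {
  set.seed(seed)
  p_anc <- stats::runif(n_snps, ancestral_freq[1], ancestral_freq[2])
  freqs <- draw_cluster_frequencies(p_anc, fst_target, n_clusters)
  geno <- simulate_genotypes(freqs, mothers_per_cluster, missing_rate = 0)
  n_m <- length(geno$samples)
  fam <- data.frame(family = geno$samples,
                    cluster = as.character(geno$populations),
                    stringsAsFactors = FALSE)
  off <- fam[rep(seq_len(n_m), each = offspring_per_family), ]
  rownames(off) <- NULL
  off$tree_id <- sprintf("O%05d", seq_len(nrow(off)))
  ## trial-design columns so the table is fit-ready: one site, one block
  ## (absorbed into the intercept), ABH as pure noise orthogonal to genetics
  off$site <- "S1"
  off$block <- "B1"
  off$abh <- stats::rnorm(nrow(off))
  off$ring <- 1L
  k_idx <- match(off$cluster, paste0("C", seq_len(n_clusters)))

  causal <- lapply(seq_len(n_traits), function(i)
    sort(sample.int(n_snps, n_causal)))
  betas <- lapply(seq_len(n_traits), function(i) stats::rnorm(n_causal, 0, effect_sd))

  all_loci <- sort(unique(unlist(causal)))
  mother_calls <- geno$calls[off$family, all_loci, drop = FALSE]
  ## maternal gamete: one allele drawn from the mother's two
  maternal <- matrix(stats::rbinom(length(mother_calls), 1L, mother_calls / 2),
                     nrow = nrow(mother_calls))
  ## paternal gamete: pollen cloud at the cluster frequency
  pfreq <- freqs[, all_loci, drop = FALSE][k_idx, , drop = FALSE]
  paternal <- matrix(stats::rbinom(length(pfreq), 1L, pfreq), nrow = nrow(pfreq))
  dosage <- maternal + paternal
  colnames(dosage) <- as.character(all_loci)

  for (i in seq_len(n_traits)) {
    X <- dosage[, as.character(causal[[i]]), drop = FALSE]
    off[[paste0("y", i)]] <- as.numeric(X %*% betas[[i]]) +
      stats::rnorm(nrow(off), 0, env_sd)
  }
  list(genotypes = geno, phenotypes = off, causal = causal, effects = betas,
       freqs = freqs)
}
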
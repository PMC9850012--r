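ring_table <- function(rings, year = NULL, n_tree = 1) {
  d <- expand.grid(tree_id = sprintf("T%02d", seq_len(n_tree)), ring = rings,
                   stringsAsFactors = FALSE)
  d$family <- "F1"; d$site <- "S1"; d$dbh <- 1
  if (!is.null(year)) d$year <- year[match(d$ring, rings)]
  d
}

test_that("ring preparation keeps rings 3..13 and respects the year cutoff", {
  d <- ring_table(1:15)
  out <- prepare_rings(d)
  expect_identical(sort(unique(out$ring)), 3:13)
  expect_equal(attr(out, "report")$removed_innermost, 2L)
  expect_equal(attr(out, "report")$removed_beyond_max, 2L)

  d2 <- ring_table(3:13, year = 1996 + (3:13))
  expect_identical(prepare_rings(d2, last_calendar_year = 2009)$ring, d2$ring)
  out2 <- prepare_rings(d2, last_calendar_year = 2007)
  expect_true(all(out2$year <= 2007))

  ## randomized ring sets vs the brute-force predicate
  set.seed(81)
  for (i in 1:5) {
    rings <- sample(1:20, 12)
    yrs <- sample(2000:2012, 12, replace = TRUE)
    d3 <- ring_table(rings, year = yrs)
    out3 <- prepare_rings(d3, max_ring = 13, drop_innermost = 2,
                          last_calendar_year = 2008)
    keep <- d3$ring > 2 & d3$ring <= 13 & d3$year <= 2008
    expect_identical(out3$ring, d3$ring[keep])
  }
  expect_error(prepare_rings(ring_table(1:2)), "no rings left")
})

test_that("family filter enforces the per-site offspring minimum", {
  mk <- function(fam, site, n) data.frame(
    tree_id = paste0(fam, site, seq_len(n)), family = fam, site = site,
    stringsAsFactors = FALSE)
  d <- rbind(mk("F1", "A", 4), mk("F1", "B", 3),   # fails at site B
             mk("F2", "A", 4), mk("F2", "B", 4),   # kept
             mk("F3", "A", 5), mk("F3", "B", 6))   # kept
  out <- filter_families(d, 4)
  expect_identical(sort(unique(out$family)), c("F2", "F3"))

  ## all families adequate -> unchanged
  d2 <- rbind(mk("F1", "A", 4), mk("F1", "B", 4))
  expect_identical(filter_families(d2, 4)$tree_id, d2$tree_id)

  ## random designs vs brute-force group counting
  set.seed(82)
  for (i in 1:5) {
    d3 <- data.frame(family = sample(sprintf("F%d", 1:8), 120, replace = TRUE),
                     site = sample(c("A", "B"), 120, replace = TRUE),
                     stringsAsFactors = FALSE)
    d3$tree_id <- sprintf("T%03d", seq_len(nrow(d3)))
    out3 <- filter_families(d3, 3)
    cnt <- table(d3$family, d3$site)
    keep_fam <- rownames(cnt)[apply(cnt, 1, function(r) all(r >= 3))]
    expect_identical(sort(unique(out3$family)), sort(keep_fam))
  }
})

test_that("stand filter drops under-represented stands when present", {
  d <- data.frame(tree_id = sprintf("T%02d", 1:40),
                  family = rep(sprintf("F%d", 1:8), each = 5),
                  site = "A",
                  stand = rep(c("st1", "st2"), c(30, 10)),
                  stringsAsFactors = FALSE)
  ## st2 holds only 2 families -> removed
  out <- filter_families(d, min_offspring_per_site = 1,
                         min_families_per_stand = 3)
  expect_false(any(out$stand == "st2"))
  expect_equal(length(unique(out$family)), 6L)
})

test_that("normalization gives unit grand means and is scale invariant", {
  set.seed(83)
  d <- data.frame(dbh = runif(50, 10, 300), rw = runif(50, 0.5, 8),
                  wd = 7)
  out <- normalize_traits(d, c("dbh", "rw", "wd"))
  expect_equal(mean(out$dbh), 1, tolerance = 1e-12)
  expect_equal(mean(out$rw), 1, tolerance = 1e-12)
  expect_true(all(out$wd == 1))
  d2 <- d; d2$dbh <- d$dbh * 2; d2$rw <- d$rw * 2
  out2 <- normalize_traits(d2, c("dbh", "rw"))
  expect_equal(out2$dbh, out$dbh, tolerance = 1e-12)
  expect_error(normalize_traits(data.frame(dbh = c(-1, 1))), "zero")
})

test_that("heritability follows the half-sib intraclass formula", {
  expect_equal(heritability(c(sigma2_F = 0.05, sigma2_B = 0.1,
                              sigma2_resid = 0.35)), 0.4)
  expect_equal(heritability(c(sigma2_F = 0, sigma2_B = 0.1,
                              sigma2_resid = 0.4)), 0)
  expect_warning(h <- heritability(c(sigma2_F = 1, sigma2_B = 0.1,
                                     sigma2_resid = 0.4)), "exceeds 1")
  expect_gt(h, 1)
  expect_error(heritability(c(sigma2_F = 0, sigma2_B = 0, sigma2_resid = 0)),
               "zero")
})

test_that("QST follows the printed and the additive-variance forms", {
  vc <- c(sigma2_A = 0.1, sigma2_F = 0.2)
  expect_equal(qst(vc), 0.1 / 0.5)
  expect_equal(qst(vc, method = "spitze"), 0.1 / 1.7)
  expect_equal(qst(c(sigma2_A = 0, sigma2_F = 0.3)), 0)
  expect_equal(qst(c(sigma2_A = 0.2, sigma2_F = 0)), 1)
  expect_error(qst(c(sigma2_A = 0, sigma2_F = 0)), "undefined")
})

test_that("heritability and QST are invariant to trait rescaling", {
  d <- make_vc_data(sA = 0.1, seed = 84)
  f1 <- fit_ring_model(d, "y", model = 3)
  d$y <- d$y * 7
  f2 <- fit_ring_model(d, "y", model = 3)
  expect_equal(heritability(f1), heritability(f2), tolerance = 1e-4)
  expect_equal(qst(f1), qst(f2), tolerance = 1e-4)
  ## QST monotone in sigma2_A at fixed sigma2_F
  qs <- sapply(c(0.01, 0.05, 0.2, 0.5),
               function(a) qst(c(sigma2_A = a, sigma2_F = 0.2)))
  expect_true(all(diff(qs) > 0))
})

test_that("the per-ring battery fits every trait-ring cell and is order independent", {
  cfg <- sim_config(n_snps = 10, families_per_cluster = 6,
                    offspring_per_family_per_site = 4,
                    ring_range = c(3L, 5L),
                    ontogeny_slopes = c(dbh = 0.1, wd = 0.01), seed = 85)
  ph <- normalize_traits(simulate_phenotypes(cfg), c("dbh", "wd"))
  b <- ring_battery(ph, model = 1, traits = c("dbh", "wd"), include_abh = TRUE)
  expect_equal(nrow(b$results), 7L)  # 2 traits x 3 rings + ABH
  expect_equal(b$bonferroni, 0.05 / 6)
  expect_true(all(is.finite(b$results$h2)))
  ph_shuffled <- ph[sample(nrow(ph)), ]
  b2 <- ring_battery(ph_shuffled, model = 1, traits = c("dbh", "wd"))
  o1 <- b$results[b$results$trait != "abh", ]
  o2 <- b2$results
  o2 <- o2[order(match(paste(o2$trait, o2$ring), paste(o1$trait, o1$ring))), ]
  expect_equal(o1$sigma2_F, o2$sigma2_F, tolerance = 1e-6)
})

test_that("battery flags cluster effects only where they exist", {
  set.seed(86)
  ## dbh carries a strong cluster signal, wd none
  d <- NULL
  for (r in 3:5) {
    dr <- make_vc_data(n_cluster = 6, n_fam_per_cluster = 10, n_off = 6,
                       sA = 0, sF = 0.05, sB = 0.02, sE = 0.2,
                       seed = 860 + r)
    dr$ring <- r
    dr$dbh <- dr$y + c(0, 0.2, 0.4, 0.6, 0.8, 1.0)[as.integer(factor(dr$cluster))]
    dr$wd <- rnorm(nrow(dr), 1, 0.3)
    d <- rbind(d, dr)
  }
  b <- ring_battery(d, model = 2, traits = c("dbh", "wd"))
  p_dbh <- b$results$p_cluster[b$results$trait == "dbh"]
  p_wd <- b$results$p_cluster[b$results$trait == "wd"]
  expect_true(all(p_dbh < b$bonferroni))
  expect_true(mean(p_wd > b$bonferroni) >= 2 / 3)
})

test_that("trend tests detect slopes and respect symmetry", {
  tt <- suppressWarnings(trend_test(1:10 * 2, 1:10))  # exact fit by design
  expect_equal(tt$slope, 2)
  expect_lt(tt$p, 1e-10)
  set.seed(870)
  noisy <- 2 * (1:10) + rnorm(10, 0, 0.5)
  tt_n <- trend_test(noisy, 1:10)
  rev_tt <- trend_test(rev(noisy), 1:10)
  expect_equal(rev_tt$slope, -tt_n$slope, tolerance = 1e-10)
  expect_equal(abs(rev_tt$t), abs(tt_n$t), tolerance = 1e-10)
  const <- trend_test(rep(1, 5), 1:5)
  expect_true(is.na(const$t))
  expect_error(trend_test(c(1, 2), c(1, 2)), "at least 3")

  ## calibration: i.i.d. noise rejects at ~alpha
  set.seed(87)
  p <- replicate(1000, trend_test(rnorm(11), 1:11)$p)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("coefficient of variation per ring tracks the definition", {
  d <- data.frame(ring = rep(c(3, 4), each = 4),
                  dbh = c(1, 2, 3, 4, 10, 10, 10, 10))
  cv <- cv_per_ring(d, "dbh")
  expect_equal(cv$cv[cv$ring == 3], sd(1:4) / 2.5)
  expect_equal(cv$cv[cv$ring == 4], 0)
})

test_that("family-effect PCA recovers the latitudinal ordering of clusters", {
  set.seed(88)
  clus <- sprintf("C%d", 1:6)
  lat_offsets <- seq(-0.5, 0.5, length.out = 6)
  d <- NULL
  for (r in 3:4) {
    dr <- make_vc_data(n_cluster = 6, n_fam_per_cluster = 8, n_off = 5,
                       sA = 0, sF = 0.05, sB = 0.01, sE = 0.1, seed = 880 + r)
    dr$ring <- r
    off <- lat_offsets[as.integer(factor(dr$cluster))]
    dr$dbh <- dr$y + off
    dr$rw <- dr$y * 0.5 + off * 0.8 + rnorm(nrow(dr), 0, 0.1)
    d <- rbind(d, dr)
  }
  b <- ring_battery(d, model = 1, traits = c("dbh", "rw"))
  fam_cluster <- setNames(d$cluster[!duplicated(d$family)],
                          d$family[!duplicated(d$family)])
  p <- family_effect_pca(b, cluster_map = fam_cluster)
  cent <- p$centroids[clus, "PC1"]
  expect_equal(abs(cor(cent, 1:6, method = "spearman")), 1)
  expect_lte(sum(p$pve), 100 + 1e-8)
  ## residual mode runs too
  p2 <- family_effect_pca(b, what = "residuals", cluster_map = fam_cluster)
  expect_equal(dim(p2$matrix), dim(p$matrix))
})

test_that("label shuffling inflates within-group variance when structure is real", {
  set.seed(89)
  d <- make_vc_data(n_cluster = 4, n_fam_per_cluster = 12, n_off = 6,
                    sA = 0, sF = 0.5, sB = 0, sE = 0.1, seed = 89)
  out <- shuffle_variance_test(d, "y", level = "family", n_perm = 199, seed = 90)
  expect_lt(out$p, 0.02)
  expect_gt(mean(out$perm), out$observed)
  expect_gte(out$p, 1 / 200)  # permutation p bounded away from 0

  ## pure-noise labels: p roughly uniform
  ps <- sapply(1:20, function(i) {
    dn <- make_vc_data(n_cluster = 4, n_fam_per_cluster = 10, n_off = 4,
                       sA = 0, sF = 0, sB = 0, sE = 1, seed = 900 + i)
    shuffle_variance_test(dn, "y", level = "family", n_perm = 199,
                          seed = 900 + i)$p
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})
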
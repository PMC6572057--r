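# hand-made test_stats rows for surface construction
fake_stats <- function(z1, z2, name = sprintf("m%03d", seq_along(z1))) {
  data.frame(metabolite = name, mean_diff = z1 * exp(z2), se = exp(z2),
             t = z1, df = 20, p = 2 * pt(-abs(z1), 20), z1 = z1, z2 = z2,
             stringsAsFactors = FALSE)
}

test_that("two_sample_stats reproduces the Welch form by hand", {
  m <- intensity_matrix(matrix(c(1, 2, 3, 4, 5, 6), 1),
                        group_labels = rep(c("a", "b"), each = 3))
  st <- two_sample_stats(m)
  expect_equal(st$mean_diff, -3)
  expect_equal(st$se, sqrt(1 / 3 + 1 / 3))
  expect_equal(st$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(st$z1, st$t)
  expect_equal(st$z2, log(st$se))
  # identical group means give t = 0
  m0 <- intensity_matrix(matrix(c(1, 2, 1, 2), 1),
                         group_labels = c("a", "a", "b", "b"))
  expect_equal(two_sample_stats(m0)$t, 0)
})

test_that("swapping group labels negates t and preserves se", {
  set.seed(44)
  v <- matrix(rnorm(50 * 10), 50)
  m1 <- intensity_matrix(v, group_labels = rep(c("a", "b"), each = 5))
  m2 <- intensity_matrix(v, group_labels = rep(c("b", "a"), each = 5))
  s1 <- two_sample_stats(m1); s2 <- two_sample_stats(m2)
  expect_equal(s1$t, -s2$t)
  expect_equal(s1$se, s2$se)
  expect_equal(s1$p, s2$p)
})

test_that("degenerate rows are floored and give t = 0 in every permutation", {
  set.seed(45)
  v <- rbind(matrix(rnorm(5 * 8), 5), rep(3, 8))
  m <- intensity_matrix(v, group_labels = rep(c("a", "b"), each = 4))
  expect_warning(st <- two_sample_stats(m), "floored")
  expect_equal(st$t[6], 0)
  perm <- permutation_null(m, np = 5, seed = 2)
  expect_true(all(perm$t[perm$metabolite == "met6"] == 0))
})

test_that("permutation_null is seed-reproducible and honors the identity hook", {
  set.seed(46)
  m <- tiny_matrix(matrix(rnorm(40 * 8), 40), 4, 4)
  p1 <- permutation_null(m, np = 10, seed = 9)
  p2 <- permutation_null(m, np = 10, seed = 9)
  expect_identical(p1, p2)
  obs <- two_sample_stats(m)
  pid <- permutation_null(m, np = 1, seed = 1,
                          permutations = matrix(1:4, nrow = 1))
  expect_equal(pid$t, obs$t)
  expect_equal(pid$se, obs$se)
})

test_that("excess np falls back to exhaustive enumeration", {
  set.seed(47)
  m <- tiny_matrix(matrix(rnorm(10 * 4), 10), 2, 2)
  expect_warning(p <- permutation_null(m, np = 50, seed = 3),
                 "enumerating exhaustively")
  expect_equal(attr(p, "np"), choose(4, 2))
})

test_that("complete-null construction gives r = np/(np+1) and fdr2d = pi0", {
  set.seed(48)
  obs <- fake_stats(rnorm(300), rnorm(300, 0, 0.3))
  np <- 7
  perm <- do.call(rbind, replicate(np, obs, simplify = FALSE))
  attr(perm, "np") <- np
  surf <- estimate_r(obs, perm, smoothing_df = 0)
  occupied <- surf$coverage
  expect_equal(unname(surf$r[occupied]),
               rep(np / (np + 1), sum(occupied)), tolerance = 1e-12)
  pi0 <- 0.87
  surf <- fdr2d_surface(surf, pi0)
  expect_equal(unname(surf$fdr[occupied]),
               rep(pi0, sum(occupied)), tolerance = 1e-12)
  # the same identity holds for the collapsed one-dimensional rate
  curve <- fdr1d_curve(obs, perm, pi0 = pi0, smoothing_df = 0, np = np)
  filled <- curve$count_observed + curve$count_permuted > 0
  expect_equal(curve$fdr1d[filled], rep(pi0, sum(filled)), tolerance = 1e-12)
})

test_that("unsmoothed r equals raw per-cell proportions (counting oracle)", {
  obs <- fake_stats(c(-2, -2, 2, 2, 2), c(0, 0, 0, 0, 0))
  perm <- fake_stats(c(-2, -2, -2, 2, rep(c(-2, 2), 3)), rep(0, 10))
  grid <- list(breaks1 = c(-4, 0, 4), breaks2 = c(-1, 0.5, 2))
  grid$mid1 <- c(-2, 2); grid$mid2 <- c(-0.25, 1.25)
  surf <- estimate_r(obs, perm, grid = grid, smoothing_df = 0, np = 2)
  # cell (z1<0, z2 low): 2 observed, 6 permuted -> 6/8
  expect_equal(surf$r[1, 1], 6 / 8)
  # cell (z1>0, z2 low): 3 observed, 4 permuted -> 4/7
  expect_equal(surf$r[2, 1], 4 / 7)
  # cell with 0 observed but k > 0 permuted: raw proportion 1, clamped
  obs2 <- fake_stats(c(-2, -2), c(-0.25, -0.25))
  perm2 <- fake_stats(c(-2, -2, 2, 2), rep(-0.25, 4))
  surf2 <- estimate_r(obs2, perm2, grid = grid, smoothing_df = 0, np = 2)
  expect_equal(surf2$r[2, 1], 1 - 1e-4)
})

test_that("fdr2d plug-in formula matches direct recomputation", {
  set.seed(49)
  obs <- fake_stats(rnorm(100), rnorm(100, 0, 0.2))
  perm <- fake_stats(rnorm(500), rnorm(500, 0, 0.2))
  surf <- estimate_r(obs, perm, smoothing_df = 4, np = 5)
  pi0 <- 0.6
  filled <- fdr2d_surface(surf, pi0)
  manual <- pmin(pmax(pi0 * surf$r / (5 * (1 - surf$r)), 0), 1)
  expect_equal(filled$fdr, manual, tolerance = 1e-12)
  expect_true(all(filled$fdr >= 0 & filled$fdr <= 1))
})

test_that("fdr1d is symmetric for symmetric statistics and matches counting", {
  z <- c(-3, -1, 1, 3)
  obs <- fake_stats(z, rep(0, 4))
  perm <- fake_stats(rep(z, 2), rep(0, 8))
  curve <- fdr1d_curve(obs, perm, pi0 = 1, n_bins = 4, smoothing_df = 0, np = 2)
  # counting oracle per bin: r = perm/(perm+obs) = 2/3, fdr1d = (2/3)/(2*(1/3)) = 1
  filled <- curve$count_observed > 0
  expect_equal(curve$fdr1d[filled], rep(1, sum(filled)))
  expect_equal(curve$fdr1d, rev(curve$fdr1d), tolerance = 1e-12)
})

test_that("estimate_pi0 recovers the null proportion", {
  set.seed(50)
  # complete null: observed and permuted share the same distribution
  obs <- fake_stats(rnorm(2000), rnorm(2000, 0, 0.2))
  perm <- fake_stats(rnorm(10000), rnorm(10000, 0, 0.2))
  expect_equal(estimate_pi0(obs, perm), 1, tolerance = 0.05)
  # half the metabolites pushed far out: estimate near 0.5
  z_obs <- c(rnorm(1000), rnorm(1000, 12))
  obs2 <- fake_stats(z_obs, rnorm(2000, 0, 0.2))
  expect_equal(estimate_pi0(obs2, perm), 0.5, tolerance = 0.08)
  expect_lte(estimate_pi0(obs2, perm), 1)
  expect_gt(estimate_pi0(obs2, perm), 0)
})

test_that("rejection thresholds behave at the extremes and on a toy surface", {
  obs <- fake_stats(c(-2, -2, 2, 2), c(-0.25, 1.25, -0.25, 1.25))
  perm <- do.call(rbind, replicate(3, obs, simplify = FALSE))
  grid <- list(breaks1 = c(-4, 0, 4), breaks2 = c(-1, 0.5, 2),
               mid1 = c(-2, 2), mid2 = c(-0.25, 1.25))
  surf <- estimate_r(obs, perm, grid = grid, smoothing_df = 0, np = 3)
  surf <- fdr2d_surface(surf, 0.8)
  # complete-null toy: every point sits at fdr2d = 0.8 (up to roundoff)
  sets <- fdr_reject(obs, surf, levels = c(0, 0.5, 0.79, 0.81, 1))
  expect_equal(vapply(sets, `[[`, 0, "n"), c(0, 0, 0, 4, 4))
  # nesting across levels
  ns <- vapply(sets, `[[`, 0, "n")
  expect_true(all(diff(ns) >= 0))
  for (k in seq_len(length(sets) - 1))
    expect_true(all(sets[[k]]$rejected %in% sets[[k + 1]]$rejected))
})

test_that("equal-t points with 10x different se separate in fdr2d, not fdr1d", {
  t0 <- 2; se1 <- 1; se2 <- 10
  grid <- list(breaks1 = c(0, 4, 8), breaks2 = c(-1, 1, 3.6),
               mid1 = c(2, 6), mid2 = c(0, 2.3))
  # the two target points: same t, standard errors 1 and 10
  pt_a <- fake_stats(t0, log(se1), "point_small_se")
  pt_b <- fake_stats(t0, log(se2), "point_large_se")
  filler_obs <- fake_stats(c(rep(2, 18), rep(6, 4)),
                           c(rep(0, 9), rep(2.3, 9), rep(0, 4)))
  obs <- rbind(pt_a, pt_b, filler_obs)
  # permuted cloud: the low-se cell is observation-rich (10 perm : 11 obs),
  # the high-se cell is permutation-rich (90 perm : 10 obs)
  perm <- fake_stats(c(rep(2, 100), rep(6, 20)),
                     c(rep(0, 10), rep(2.3, 90), rep(0, 20)))
  surf <- estimate_r(obs, perm, grid = grid, smoothing_df = 0, np = 5)
  surf <- fdr2d_surface(surf, pi0 = 0.5)
  fdr_a <- assign_fdr2d(pt_a, surf)
  fdr_b <- assign_fdr2d(pt_b, surf)
  expect_gt(abs(fdr_a - fdr_b), 0.2)
  expect_lt(fdr_a, fdr_b)  # small-se point is the cheaper rejection here
  # the collapsed 1D rate cannot tell them apart: same t, same fdr1d
  curve <- fdr1d_curve(obs, perm, pi0 = 0.5, n_bins = 2, smoothing_df = 0,
                       np = 5)
  expect_equal(assign_fdr1d(pt_a, curve), assign_fdr1d(pt_b, curve))
})

test_that("plot_data coordinates follow their definitions", {
  set.seed(51)
  obs <- fake_stats(c(0, rnorm(99)), rnorm(100, 0, 0.3))
  perm <- fake_stats(rnorm(400), rnorm(400, 0, 0.3))
  surf <- fdr2d_surface(estimate_r(obs, perm, smoothing_df = 4, np = 4), 0.9)
  volcano <- plot_data(obs, surf, mode = "volcano")
  expect_equal(volcano$points$y, obs$z2)
  expect_equal(volcano$points$x, obs$mean_diff)
  tornado <- plot_data(obs, surf, mode = "tornado")
  expect_equal(tornado$points$y[1], 0)  # t = 0 -> p = 1 -> -log10(p) = 0
  expect_equal(tornado$points$y, -log10(obs$p))
})

test_that("isolines separate low-fdr cells from high-fdr cells", {
  # toy surface with a known fdr gradient in z1
  obs <- fake_stats(seq(-4, 4, length.out = 60), rep(0, 60))
  surf <- list(breaks1 = seq(-5, 5, length.out = 21),
               breaks2 = c(-1, 0, 1),
               z1 = seq(-4.75, 4.75, by = 0.5), z2 = c(-0.5, 0.5),
               r = matrix(0.5, 20, 2), np = 1,
               counts_observed = matrix(1, 20, 2),
               counts_permuted = matrix(1, 20, 2),
               coverage = matrix(TRUE, 20, 2), smoothing_df = 0)
  class(surf) <- "fdr2d_surface"
  surf$fdr <- matrix(rep(plogis(seq(-4.75, 4.75, by = 0.5)), 2), 20, 2)
  surf$pi0 <- 1
  pd <- plot_data(obs, surf, levels = 0.5, mode = "volcano")
  expect_gt(nrow(pd$isolines), 0)
  # the level-0.5 contour of plogis(z1) sits at z1 = 0; in volcano
  # coordinates x = z1 * exp(z2) with z2 on the contour, so x/exp(y) = z1
  z1_on_iso <- pd$isolines$x / exp(pd$isolines$y)
  expect_true(all(abs(z1_on_iso) < 0.26))  # within one cell width of 0
  # threshold-mask oracle: cells on either side of the isoline disagree
  mask <- surf$fdr <= 0.5
  expect_true(all(mask[surf$z1 < -0.3, ]) && !any(mask[surf$z1 > 0.3, ]))
})
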
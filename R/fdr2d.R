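#' Welch two-sample statistics for every metabolite
#'
#' For each metabolite the mean difference between the two groups, the
#' pooled (Welch) standard error `Sp = sqrt(S1^2/n1 + S2^2/n2)` and the
#' t-statistic `T = (Xbar1 - Xbar2) / Sp` are computed, together with the
#' coordinates used by the two-dimensional local fdr: `z1 = T` and
#' `z2 = log(Sp)`. p-values use the t reference distribution with
#' Welch-Satterthwaite degrees of freedom (two-sided).
#'
#' Metabolites with (near-)zero standard error are floored at
#' `1e-8 * median(se)` with a warning so that every statistic is finite.
#'
#' @param m An [intensity_matrix()] (two groups, each with >= 2 subjects).
#' @return A data frame of class `test_stats` with columns `metabolite`,
#'   `mean_diff`, `se`, `t`, `df`, `p`, `z1`, `z2`.
#' @examples
#' m <- intensity_matrix(rbind(c(1, 2, 3, 4, 5, 6)),
#'                       group_labels = rep(c("a", "b"), each = 3))
#' two_sample_stats(m)  # t = -3/sqrt(2/3)
#' @export
two_sample_stats <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  g <- m$groups
  if (any(table(g) < 2L))
    stop("two_sample_stats: each group needs at least 2 subjects")
  x1 <- m$values[, g == levels(g)[1L], drop = FALSE]
  x2 <- m$values[, g == levels(g)[2L], drop = FALSE]
  welch_stats(x1, x2, rownames(m$values))
}

# vectorized Welch machinery shared with the permutation null
welch_stats <- function(x1, x2, names, se_floor_warn = TRUE) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  a1 <- v1 / n1; a2 <- v2 / n2
  se2 <- a1 + a2
  se <- sqrt(se2)
  floor_val <- 1e-8 * stats::median(se[se > 0])
  degenerate <- se < floor_val | !is.finite(se) | se == 0
  if (any(degenerate)) {
    if (se_floor_warn)
      warning("two_sample_stats: ", sum(degenerate),
              " metabolite(s) with degenerate standard error floored at ",
              signif(floor_val, 3))
    se[degenerate] <- floor_val
    se2[degenerate] <- floor_val^2
  }
  t <- (m1 - m2) / se
  df <- se2^2 / (a1^2 / (n1 - 1) + a2^2 / (n2 - 1))
  df[!is.finite(df) | df <= 0] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df = df)
  out <- data.frame(metabolite = names, mean_diff = m1 - m2, se = se,
                    t = t, df = df, p = p, z1 = t, z2 = log(se),
                    stringsAsFactors = FALSE)
  class(out) <- c("test_stats", "data.frame")
  out
}

#' Permutation null statistics
#'
#' Recomputes the full set of two-sample statistics under `np` random
#' permutations of the group labels (each permutation rearranges all labels
#' without replacement), giving the empirical null cloud in the `(z1, z2)`
#' plane. When `np` exceeds the number of distinct label assignments
#' (`choose(n, n1)`), a warning is issued and all distinct assignments are
#' enumerated exhaustively instead.
#'
#' @param m An [intensity_matrix()].
#' @param np Number of permutations (>= 1).
#' @param seed Integer seed; required for reproducibility.
#' @param permutations Optional integer matrix (one row per permutation) of
#'   column indices taking the role of group 1, overriding random
#'   generation — a hook for exact tests (e.g. the identity permutation).
#' @return A `test_stats` data frame with an extra `perm` column stacking
#'   all permutations; attribute `np` records their number.
#' @export
permutation_null <- function(m, np = 100, seed, permutations = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  np <- as.integer(np)
  if (np < 1L) stop("permutation_null: np must be >= 1")
  g <- m$groups
  n <- length(g); n1 <- sum(g == levels(g)[1L])
  if (is.null(permutations)) {
    if (missing(seed) || is.null(seed))
      stop("permutation_null: a seed is required")
    total <- choose(n, n1)
    if (np > total) {
      warning("permutation_null: np = ", np, " exceeds the ", total,
              " distinct label assignments; enumerating exhaustively")
      permutations <- t(utils::combn(n, n1))
    } else {
      set.seed(as.integer(seed))
      permutations <- t(vapply(seq_len(np),
                               function(b) sample.int(n, n1),
                               integer(n1)))
    }
  }
  np_eff <- nrow(permutations)
  res <- vector("list", np_eff)
  for (b in seq_len(np_eff)) {
    idx1 <- permutations[b, ]
    x1 <- m$values[, idx1, drop = FALSE]
    x2 <- m$values[, -idx1, drop = FALSE]
    st <- welch_stats(x1, x2, rownames(m$values), se_floor_warn = FALSE)
    st$perm <- b
    res[[b]] <- st
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "np") <- np_eff
  class(out) <- c("test_stats", "data.frame")
  out
}

#' Define the evaluation grid over the (z1, z2) plane
#'
#' A rectangular grid of cells spanning the combined range of the observed
#' and permuted points, padded on each side so every point falls strictly
#' inside.
#'
#' @param observed,permuted `test_stats` data frames (or anything with `z1`,
#'   `z2` columns).
#' @param n Number of cells per axis, length 2 (z1, z2).
#' @param pad Fractional range padding per side.
#' @return A list with `breaks1`, `breaks2` (cell boundaries) and `mid1`,
#'   `mid2` (cell centers).
#' @export
fdr_grid <- function(observed, permuted = NULL, n = c(50, 50), pad = 0.05) {
  z1 <- c(observed$z1, permuted$z1)
  z2 <- c(observed$z2, permuted$z2)
  n <- rep_len(as.integer(n), 2L)
  stretch <- function(r) {
    w <- diff(r)
    if (w == 0) w <- max(abs(r), 1)
    r + c(-1, 1) * pad * w
  }
  r1 <- stretch(range(z1)); r2 <- stretch(range(z2))
  breaks1 <- seq(r1[1L], r1[2L], length.out = n[1L] + 1L)
  breaks2 <- seq(r2[1L], r2[2L], length.out = n[2L] + 1L)
  list(breaks1 = breaks1, breaks2 = breaks2,
       mid1 = (breaks1[-1L] + breaks1[-length(breaks1)]) / 2,
       mid2 = (breaks2[-1L] + breaks2[-length(breaks2)]) / 2)
}

bin_counts <- function(z1, z2, grid) {
  i <- findInterval(z1, grid$breaks1, rightmost.closed = TRUE,
                    all.inside = TRUE)
  j <- findInterval(z2, grid$breaks2, rightmost.closed = TRUE,
                    all.inside = TRUE)
  n1 <- length(grid$mid1); n2 <- length(grid$mid2)
  counts <- matrix(0, n1, n2)
  tab <- table(factor(i, levels = seq_len(n1)), factor(j, levels = seq_len(n2)))
  counts[] <- as.numeric(tab)
  counts
}

#' Estimate the permuted-point ratio r(z) over the grid
#'
#' The key ingredient of the two-dimensional local fdr is the ratio
#' `r(z) = np f0(z) / (f(z) + np f0(z))`, which equals the local proportion
#' of permutation-derived points among all points (observed plus permuted)
#' near `z`. It is estimated by a smoothed binomial regression of point
#' origin on the binned `(z1, z2)` plane: per-cell counts of permuted and
#' observed points are fitted with a fixed-degrees-of-freedom thin-plate
#' spline (`mgcv::gam`, logit link). With `smoothing_df = 0` the raw
#' per-cell proportions are returned unsmoothed. Estimates are clamped to
#' `[1e-4, 1 - 1e-4]`; cells containing no points take the smoother's
#' extrapolated value and are flagged in the coverage mask.
#'
#' @param observed Observed `test_stats` (one row per metabolite).
#' @param permuted Permutation-null `test_stats` from [permutation_null()].
#' @param grid A grid from [fdr_grid()]; built automatically when `NULL`.
#' @param smoothing_df Spline degrees of freedom (default 8); 0 for raw
#'   proportions.
#' @param np Number of permutations; inferred from `permuted` when missing.
#' @return An object of class `fdr2d_surface`: list with the grid, `r`
#'   (matrix of clamped ratios), `counts_observed`, `counts_permuted`,
#'   `coverage` (logical matrix, TRUE where a cell holds data), `np`,
#'   `smoothing_df`; `fdr` and `pi0` are filled by [fdr2d_surface()].
#' @export
estimate_r <- function(observed, permuted, grid = NULL, smoothing_df = 8,
                       np = NULL) {
  if (is.null(np)) np <- attr(permuted, "np") %||% (nrow(permuted) / nrow(observed))
  if (abs(np - round(np)) > 1e-8)
    stop("estimate_r: permuted size is not a multiple of observed size; pass np")
  np <- round(np)
  if (is.null(grid)) grid <- fdr_grid(observed, permuted)
  co <- bin_counts(observed$z1, observed$z2, grid)
  cp <- bin_counts(permuted$z1, permuted$z2, grid)
  if (sum(co) != nrow(observed) || sum(cp) != nrow(permuted))
    stop("estimate_r: grid does not cover all points; widen the grid")
  tot <- co + cp
  coverage <- tot > 0
  delta <- 1e-4
  if (smoothing_df <= 0) {
    r <- matrix(NA_real_, nrow(co), ncol(co))
    r[coverage] <- cp[coverage] / tot[coverage]
    r[!coverage] <- np / (np + 1)  # no-data cells: neutral prior ratio
  } else {
    cells <- expand.grid(z1 = grid$mid1, z2 = grid$mid2)
    dat <- data.frame(cells, perm = as.vector(cp), obs = as.vector(co))
    fitdat <- dat[as.vector(coverage), , drop = FALSE]
    k <- max(3L, as.integer(smoothing_df) + 1L)
    fit <- mgcv::gam(cbind(perm, obs) ~ s(z1, z2, k = k, fx = TRUE),
                     family = stats::binomial(), data = fitdat,
                     method = "GCV.Cp")
    pred <- stats::predict(fit, newdata = dat, type = "response")
    r <- matrix(as.numeric(pred), nrow(co), ncol(co))
  }
  r <- pmin(pmax(r, delta), 1 - delta)  # r first so matrix dim is kept
  structure(list(breaks1 = grid$breaks1, breaks2 = grid$breaks2,
                 z1 = grid$mid1, z2 = grid$mid2, r = r, fdr = NULL,
                 pi0 = NA_real_, np = np, counts_observed = co,
                 counts_permuted = cp, coverage = coverage,
                 smoothing_df = smoothing_df),
            class = "fdr2d_surface")
}

#' @export
print.fdr2d_surface <- function(x, ...) {
  cat("<fdr2d_surface> ", length(x$z1), " x ", length(x$z2), " grid, np = ",
      x$np, ", ", sum(x$coverage), " occupied cells",
      if (!is.na(x$pi0)) paste0(", pi0 = ", signif(x$pi0, 4)), "\n", sep = "")
  invisible(x)
}

#' Fill the fdr2d surface by the plug-in formula
#'
#' Converts the estimated ratio `r(z)` into the two-dimensional local false
#' discovery rate via
#' `fdr2d(z) = pi0 r(z) / (np (1 - r(z)))`, clipped to `[0, 1]`. Under a
#' complete null (permuted cloud identical to the observed cloud)
#' `r = np/(np+1)` and the surface equals `pi0` everywhere.
#'
#' @param surface An `fdr2d_surface` from [estimate_r()].
#' @param pi0 Null-proportion estimate in (0, 1], e.g. from
#'   [estimate_pi0()].
#' @return The surface with `fdr` (matrix) and `pi0` filled.
#' @export
fdr2d_surface <- function(surface, pi0) {
  stopifnot(inherits(surface, "fdr2d_surface"))
  if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 > 1)
    stop("fdr2d_surface: pi0 must be a scalar in (0, 1]")
  fdr <- pi0 * surface$r / (surface$np * (1 - surface$r))
  surface$fdr <- pmin(pmax(fdr, 0), 1)  # fdr first so matrix dim is kept
  surface$pi0 <- pi0
  surface
}

#' One-dimensional local fdr along the t-axis
#'
#' The same smoothed-proportion machinery as [estimate_r()], collapsed onto
#' the `z1` (t-statistic) axis: `fdr1d(z1) = pi0 f0(z1) / f(z1)`, computed
#' via the 1D ratio `r1(z1)` and the identity
#' `f0/f = r1 / (np (1 - r1))`. Provided for comparison with the
#' two-dimensional rate (points with equal t receive equal fdr1d regardless
#' of their standard errors).
#'
#' @inheritParams estimate_r
#' @param pi0 Null proportion in (0, 1].
#' @param n_bins Number of z1 bins.
#' @return A data frame with columns `z1` (bin centers), `r`, `fdr1d`,
#'   `count_observed`, `count_permuted`; attribute `breaks` holds the bin
#'   boundaries. Per-point values can be read off with [assign_fdr1d()].
#' @export
fdr1d_curve <- function(observed, permuted, pi0, n_bins = 100,
                        smoothing_df = 8, np = NULL) {
  if (is.null(np)) np <- attr(permuted, "np") %||% (nrow(permuted) / nrow(observed))
  np <- round(np)
  z <- c(observed$z1, permuted$z1)
  pad <- 0.05 * diff(range(z))
  breaks <- seq(min(z) - pad, max(z) + pad, length.out = n_bins + 1L)
  mid <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  co <- tabulate(findInterval(observed$z1, breaks, all.inside = TRUE), n_bins)
  cp <- tabulate(findInterval(permuted$z1, breaks, all.inside = TRUE), n_bins)
  tot <- co + cp
  delta <- 1e-4
  if (smoothing_df <= 0) {
    r <- ifelse(tot > 0, cp / pmax(tot, 1), np / (np + 1))
  } else {
    keep <- tot > 0
    k <- max(3L, as.integer(smoothing_df) + 1L)
    fit <- mgcv::gam(cbind(perm, obs) ~ s(z1, k = k, fx = TRUE),
                     family = stats::binomial(),
                     data = data.frame(z1 = mid[keep], perm = cp[keep],
                                       obs = co[keep]))
    r <- as.numeric(stats::predict(fit, newdata = data.frame(z1 = mid),
                                   type = "response"))
  }
  r <- pmin(1 - delta, pmax(delta, r))
  out <- data.frame(z1 = mid, r = r,
                    fdr1d = pmin(1, pmax(0, pi0 * r / (np * (1 - r)))),
                    count_observed = co, count_permuted = cp)
  attr(out, "breaks") <- breaks
  out
}

#' Per-point fdr1d lookup
#'
#' @param records `test_stats` rows to score.
#' @param curve Output of [fdr1d_curve()].
#' @return Numeric vector of fdr1d values (linear interpolation between bin
#'   centers, constant beyond the ends).
#' @export
assign_fdr1d <- function(records, curve) {
  stats::approx(curve$z1, curve$fdr1d, xout = records$z1, rule = 2)$y
}

#' Estimate the null proportion pi0 by central matching
#'
#' Truly differential metabolites push observed t-statistics into the tails,
#' thinning the center of the observed distribution relative to the
#' permutation null. The estimator compares the fraction of observed points
#' whose `z1` falls in the central 50% band of the permuted `z1`
#' distribution with the corresponding permuted fraction; their ratio
#' estimates `pi0` and is capped at 1. Under a complete null the estimate is
#' close to 1.
#'
#' @inheritParams estimate_r
#' @param central Central probability mass of the permuted distribution
#'   defining the matching window (default 0.5).
#' @return A scalar in (0, 1].
#' @export
estimate_pi0 <- function(observed, permuted, central = 0.5) {
  stopifnot(nrow(observed) > 0, nrow(permuted) > 0)
  qs <- stats::quantile(permuted$z1, probs = c((1 - central) / 2,
                                               1 - (1 - central) / 2))
  in_win <- function(z) mean(z >= qs[1L] & z <= qs[2L])
  denom <- in_win(permuted$z1)
  if (denom == 0) return(1)
  max(1e-3, min(1, in_win(observed$z1) / denom))
}

# bilinear interpolation of a grid matrix at arbitrary points;
# coordinates outside the center lattice are clamped to the nearest cell
interp_surface <- function(surface, what, z1, z2) {
  g1 <- surface$z1; g2 <- surface$z2
  m <- surface[[what]]
  x <- pmin(pmax(z1, g1[1L]), g1[length(g1)])
  y <- pmin(pmax(z2, g2[1L]), g2[length(g2)])
  i <- pmin(findInterval(x, g1), length(g1) - 1L)
  j <- pmin(findInterval(y, g2), length(g2) - 1L)
  i <- pmax(i, 1L); j <- pmax(j, 1L)
  fx <- (x - g1[i]) / (g1[i + 1L] - g1[i])
  fy <- (y - g2[j]) / (g2[j + 1L] - g2[j])
  v <- (1 - fx) * (1 - fy) * m[cbind(i, j)] +
       fx * (1 - fy) * m[cbind(i + 1L, j)] +
       (1 - fx) * fy * m[cbind(i, j + 1L)] +
       fx * fy * m[cbind(i + 1L, j + 1L)]
  outside <- z1 < g1[1L] | z1 > g1[length(g1)] |
             z2 < g2[1L] | z2 > g2[length(g2)]
  attr(v, "outside") <- outside
  v
}

#' Per-point fdr2d values
#'
#' @param records `test_stats` rows to score.
#' @param surface A filled surface from [fdr2d_surface()].
#' @return Numeric vector of fdr2d values at each point's `(z1, z2)`
#'   location (bilinear interpolation between cell centers; points beyond
#'   the center lattice take the nearest cell's value and are flagged in the
#'   `outside` attribute).
#' @export
assign_fdr2d <- function(records, surface) {
  stopifnot(inherits(surface, "fdr2d_surface"))
  if (is.null(surface$fdr)) stop("assign_fdr2d: surface has no fdr; call fdr2d_surface()")
  interp_surface(surface, "fdr", records$z1, records$z2)
}

#' Isoline rejection at a set of fdr2d levels
#'
#' Each metabolite is assigned the fdr2d value at its `(z1, z2)` location
#' and is rejected at level `alpha` iff its fdr2d is at most `alpha` —
#' geometrically, iff its point lies outside the corresponding isoline of
#' the surface. Rejection sets are nested across levels.
#'
#' @param records Observed `test_stats`.
#' @param surface A filled `fdr2d_surface`.
#' @param levels Numeric vector of nominal fdr2d thresholds.
#' @return A list of class `rejection_sets`: per level, a list with
#'   `level`, `rejected` (metabolite names) and `n`. The per-metabolite
#'   fdr2d vector is attached as attribute `fdr2d`.
#' @export
fdr_reject <- function(records, surface, levels = c(0.05, 0.1, 0.2, 0.3)) {
  fdr <- assign_fdr2d(records, surface)
  levels <- sort(levels)
  sets <- lapply(levels, function(a) {
    list(level = a, rejected = records$metabolite[fdr <= a],
         n = sum(fdr <= a))
  })
  structure(sets, class = "rejection_sets", fdr2d = fdr)
}

#' @export
print.rejection_sets <- function(x, ...) {
  cat("<rejection_sets>\n")
  for (s in x)
    cat(sprintf("  level %.3g: %d rejected\n", s$level, s$n))
  invisible(x)
}

#' Volcano / tornado plot data with fdr2d isolines
#'
#' Builds the plottable point table and the isoline polylines for the two
#' standard displays: the volcano plot (x = mean difference, y = log
#' standard error, i.e. `z2`) and the tornado plot (x = mean difference,
#' y = -log10 p-value). Isolines are extracted as level contours of the
#' fdr2d surface in `(z1, z2)` coordinates and mapped into each plot's
#' coordinate system via `mean_diff = z1 * exp(z2)`; the tornado's p-axis
#' uses the t reference with the median Welch degrees of freedom.
#'
#' @param records Observed `test_stats`.
#' @param surface A filled `fdr2d_surface`.
#' @param levels Isoline levels.
#' @param mode `"volcano"` or `"tornado"`.
#' @return A list with `points` (data frame `metabolite`, `x`, `y`, `fdr2d`)
#'   and `isolines` (data frame `level`, `piece`, `x`, `y`).
#' @export
plot_data <- function(records, surface, levels = c(0.05, 0.1, 0.2, 0.3),
                      mode = c("volcano", "tornado")) {
  mode <- match.arg(mode)
  stopifnot(inherits(surface, "fdr2d_surface"))
  if (is.null(surface$fdr)) stop("plot_data: surface has no fdr; call fdr2d_surface()")
  fdr <- assign_fdr2d(records, surface)
  med_df <- stats::median(records$df)
  tornado_y <- function(z1) -log10(2 * stats::pt(-abs(z1), df = med_df))
  pts <- data.frame(metabolite = records$metabolite,
                    x = records$mean_diff,
                    y = if (mode == "volcano") records$z2
                        else -log10(records$p),
                    fdr2d = fdr, stringsAsFactors = FALSE)
  cl <- grDevices::contourLines(surface$z1, surface$z2, surface$fdr,
                                levels = levels)
  iso <- if (length(cl) == 0L) {
    data.frame(level = numeric(0), piece = integer(0), x = numeric(0),
               y = numeric(0))
  } else {
    do.call(rbind, lapply(seq_along(cl), function(k) {
      z1 <- cl[[k]]$x; z2 <- cl[[k]]$y
      data.frame(level = cl[[k]]$level, piece = k,
                 x = z1 * exp(z2),
                 y = if (mode == "volcano") z2 else tornado_y(z1))
    }))
  }
  list(points = pts, isolines = iso, mode = mode)
}

#' Render a volcano or tornado plot
#'
#' Base-graphics rendering of [plot_data()]: one point per metabolite and
#' red fdr2d isolines at the requested levels.
#'
#' @inheritParams plot_data
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [plot_data()] list.
#' @export
plot_fdr2d <- function(records, surface, levels = c(0.05, 0.1, 0.2, 0.3),
                       mode = c("volcano", "tornado"), ...) {
  mode <- match.arg(mode)
  pd <- plot_data(records, surface, levels, mode)
  ylab <- if (mode == "volcano") "log(standard error)" else "-log10(p)"
  graphics::plot(pd$points$x, pd$points$y, pch = 16, cex = 0.5,
                 col = "grey40", xlab = "mean difference", ylab = ylab,
                 main = paste0(mode, " plot, fdr2d isolines at ",
                               paste(levels, collapse = ", ")), ...)
  for (pc in split(pd$isolines, pd$isolines$piece))
    graphics::lines(pc$x, pc$y, col = "red", lwd = 1.5)
  invisible(pd)
}
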
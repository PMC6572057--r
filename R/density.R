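#' Kernel density estimate of matched dissimilarity scores
#'
#' Evaluates the kernel density estimator
#' \deqn{\hat f(t) = \frac{1}{nh}\sum_{i=1}^n K\!\left(\frac{t-s_i}{h}\right)}
#' exactly at the requested grid points, as a non-parametric cross-check of
#' the parametric mixture fitted by EM (see [matched_score_density()]).
#'
#' @param scores Numeric sample of matched scores (n >= 1).
#' @param h Positive bandwidth, or `"auto"` for Silverman's rule of thumb
#'   `0.9 min(sd, IQR/1.34) n^{-1/5}` (requires n >= 2 and positive spread).
#' @param kernel `"gaussian"` (default) or `"epanechnikov"`.
#' @param grid Evaluation points; by default 512 points spanning the data
#'   range extended by 4 bandwidths on each side.
#' @return An object of class `kde_estimate`: list with `x` (grid), `y`
#'   (density values), `h`, `kernel`, `n`.
#' @examples
#' k <- kde(c(3, 5, 9), h = 1)
#' sum(diff(k$x) * (head(k$y, -1) + tail(k$y, -1)) / 2)  # ~1
#' @export
kde <- function(scores, h = "auto", kernel = c("gaussian", "epanechnikov"),
                grid = NULL) {
  kernel <- match.arg(kernel)
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n == 0L) stop("kde: empty sample")
  if (any(!is.finite(scores))) stop("kde: non-finite scores")
  if (identical(h, "auto")) {
    if (n < 2L) stop("kde: bandwidth cannot be auto-selected from a single point")
    spread <- min(stats::sd(scores), stats::IQR(scores) / 1.34)
    if (spread <= 0) spread <- stats::sd(scores)
    if (spread <= 0) stop("kde: degenerate sample; supply a bandwidth")
    h <- 0.9 * spread * n^(-1 / 5)
  }
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("kde: bandwidth h must be a positive scalar")
  if (is.null(grid))
    grid <- seq(min(scores) - 4 * h, max(scores) + 4 * h, length.out = 512L)
  kfun <- switch(kernel,
    gaussian = function(u) stats::dnorm(u),
    epanechnikov = function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0))
  # exact evaluation of (1/nh) sum K((t - s_i)/h) at each grid point
  u <- outer(grid, scores, function(t, s) (t - s) / h)
  y <- rowSums(kfun(u)) / (n * h)
  structure(list(x = grid, y = y, h = h, kernel = kernel, n = n),
            class = "kde_estimate")
}

#' @export
print.kde_estimate <- function(x, ...) {
  cat("<kde_estimate> n = ", x$n, ", ", x$kernel, " kernel, h = ",
      signif(x$h, 4), ", ", length(x$x), " grid points\n", sep = "")
  invisible(x)
}

#' Density-overlay table for the mixture-vs-KDE diagnostic
#'
#' Builds the table behind the standard overlay plot comparing the
#' parametric matched-score mixture with the kernel density estimate
#' computed from the same scores: good agreement indicates the EM component
#' means and variances are estimated appropriately.
#'
#' @param fit An `ident_fit` from [fit_em()].
#' @param h,kernel Passed to [kde()].
#' @param n_grid Number of evaluation points.
#' @return Data frame with columns `score`, `mixture`, `kde`.
#' @export
density_overlay <- function(fit, h = "auto", kernel = "gaussian",
                            n_grid = 256L) {
  stopifnot(inherits(fit, "ident_fit"))
  s <- fit$observed$score[fit$observed$z == 1L]
  grid <- seq(max(0, min(s) - 5), min(90, max(s) + 5), length.out = n_grid)
  k <- kde(s, h = h, kernel = kernel, grid = grid)
  data.frame(score = grid,
             mixture = matched_score_density(grid, fit$theta),
             kde = k$y)
}
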
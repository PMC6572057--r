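#' Parameters of the hierarchical identification model
#'
#' The identification model has four layers per library metabolite j:
#' presence `Y ~ Bernoulli(rho)`; matching `Z | Y = y ~ Bernoulli(gamma_y)`;
#' correctness `W | Y = 1, Z = 1 ~ Bernoulli(tau)` with `W` identically 0
#' when `Y = 0, Z = 1` (a match to an absent metabolite cannot be correct)
#' and `W` undefined when `Z = 0`; and the matched dissimilarity score
#' `S | W = 1 ~ Normal(mu_T, sigma2_T)` for correct matches versus a one- or
#' two-component normal mixture for incorrect matches (`W = 0` or `Y = 0`).
#' Correct matches score lower (more similar), so `mu_T` below every
#' false-component mean is enforced as an identifiability constraint.
#'
#' @param rho Prior presence probability P(Y=1), in (0,1).
#' @param tau Correct-match probability P(W=1 | Y=1, Z=1), in (0,1).
#' @param gamma1 Match probability for present metabolites P(Z=1 | Y=1).
#' @param gamma0 Match probability for absent metabolites P(Z=1 | Y=0).
#' @param mu_T,sigma2_T Mean (degrees) and variance (degrees squared) of the
#'   correct-match score component.
#' @param false_weights,false_means,false_vars Mixing weights (summing to 1),
#'   means and variances of the 1 or 2 incorrect-match score components.
#' @return An object of class `ident_params` (a validated list).
#' @export
ident_params <- function(rho, tau, gamma1, gamma0, mu_T, sigma2_T,
                         false_weights = 1, false_means, false_vars) {
  theta <- structure(
    list(rho = rho, tau = tau, gamma1 = gamma1, gamma0 = gamma0,
         mu_T = mu_T, sigma2_T = sigma2_T,
         false_weights = as.numeric(false_weights),
         false_means = as.numeric(false_means),
         false_vars = as.numeric(false_vars)),
    class = "ident_params")
  validate_ident_params(theta)
  theta
}

validate_ident_params <- function(theta) {
  with(theta, {
    probs <- c(rho = rho, tau = tau, gamma1 = gamma1, gamma0 = gamma0)
    if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
      stop("ident_params: probabilities out of [0,1]: ",
           paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
    if (rho <= 0 || rho >= 1) stop("ident_params: rho must be in (0,1)")
    if (tau <= 0 || tau >= 1) stop("ident_params: tau must be in (0,1)")
    if (gamma1 <= 0) stop("ident_params: gamma1 must be in (0,1]")
    if (gamma0 >= 1) stop("ident_params: gamma0 must be in [0,1)")
    K <- length(false_weights)
    if (!K %in% c(1L, 2L) || length(false_means) != K || length(false_vars) != K)
      stop("ident_params: 1 or 2 false components with matching weights/means/vars required")
    if (abs(sum(false_weights) - 1) > 1e-8)
      stop("ident_params: false-component weights must sum to 1")
    if (any(false_weights <= 0)) stop("ident_params: false weights must be positive")
    if (sigma2_T <= 0 || any(false_vars <= 0))
      stop("ident_params: variances must be positive")
    if (mu_T >= min(false_means))
      stop("ident_params: mu_T must lie below every false-component mean ",
           "(correct matches are more similar)")
  })
  invisible(theta)
}

#' @export
print.ident_params <- function(x, ...) {
  cat("<ident_params>\n")
  cat(sprintf("  rho = %.4f  tau = %.4f  gamma1 = %.4f  gamma0 = %.4f\n",
              x$rho, x$tau, x$gamma1, x$gamma0))
  cat(sprintf("  correct component: N(%.3f, %.3f)\n", x$mu_T, x$sigma2_T))
  for (k in seq_along(x$false_weights))
    cat(sprintf("  false component %d: weight %.3f, N(%.3f, %.3f)\n",
                k, x$false_weights[k], x$false_means[k], x$false_vars[k]))
  invisible(x)
}

# density of the incorrect-match score mixture
false_density <- function(s, theta) {
  d <- 0
  for (k in seq_along(theta$false_weights))
    d <- d + theta$false_weights[k] *
      stats::dnorm(s, theta$false_means[k], sqrt(theta$false_vars[k]))
  d
}

# coerce accepted inputs (match_library()$matches or plain data.frame)
# to the canonical observed-data frame: name, z, score
as_observed <- function(observed) {
  if (is.list(observed) && !is.data.frame(observed) && !is.null(observed$matches))
    observed <- observed$matches
  if (!is.data.frame(observed) || is.null(observed$z))
    stop("observed data must be a data frame with a 'z' column (and 'score')")
  z <- as.integer(observed$z)
  if (any(!z %in% c(0L, 1L))) stop("observed 'z' must be 0/1")
  score <- if (!is.null(observed$score)) as.numeric(observed$score) else rep(NA_real_, length(z))
  if (any(z == 1L & !is.finite(score)))
    stop("matched records (z = 1) must carry a finite score")
  name <- if (!is.null(observed$name)) as.character(observed$name)
          else sprintf("lib%04d", seq_along(z))
  data.frame(name = name, z = z, score = score, stringsAsFactors = FALSE)
}

#' Complete-data log-likelihood of the identification model
#'
#' Evaluates the complete-data log-likelihood over fully specified latent
#' states, using the factorization
#' `[Y, Z, W, S] = [Y] [Z | Y] [W | Y, Z] [S | Y, Z, W]`. The score factor is
#' `Normal(mu_T, sigma2_T)` when `w = 1` and the false-component mixture when
#' `w = 0`; unmatched records (`z = 0`) contribute only the first two
#' factors. Impossible configurations (e.g. `w = 1` with `y = 0`) give
#' `-Inf`.
#'
#' @param states Data frame with columns `y`, `z`, `w` (NA when `z = 0`) and
#'   `s` (NA when `z = 0`).
#' @param theta An [ident_params()] object.
#' @return The scalar complete-data log-likelihood (may be `-Inf`).
#' @export
complete_loglik <- function(states, theta) {
  validate_ident_params(theta)
  stopifnot(is.data.frame(states), all(c("y", "z") %in% names(states)))
  y <- as.integer(states$y); z <- as.integer(states$z)
  w <- if (is.null(states$w)) rep(NA_integer_, length(y)) else as.integer(states$w)
  s <- if (is.null(states$s)) rep(NA_real_, length(y)) else as.numeric(states$s)
  ll <- 0
  for (i in seq_along(y)) {
    li <- log(ifelse(y[i] == 1L, theta$rho, 1 - theta$rho))
    gz <- if (y[i] == 1L) theta$gamma1 else theta$gamma0
    li <- li + log(ifelse(z[i] == 1L, gz, 1 - gz))
    if (z[i] == 1L) {
      if (is.na(w[i])) stop("complete_loglik: matched record ", i, " has undefined w")
      if (y[i] == 1L) {
        li <- li + log(ifelse(w[i] == 1L, theta$tau, 1 - theta$tau))
      } else if (w[i] == 1L) {
        li <- -Inf  # a match to an absent metabolite is never correct
      }
      if (is.finite(li)) {
        dens <- if (w[i] == 1L)
          stats::dnorm(s[i], theta$mu_T, sqrt(theta$sigma2_T))
        else false_density(s[i], theta)
        li <- li + log(dens)
      }
    }
    ll <- ll + li
  }
  ll
}

# column layout of the responsibility matrix for K false components:
# y1w1 | y1w0.1..K | y0w0.1..K | y1z0 | y0z0
resp_colnames <- function(K) {
  c("y1w1", paste0("y1w0.", seq_len(K)), paste0("y0w0.", seq_len(K)),
    "y1z0", "y0z0")
}

# per-record joint masses of every admissible (y, w, component) configuration
config_masses <- function(obs, theta) {
  n <- nrow(obs); K <- length(theta$false_weights)
  m <- matrix(0, nrow = n, ncol = 3L + 2L * K,
              dimnames = list(NULL, resp_colnames(K)))
  mi <- obs$z == 1L
  if (any(mi)) {
    s <- obs$score[mi]
    m[mi, "y1w1"] <- theta$rho * theta$gamma1 * theta$tau *
      stats::dnorm(s, theta$mu_T, sqrt(theta$sigma2_T))
    for (k in seq_len(K)) {
      fk <- theta$false_weights[k] *
        stats::dnorm(s, theta$false_means[k], sqrt(theta$false_vars[k]))
      m[mi, paste0("y1w0.", k)] <- theta$rho * theta$gamma1 * (1 - theta$tau) * fk
      m[mi, paste0("y0w0.", k)] <- (1 - theta$rho) * theta$gamma0 * fk
    }
  }
  if (any(!mi)) {
    m[!mi, "y1z0"] <- theta$rho * (1 - theta$gamma1)
    m[!mi, "y0z0"] <- (1 - theta$rho) * (1 - theta$gamma0)
  }
  m
}

#' E-step: posterior responsibilities over latent configurations
#'
#' For each library metabolite, computes the posterior probability of every
#' admissible latent configuration given its observed `(z, score)` pair and
#' the current parameters: for matched records the configurations are
#' `(y=1, w=1)`, `(y=1, w=0, component k)` and `(y=0, w=0, component k)`;
#' for unmatched records, `y = 1` and `y = 0`. Rows sum to 1.
#'
#' @param observed A data frame with columns `z` and `score` (the `matches`
#'   element of [match_library()] is accepted directly).
#' @param theta An [ident_params()] object.
#' @return A matrix of responsibilities, one row per metabolite, with an
#'   attribute `loglik` holding the observed-data log-likelihood at `theta`.
#' @export
e_step <- function(observed, theta) {
  validate_ident_params(theta)
  obs <- as_observed(observed)
  m <- config_masses(obs, theta)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("e_step: zero total posterior mass for record(s) ",
         paste(utils::head(which(tot <= 0), 5), collapse = ", "))
  r <- m / tot
  attr(r, "loglik") <- sum(log(tot))
  r
}

PROB_CLAMP <- 1e-6
VAR_FLOOR <- 1e-6

clamp_prob <- function(p) min(1 - PROB_CLAMP, max(PROB_CLAMP, p))

#' M-step: closed-form parameter updates
#'
#' Maximizes the EM target function (expected complete-data log-likelihood)
#' in closed form: weighted-proportion updates for `rho`, `tau`, `gamma1`,
#' `gamma0` and weighted mean/variance updates for the normal components.
#' Probabilities are clamped away from 0/1, variances floored, and the
#' ordering constraint `mu_T < min(false means)` restored by component
#' relabeling if an update violates it. Parameters named in `fixed` are held
#' at their supplied values (used when match rates are known by design; see
#' the methods vignette on identifiability).
#'
#' @param observed As in [e_step()].
#' @param responsibilities Matrix returned by [e_step()].
#' @param fixed Optional named list of parameters to hold fixed, e.g.
#'   `list(gamma1 = 0.9, gamma0 = 0.1)`.
#' @return An [ident_params()] object.
#' @export
m_step <- function(observed, responsibilities, fixed = list()) {
  obs <- as_observed(observed)
  r <- responsibilities
  K <- (ncol(r) - 3L) / 2L
  stopifnot(nrow(r) == nrow(obs), K %in% c(1, 2))
  y1cols <- c("y1w1", paste0("y1w0.", seq_len(K)), "y1z0")
  py1 <- rowSums(r[, y1cols, drop = FALSE])
  z <- obs$z
  upd <- list()
  upd$rho <- clamp_prob(mean(py1))
  upd$gamma1 <- clamp_prob(sum(py1 * z) / sum(py1))
  upd$gamma0 <- clamp_prob(sum((1 - py1) * z) / sum(1 - py1))
  mi <- z == 1L
  w1 <- r[mi, "y1w1"]
  w0 <- rowSums(r[mi, paste0("y1w0.", seq_len(K)), drop = FALSE])
  upd$tau <- clamp_prob(sum(w1) / sum(w1 + w0))
  s <- obs$score[mi]
  upd$mu_T <- sum(w1 * s) / sum(w1)
  upd$sigma2_T <- max(VAR_FLOOR, sum(w1 * (s - upd$mu_T)^2) / sum(w1))
  u <- r[mi, paste0("y1w0.", seq_len(K)), drop = FALSE] +
       r[mi, paste0("y0w0.", seq_len(K)), drop = FALSE]
  colw <- colSums(u)
  if (any(colw < 1e-8)) {
    warning("m_step: false component starved of weight; variance floored")
    colw <- pmax(colw, 1e-8)
  }
  upd$false_weights <- unname(colw / sum(colw))
  upd$false_means <- unname(colSums(u * s) / colw)
  upd$false_vars <- unname(pmax(VAR_FLOOR,
                                colSums(u * outer(s, upd$false_means, "-")^2) / colw))
  for (nm in names(fixed)) upd[[nm]] <- fixed[[nm]]
  # restore identifiability ordering by relabeling if violated
  if (upd$mu_T >= min(upd$false_means)) {
    k <- which.min(upd$false_means)
    tmp_m <- upd$false_means[k]; tmp_v <- upd$false_vars[k]
    upd$false_means[k] <- upd$mu_T; upd$false_vars[k] <- upd$sigma2_T
    upd$mu_T <- tmp_m; upd$sigma2_T <- tmp_v
    if (upd$mu_T >= min(upd$false_means))
      upd$false_means[k] <- upd$mu_T + abs(upd$mu_T) * 1e-3 + 1e-3
  }
  ident_params(upd$rho, upd$tau, upd$gamma1, upd$gamma0, upd$mu_T,
               upd$sigma2_T, upd$false_weights, upd$false_means,
               upd$false_vars)
}

# deterministic k-means-style initialization from matched scores
auto_init <- function(scores, K) {
  centers <- stats::quantile(scores, probs = seq(0.15, 0.85, length.out = K + 1L))
  centers <- matrix(sort(unique(jitter_centers(centers))), ncol = 1L)
  km <- stats::kmeans(matrix(scores, ncol = 1L), centers = centers)
  ord <- order(km$centers[, 1L])
  grp_stats <- lapply(ord, function(g) {
    x <- scores[km$cluster == g]
    list(n = length(x), mean = mean(x),
         var = max(VAR_FLOOR, stats::var(x) %||% VAR_FLOOR))
  })
  true_c <- grp_stats[[1L]]
  false_c <- grp_stats[-1L]
  wts <- vapply(false_c, function(g) g$n, numeric(1))
  means <- vapply(false_c, function(g) g$mean, numeric(1))
  vars <- vapply(false_c, function(g) if (is.na(g$var)) VAR_FLOOR else g$var, numeric(1))
  means[means <= true_c$mean] <- true_c$mean + 1e-3
  ident_params(rho = 0.5, tau = 0.5, gamma1 = 0.9, gamma0 = 0.1,
               mu_T = true_c$mean,
               sigma2_T = if (is.na(true_c$var)) VAR_FLOOR else true_c$var,
               false_weights = wts / sum(wts),
               false_means = means, false_vars = vars)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# nudge coincident quantile centers apart so kmeans accepts them
jitter_centers <- function(x) {
  x <- as.numeric(x)
  while (anyDuplicated(x)) x[duplicated(x)] <- x[duplicated(x)] + 1e-6
  x
}

#' Fit the identification model by EM
#'
#' Alternates [e_step()] and [m_step()] until the relative change in the
#' observed-data log-likelihood falls below `tol` or `max_iter` is reached.
#' The observed-data log-likelihood is non-decreasing across iterations (the
#' EM ascent property); the full per-iteration parameter trace is recorded
#' for convergence diagnostics.
#'
#' @inheritParams e_step
#' @param n_false_components 1 or 2 normal components for incorrect-match
#'   scores (2 or 3 mixture components overall including the correct one).
#' @param init An [ident_params()] starting point, or `"auto"` for a
#'   deterministic k-means-style split of the matched scores (component
#'   moments from the clusters; `rho`, `tau`, `gamma1`, `gamma0` start at
#'   0.5, 0.5, 0.9, 0.1).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param fixed Named list of parameters held fixed in every M-step (see
#'   [m_step()]).
#' @param seed Optional integer; accepted for interface uniformity. The
#'   default initialization is deterministic, so the fit does not depend on
#'   it.
#' @return An object of class `ident_fit`: list with elements `theta`
#'   ([ident_params()]), `trace` (data frame of per-iteration parameters and
#'   log-likelihood), `converged`, `n_iter`, `loglik`, and the observed data.
#' @export
fit_em <- function(observed, n_false_components = 1, init = "auto",
                   tol = 1e-8, max_iter = 1000, fixed = list(), seed = NULL) {
  obs <- as_observed(observed)
  K <- as.integer(n_false_components)
  if (!K %in% c(1L, 2L)) stop("fit_em: n_false_components must be 1 or 2")
  n_matched <- sum(obs$z == 1L)
  if (n_matched < 10L)
    stop("fit_em: only ", n_matched,
         " matched scores; the model is unidentifiable at this size (need >= 10)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  theta <- if (identical(init, "auto"))
    auto_init(obs$score[obs$z == 1L], K)
  else {
    validate_ident_params(init)
    init
  }
  for (nm in names(fixed)) theta[[nm]] <- fixed[[nm]]
  validate_ident_params(theta)

  trace <- vector("list", max_iter)
  ll_prev <- -Inf; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r <- e_step(obs, theta)
    ll <- attr(r, "loglik")
    trace[[it]] <- data.frame(
      iter = it, loglik = ll, rho = theta$rho, tau = theta$tau,
      gamma1 = theta$gamma1, gamma0 = theta$gamma0,
      mu_T = theta$mu_T, sigma2_T = theta$sigma2_T,
      t(stats::setNames(theta$false_weights, paste0("false_weight.", seq_len(K)))),
      t(stats::setNames(theta$false_means, paste0("false_mean.", seq_len(K)))),
      t(stats::setNames(theta$false_vars, paste0("false_var.", seq_len(K)))))
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + tol)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    theta <- m_step(obs, r, fixed = fixed)
  }
  trace <- do.call(rbind, trace[seq_len(it)])
  structure(list(theta = theta, trace = trace, converged = converged,
                 n_iter = it, loglik = trace$loglik[it], observed = obs),
            class = "ident_fit")
}

#' @export
print.ident_fit <- function(x, ...) {
  cat("<ident_fit> ", nrow(x$observed), " library metabolites (",
      sum(x$observed$z), " matched), ", x$n_iter, " EM iterations, ",
      if (x$converged) "converged" else "NOT converged",
      ", loglik = ", format(x$loglik), "\n", sep = "")
  print(x$theta)
  invisible(x)
}

#' Posterior confidence measure per library metabolite
#'
#' The confidence measure for library metabolite j is the posterior
#' probability that it is present in the sample given its match indicator
#' and (if matched) its dissimilarity score,
#' `P(Y_j = 1 | Z_j, S_j; theta)`. Unmatched metabolites use only the
#' presence and match-rate factors: their posterior is
#' `rho (1 - gamma1) / (rho (1 - gamma1) + (1 - rho)(1 - gamma0))`.
#'
#' @param observed As in [e_step()]; an `ident_fit` object is also accepted
#'   (its stored data and estimates are used).
#' @param theta An [ident_params()] object (ignored when `observed` is an
#'   `ident_fit`).
#' @return A data frame of class `confidence_table` with columns `name`,
#'   `posterior`, `z`, `score`, sorted by posterior descending (ties broken
#'   by name).
#' @export
confidence_measure <- function(observed, theta = NULL) {
  if (inherits(observed, "ident_fit")) {
    theta <- observed$theta
    observed <- observed$observed
  }
  if (is.null(theta)) stop("confidence_measure: theta required")
  validate_ident_params(theta)
  obs <- as_observed(observed)
  r <- e_step(obs, theta)
  K <- (ncol(r) - 3L) / 2L
  y1cols <- c("y1w1", paste0("y1w0.", seq_len(K)), "y1z0")
  posterior <- rowSums(r[, y1cols, drop = FALSE])
  out <- data.frame(name = obs$name, posterior = posterior, z = obs$z,
                    score = obs$score, stringsAsFactors = FALSE)
  out <- out[order(-out$posterior, out$name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("confidence_table", "data.frame")
  out
}

#' Marginal density of matched scores under the fitted model
#'
#' The model-implied density of a matched score (conditional on `Z = 1`) is
#' the mixture of the correct component and the false components with
#' weights proportional to `rho gamma1 tau` and
#' `rho gamma1 (1 - tau) + (1 - rho) gamma0`. Used for the density-overlay
#' diagnostic against a kernel density estimate of the observed matched
#' scores.
#'
#' @param grid Numeric vector of score values to evaluate at.
#' @param theta An [ident_params()] object.
#' @return Numeric vector of density values.
#' @export
matched_score_density <- function(grid, theta) {
  validate_ident_params(theta)
  a <- theta$rho * theta$gamma1 * theta$tau
  b <- theta$rho * theta$gamma1 * (1 - theta$tau) + (1 - theta$rho) * theta$gamma0
  (a * stats::dnorm(grid, theta$mu_T, sqrt(theta$sigma2_T)) +
     b * false_density(grid, theta)) / (a + b)
}
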
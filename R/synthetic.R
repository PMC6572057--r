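#' Simulate identification data from the hierarchical model
#'
#' Draws the full latent chain for each library metabolite — presence
#' `Y ~ Bern(rho)`, matching `Z | Y ~ Bern(gamma_Y)`, correctness
#' `W | Y=1, Z=1 ~ Bern(tau)` (`W = 0` when `Y = 0, Z = 1`), and the score
#' `S | W = 1 ~ N(mu_T, sigma2_T)` versus the false-component mixture for
#' incorrect matches — and returns both the observables and the hidden truth
#' for recovery experiments. The defaults are the reference study
#' conditions used throughout the package's simulation experiments.
#'
#' @param n_library Number of library metabolites (>= 10).
#' @param rho,tau,gamma1,gamma0,mu_T,sigma2_T,false_weights,false_means,false_vars
#'   Model parameters; see [ident_params()].
#' @param seed Integer seed (required; the draw is bit-reproducible).
#' @return A list with `observed` (data frame `name`, `z`, `score` as
#'   consumed by [fit_em()]), `truth` (data frame `name`, `y`, `z`, `w`,
#'   `s`), and `params` (the generating values as a plain list; boundary
#'   probabilities such as `rho = 1` are legal here even though the fitted
#'   model keeps them interior).
#' @export
simulate_identification <- function(n_library = 2000, rho = 0.7, tau = 0.8,
                                    gamma1 = 0.9, gamma0 = 0.1,
                                    mu_T = 5, sigma2_T = 4,
                                    false_weights = 1, false_means = 40,
                                    false_vars = 100, seed) {
  if (missing(seed) || is.null(seed))
    stop("simulate_identification: a seed is required")
  if (n_library < 10L) stop("simulate_identification: n_library must be >= 10")
  probs <- c(rho = rho, tau = tau, gamma1 = gamma1, gamma0 = gamma0)
  if (any(probs < 0 | probs > 1))
    stop("simulate_identification: probabilities out of [0, 1]")
  if (sigma2_T <= 0 || any(false_vars <= 0))
    stop("simulate_identification: variances must be positive")
  false_weights <- as.numeric(false_weights)
  if (abs(sum(false_weights) - 1) > 1e-8)
    stop("simulate_identification: false_weights must sum to 1")
  theta <- list(rho = rho, tau = tau, gamma1 = gamma1, gamma0 = gamma0,
                mu_T = mu_T, sigma2_T = sigma2_T,
                false_weights = false_weights,
                false_means = as.numeric(false_means),
                false_vars = as.numeric(false_vars))
  set.seed(as.integer(seed))
  n <- as.integer(n_library)
  y <- stats::rbinom(n, 1L, rho)
  z <- stats::rbinom(n, 1L, ifelse(y == 1L, gamma1, gamma0))
  w <- rep(NA_integer_, n)
  s <- rep(NA_real_, n)
  mi <- z == 1L
  w[mi] <- ifelse(y[mi] == 1L, stats::rbinom(sum(mi), 1L, tau), 0L)
  correct <- mi & w == 1L
  s[correct] <- stats::rnorm(sum(correct), mu_T, sqrt(sigma2_T))
  wrong <- mi & w == 0L
  if (any(wrong)) {
    comp <- sample.int(length(theta$false_weights), sum(wrong),
                       replace = TRUE, prob = theta$false_weights)
    s[wrong] <- stats::rnorm(sum(wrong), theta$false_means[comp],
                             sqrt(theta$false_vars[comp]))
  }
  name <- sprintf("M%04d", seq_len(n))
  list(observed = data.frame(name = name, z = z, score = s,
                             stringsAsFactors = FALSE),
       truth = data.frame(name = name, y = y, z = z, w = w, s = s,
                          stringsAsFactors = FALSE),
       params = theta)
}

# one random spectrum: distinct integer m/z positions, log-normal intensities
random_spectrum <- function(name, mz_range, n_peaks) {
  mz <- sort(sample(seq(mz_range[1L], mz_range[2L]), n_peaks))
  intensity <- stats::rlnorm(n_peaks, meanlog = log(1e4), sdlog = 1)
  mass_spectrum(name, mz, intensity)
}

perturb_spectrum <- function(spec, noise_sd) {
  if (noise_sd == 0) return(spec)
  mass_spectrum(spec$name, spec$mz,
                spec$intensity * exp(stats::rnorm(length(spec$mz), 0, noise_sd)))
}

#' Simulate paired sample/library spectral sets
#'
#' Builds an end-to-end fixture for the matching stage: `n_shared`
#' metabolites present in both tables (the sample copy carries
#' multiplicative log-normal intensity noise), plus metabolites exclusive to
#' one table. Peak positions are distinct integer m/z values drawn from
#' `mz_range`, so unrelated spectra are near-orthogonal by construction.
#'
#' @param n_shared,n_sample_only,n_library_only Metabolite counts (at least
#'   one shared).
#' @param mz_range Integer m/z range to draw peak positions from.
#' @param peaks_per_spectrum Number of peaks per spectrum.
#' @param noise_sd Standard deviation of the log-normal intensity noise on
#'   the sample copies (0 gives identical shared pairs, score exactly 0).
#' @param seed Integer seed (required).
#' @return A list with `sample` and `library` ([peak_table()]s) and `truth`
#'   (data frame `name`, `in_sample`, `in_library`).
#' @export
simulate_spectra <- function(n_shared = 20, n_sample_only = 5,
                             n_library_only = 5, mz_range = c(50, 500),
                             peaks_per_spectrum = 30, noise_sd = 0.1, seed) {
  if (missing(seed) || is.null(seed))
    stop("simulate_spectra: a seed is required")
  if (n_shared < 1L) stop("simulate_spectra: at least one shared metabolite required")
  set.seed(as.integer(seed))
  shared <- lapply(seq_len(n_shared), function(i)
    random_spectrum(sprintf("shared%03d", i), mz_range, peaks_per_spectrum))
  lib_only <- lapply(seq_len(n_library_only), function(i)
    random_spectrum(sprintf("libonly%03d", i), mz_range, peaks_per_spectrum))
  sam_only <- lapply(seq_len(n_sample_only), function(i)
    random_spectrum(sprintf("samonly%03d", i), mz_range, peaks_per_spectrum))
  library_tab <- peak_table(c(shared, lib_only))
  sample_tab <- peak_table(c(lapply(shared, perturb_spectrum, noise_sd = noise_sd),
                             sam_only))
  all_names <- c(vapply(shared, `[[`, "", "name"),
                 vapply(lib_only, `[[`, "", "name"),
                 vapply(sam_only, `[[`, "", "name"))
  truth <- data.frame(
    name = all_names,
    in_sample = all_names %in% peak_names(sample_tab),
    in_library = all_names %in% peak_names(library_tab),
    stringsAsFactors = FALSE)
  list(sample = sample_tab, library = library_tab, truth = truth)
}

#' Simulate a two-group intensity matrix with known differential status
#'
#' Generates the biomarker-discovery test bed: a `pi0` fraction of
#' metabolites are null (both groups share the same mean), the rest are
#' alternatives whose group-2 mean is shifted by `effect_size` within-group
#' standard deviations. Per-metabolite baselines are drawn log-uniform on
#' `[1e3, 1e6]` and per-metabolite variances log-uniform over a
#' `var_spread`-fold multiplicative range, populating the log-standard-error
#' axis of the fdr2d plane.
#'
#' @param n_metabolites Number of metabolites.
#' @param n1,n2 Subjects per group (>= 2 each).
#' @param pi0 Null fraction in (0, 1].
#' @param effect_size Mean shift for alternatives, in units of the
#'   metabolite's within-group SD.
#' @param var_spread Multiplicative range of per-metabolite variances
#'   (>= 1).
#' @param seed Integer seed (required).
#' @return A list with `matrix` (an [intensity_matrix()], groups `g1`/`g2`)
#'   and `truth` (data frame `metabolite`, `null` flag, `shift`, `sd`).
#' @export
simulate_matrix <- function(n_metabolites = 1000, n1 = 15, n2 = 15,
                            pi0 = 0.8, effect_size = 2, var_spread = 10,
                            seed) {
  if (missing(seed) || is.null(seed))
    stop("simulate_matrix: a seed is required")
  if (pi0 <= 0 || pi0 > 1) stop("simulate_matrix: pi0 must be in (0, 1]")
  if (n1 < 2L || n2 < 2L) stop("simulate_matrix: each group needs >= 2 subjects")
  if (var_spread < 1) stop("simulate_matrix: var_spread must be >= 1")
  set.seed(as.integer(seed))
  p <- as.integer(n_metabolites)
  baseline <- exp(stats::runif(p, log(1e3), log(1e6)))
  sigma <- sqrt(exp(stats::runif(p, 0, log(var_spread))))  # var in [1, var_spread]
  n_alt <- round((1 - pi0) * p)
  is_null <- rep(TRUE, p)
  if (n_alt > 0) is_null[sample.int(p, n_alt)] <- FALSE
  shift <- ifelse(is_null, 0, effect_size * sigma)
  vals <- matrix(stats::rnorm(p * (n1 + n2)), nrow = p) * sigma + baseline
  vals[, (n1 + 1L):(n1 + n2)] <- vals[, (n1 + 1L):(n1 + n2)] + shift
  mets <- sprintf("met%04d", seq_len(p))
  m <- intensity_matrix(vals, metabolite_names = mets,
                        subject_ids = sprintf("s%02d", seq_len(n1 + n2)),
                        group_labels = rep(c("g1", "g2"), c(n1, n2)))
  list(matrix = m,
       truth = data.frame(metabolite = mets, null = is_null, shift = shift,
                          sd = sigma, stringsAsFactors = FALSE))
}
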
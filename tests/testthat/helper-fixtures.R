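# shared fixtures and independent oracles used across test files

# independent arccos oracle for the cosine-angle score, written against the
# formula directly (crossprod / norms), separate from the package code path
oracle_angle <- function(a, b) {
  ca <- as.numeric(crossprod(a, b)) /
    (norm(matrix(a), "F") * norm(matrix(b), "F"))
  (180 / pi) * acos(pmin(1, pmax(-1, ca)))
}

# random mass spectrum on integer m/z positions
rand_spectrum <- function(name, n_peaks = 8, mz_range = c(50, 300)) {
  mass_spectrum(name,
                mz = sort(sample(seq(mz_range[1], mz_range[2]), n_peaks)),
                intensity = runif(n_peaks, 1, 100))
}

# tiny two-record MSP text (both pair dialects, one Area field)
msp_two_records <- function() {
  c("Name: alanine",
    "Area: 1234.5",
    "Num Peaks: 3",
    "70 999 116 250",
    "190 120",
    "",
    "Name: glycine",
    "Num Peaks: 2",
    "66:500; 174:80;",
    "")
}

write_tmp_msp <- function(lines) {
  f <- tempfile(fileext = ".msp")
  writeLines(lines, f)
  f
}

# default study-condition parameters of the identification simulator,
# used by the recovery and calibration experiments
ident_truth <- list(rho = 0.7, tau = 0.8, gamma1 = 0.9, gamma0 = 0.1,
                    mu_T = 5, sigma2_T = 4)

# fit with the match-rate parameters frozen at their known design values
# (they are confounded with rho/tau when all four are free; see vignette)
fit_frozen <- function(observed, ...) {
  fit_em(observed, fixed = list(gamma1 = ident_truth$gamma1,
                                gamma0 = ident_truth$gamma0), ...)
}

# small intensity matrix with explicit values and 2+2 groups
tiny_matrix <- function(values, n1 = 3, n2 = 3) {
  intensity_matrix(values, group_labels = rep(c("a", "b"), c(n1, n2)))
}
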
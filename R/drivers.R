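#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm pnorm pt qt rnorm rbinom runif rlnorm quantile
#'   median var sd IQR setNames approx binomial predict kmeans
#' @importFrom utils head combn read.table write.csv
NULL

# run a pipeline stage, prefixing any error with the stage name so CLI
# failures always say where they happened
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

write_manifest <- function(out_dir, command, params) {
  manifest <- list(
    tool = "metpipe",
    version = as.character(utils::packageVersion("metpipe")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    command = command,
    params = params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the identification workflow
#'
#' Reads sample and library MSP files, merges redundant peaks, matches every
#' sample spectrum to its nearest library spectrum by cosine-angle score,
#' fits the hierarchical identification model by EM and writes the
#' identification table (name, posterior confidence, matched flag, score),
#' the EM parameter trace, the candidate score table and the
#' mixture-vs-KDE density overlay to `out_dir`, together with a
#' machine-readable run manifest.
#'
#' @param sample_path,library_path MSP file paths.
#' @param out_dir Output directory (created if needed).
#' @param bin_width m/z bin width for [binned_vectors()].
#' @param n_false_components 1 or 2 false-score components.
#' @param tol,max_iter EM controls; see [fit_em()].
#' @param fixed Optional named list of fixed parameters; see [m_step()].
#' @param merge Merge redundant peaks before matching (default TRUE).
#' @return Invisibly, a list with the fit, the confidence table and the
#'   written file paths.
#' @export
run_identify <- function(sample_path, library_path, out_dir,
                         bin_width = 1, n_false_components = 1,
                         tol = 1e-8, max_iter = 1000, fixed = list(),
                         merge = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sample_pt <- stage("read sample", read_msp(sample_path))
  library_pt <- stage("read library", read_msp(library_path))
  if (merge) {
    sample_pt <- stage("merge sample peaks", merge_peaks(sample_pt))
    library_pt <- stage("merge library peaks", merge_peaks(library_pt))
  }
  ml <- stage("match library",
              match_library(sample_pt, library_pt, bin_width = bin_width))
  fit <- stage("fit EM", fit_em(ml$matches,
                                n_false_components = n_false_components,
                                tol = tol, max_iter = max_iter, fixed = fixed))
  conf <- stage("confidence measure", confidence_measure(fit))
  overlay <- stage("density overlay", density_overlay(fit))
  files <- c(
    identification = file.path(out_dir, "identification.csv"),
    em_trace = file.path(out_dir, "em_trace.csv"),
    scores = file.path(out_dir, "scores.csv"),
    density_overlay = file.path(out_dir, "density_overlay.csv"))
  stage("write outputs", {
    write_table(conf, files[["identification"]])
    write_table(fit$trace, files[["em_trace"]])
    write_table(ml$scores, files[["scores"]])
    write_table(overlay, files[["density_overlay"]])
  })
  write_manifest(out_dir, "identify",
                 list(sample = sample_path, library = library_path,
                      bin_width = bin_width,
                      n_false_components = n_false_components,
                      tol = tol, max_iter = max_iter, merge = merge,
                      converged = fit$converged, n_iter = fit$n_iter))
  invisible(list(fit = fit, confidence = conf, files = files))
}

#' Run the biomarker-discovery workflow
#'
#' Reads (or accepts) a metabolite-by-subject intensity matrix with
#' two-group labels, optionally normalizes it, computes Welch statistics,
#' builds the permutation null, estimates the fdr2d surface, rejects at the
#' requested isoline levels and writes the per-metabolite results table,
#' the gridded surface, the isoline polylines, volcano/tornado plot PDFs
#' and a run manifest to `out_dir`. All outputs are deterministic given the
#' seed.
#'
#' @param matrix_path Path to the matrix file, or an [intensity_matrix()].
#' @param groups Group-label file path or spec string (ignored when
#'   `matrix_path` is already an [intensity_matrix()]); see
#'   [read_intensity_matrix()].
#' @param out_dir Output directory.
#' @param np Number of permutations.
#' @param levels Nominal fdr2d rejection levels.
#' @param seed Integer seed (required).
#' @param smoothing_df Spline df for [estimate_r()].
#' @param grid_n Grid cells per axis.
#' @param log_transform,scale_columns,center_rows,pseudocount Normalization
#'   switches; see [normalize_matrix()].
#' @param figures Render volcano/tornado PDFs (default TRUE).
#' @return Invisibly, a list with the statistics, surface, rejection sets
#'   and written file paths.
#' @export
run_discover <- function(matrix_path, groups = NULL, out_dir, np = 100,
                         levels = c(0.05, 0.1, 0.2, 0.3), seed,
                         smoothing_df = 8, grid_n = c(50, 50),
                         log_transform = FALSE, scale_columns = FALSE,
                         center_rows = FALSE, pseudocount = 1,
                         figures = TRUE) {
  if (missing(seed) || is.null(seed)) stop("run_discover: a seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- if (inherits(matrix_path, "intensity_matrix")) matrix_path
       else stage("read matrix", read_intensity_matrix(matrix_path, groups))
  if (log_transform || scale_columns || center_rows)
    m <- stage("normalize", normalize_matrix(
      m, log_transform = log_transform, scale_columns = scale_columns,
      center_rows = center_rows, pseudocount = pseudocount))
  obs <- stage("two-sample statistics", two_sample_stats(m))
  perm <- stage("permutation null", permutation_null(m, np = np, seed = seed))
  surface <- stage("estimate r", estimate_r(obs, perm,
                                            grid = fdr_grid(obs, perm, n = grid_n),
                                            smoothing_df = smoothing_df))
  pi0 <- stage("estimate pi0", estimate_pi0(obs, perm))
  surface <- stage("fdr2d surface", fdr2d_surface(surface, pi0))
  sets <- stage("rejection", fdr_reject(obs, surface, levels))
  fdr <- attr(sets, "fdr2d")
  results <- obs
  results$fdr2d <- fdr
  for (s in sets)
    results[[sprintf("rejected_%g", s$level)]] <- fdr <= s$level
  surf_tab <- data.frame(
    z1 = rep(surface$z1, times = length(surface$z2)),
    z2 = rep(surface$z2, each = length(surface$z1)),
    r = as.vector(surface$r), fdr2d = as.vector(surface$fdr),
    count_observed = as.vector(surface$counts_observed),
    count_permuted = as.vector(surface$counts_permuted))
  volcano <- stage("plot data", plot_data(obs, surface, levels, "volcano"))
  tornado <- stage("plot data", plot_data(obs, surface, levels, "tornado"))
  files <- c(results = file.path(out_dir, "results.csv"),
             surface = file.path(out_dir, "surface.csv"),
             isolines = file.path(out_dir, "isolines.csv"))
  stage("write outputs", {
    write_table(results, files[["results"]])
    write_table(surf_tab, files[["surface"]])
    pieces <- Filter(function(d) nrow(d) > 0,
                     list(volcano$isolines, tornado$isolines))
    modes <- c("volcano", "tornado")[c(nrow(volcano$isolines) > 0,
                                       nrow(tornado$isolines) > 0)]
    iso <- if (length(pieces))
      do.call(rbind, Map(function(mode, d) cbind(mode = mode, d),
                         modes, pieces))
    else
      data.frame(mode = "none", level = NA_real_, piece = NA_integer_,
                 x = NA_real_, y = NA_real_)
    write_table(iso, files[["isolines"]])
  })
  if (figures) {
    for (mode in c("volcano", "tornado")) {
      f <- file.path(out_dir, paste0(mode, ".pdf"))
      grDevices::pdf(f, width = 6, height = 5)
      plot_fdr2d(obs, surface, levels, mode)
      grDevices::dev.off()
      files[[mode]] <- f
    }
  }
  write_manifest(out_dir, "discover",
                 list(np = np, levels = levels, seed = seed,
                      smoothing_df = smoothing_df, grid_n = grid_n,
                      pi0 = pi0,
                      log_transform = log_transform,
                      scale_columns = scale_columns,
                      center_rows = center_rows,
                      n_metabolites = nrow(m$values),
                      n_subjects = ncol(m$values)))
  invisible(list(stats = obs, surface = surface, rejections = sets,
                 pi0 = pi0, files = files))
}

#' Write simulated fixtures to disk
#'
#' Front end for the simulators: `"identify"` writes observed match results
#' plus the latent truth, `"spectra"` writes paired sample/library MSP files
#' plus a truth table, `"matrix"` writes an intensity matrix CSV, a group
#' label file and the differential-status truth.
#'
#' @param what One of `"identify"`, `"spectra"`, `"matrix"`.
#' @param out_dir Output directory.
#' @param seed Integer seed (required).
#' @param ... Passed to the corresponding `simulate_*()` function.
#' @return Invisibly, the simulator's return value.
#' @export
run_simulate <- function(what = c("identify", "spectra", "matrix"),
                         out_dir, seed, ...) {
  what <- match.arg(what)
  if (missing(seed) || is.null(seed)) stop("run_simulate: a seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(what,
    identify = {
      sim <- simulate_identification(seed = seed, ...)
      write_table(sim$observed, file.path(out_dir, "observed.csv"))
      write_table(sim$truth, file.path(out_dir, "truth.csv"))
      sim
    },
    spectra = {
      sim <- simulate_spectra(seed = seed, ...)
      write_msp(sim$sample, file.path(out_dir, "sample.msp"))
      write_msp(sim$library, file.path(out_dir, "library.msp"))
      write_table(sim$truth, file.path(out_dir, "truth.csv"))
      sim
    },
    matrix = {
      sim <- simulate_matrix(seed = seed, ...)
      tab <- data.frame(metabolite = rownames(sim$matrix$values),
                        sim$matrix$values, check.names = FALSE)
      write_table(tab, file.path(out_dir, "matrix.csv"))
      writeLines(c("group", as.character(sim$matrix$groups)),
                 file.path(out_dir, "groups.txt"))
      write_table(sim$truth, file.path(out_dir, "truth.csv"))
      sim
    })
  write_manifest(out_dir, paste0("simulate ", what),
                 c(list(seed = seed), list(...)))
  invisible(res)
}
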
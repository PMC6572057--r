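#' Reduce a spectrum to a scalar intensity
#'
#' For biomarker discovery each metabolite's spectrum is reduced to one
#' number per subject: the base peak chromatogram (`"bpc"`, the maximum
#' intensity) or the total ion chromatogram (`"tic"`, the summed intensity).
#'
#' @param spec A [mass_spectrum()].
#' @param mode `"bpc"` or `"tic"`.
#' @return A non-negative scalar.
#' @export
reduce_spectrum <- function(spec, mode = c("bpc", "tic")) {
  stopifnot(inherits(spec, "mass_spectrum"))
  mode <- match.arg(mode)
  switch(mode, bpc = max(spec$intensity), tic = sum(spec$intensity))
}

#' Construct a metabolite-by-subject intensity matrix
#'
#' The input for biomarker discovery: rows are metabolites, columns are
#' subjects, and every subject belongs to one of exactly two groups (e.g.
#' disease vs control), each with at least two subjects.
#'
#' @param values Numeric matrix (metabolites x subjects).
#' @param metabolite_names Row labels; defaults to existing rownames or
#'   `met1, met2, ...`.
#' @param subject_ids Column labels; defaults to existing colnames or
#'   `s1, s2, ...`.
#' @param group_labels Vector of length `ncol(values)` with exactly two
#'   distinct levels, each appearing at least twice.
#' @return An object of class `intensity_matrix`: list with `values`
#'   (labelled matrix), `groups` (factor) and `transform_log` (character
#'   record of applied transformations, initially empty).
#' @export
intensity_matrix <- function(values, metabolite_names = NULL,
                             subject_ids = NULL, group_labels) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("intensity_matrix: values must be numeric")
  if (is.null(metabolite_names))
    metabolite_names <- rownames(values) %||% paste0("met", seq_len(nrow(values)))
  if (is.null(subject_ids))
    subject_ids <- colnames(values) %||% paste0("s", seq_len(ncol(values)))
  if (length(metabolite_names) != nrow(values) ||
      length(subject_ids) != ncol(values))
    stop("intensity_matrix: label lengths do not match matrix dimensions")
  if (length(group_labels) != ncol(values))
    stop("intensity_matrix: one group label per subject required (got ",
         length(group_labels), " for ", ncol(values), " subjects)")
  groups <- factor(group_labels)
  if (nlevels(groups) != 2L)
    stop("intensity_matrix: exactly two group levels required, got ",
         nlevels(groups), " (", paste(levels(groups), collapse = ", "), ")")
  if (any(table(groups) < 2L))
    stop("intensity_matrix: each group needs at least 2 subjects")
  dimnames(values) <- list(metabolite_names, subject_ids)
  structure(list(values = values, groups = groups,
                 transform_log = character(0)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("<intensity_matrix> ", nrow(x$values), " metabolites x ",
      ncol(x$values), " subjects; groups: ",
      paste(sprintf("%s (n=%d)", levels(x$groups), table(x$groups)),
            collapse = ", "), "\n", sep = "")
  if (length(x$transform_log))
    cat("  transforms:", paste(x$transform_log, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Read an intensity matrix and group labels from files
#'
#' The matrix file is CSV or TSV with a header row of subject ids and the
#' first column holding metabolite names. Group labels come either from a
#' separate one-column file (one label per subject, in matrix column order,
#' with an optional header) or from a compact specification string of the
#' form `"A:s1,s2 B:s3,s4"` mapping levels to subject ids.
#'
#' @param matrix_path Path to the matrix file.
#' @param groups Path to a label file, or a specification string as above.
#' @param sep Field separator; inferred from the file extension by default.
#' @return An [intensity_matrix()].
#' @export
read_intensity_matrix <- function(matrix_path, groups, sep = NULL) {
  if (!file.exists(matrix_path))
    stop("read_intensity_matrix: file not found: ", matrix_path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", matrix_path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mets <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  subjects <- colnames(vals)
  labels <- parse_groups(groups, subjects)
  intensity_matrix(vals, metabolite_names = mets, subject_ids = subjects,
                   group_labels = labels)
}

parse_groups <- function(groups, subjects) {
  if (length(groups) == 1L && grepl(":", groups) && !file.exists(groups)) {
    # "A:s1,s2 B:s3,s4" form
    parts <- strsplit(trimws(groups), "\\s+")[[1L]]
    lab <- rep(NA_character_, length(subjects))
    for (p in parts) {
      kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("parse_groups: malformed group spec '", p, "'")
      ids <- strsplit(kv[2L], ",", fixed = TRUE)[[1L]]
      missing <- setdiff(ids, subjects)
      if (length(missing))
        stop("parse_groups: unknown subject id(s): ",
             paste(missing, collapse = ", "))
      lab[match(ids, subjects)] <- kv[1L]
    }
    if (anyNA(lab))
      stop("parse_groups: subjects without a group: ",
           paste(subjects[is.na(lab)], collapse = ", "))
    return(lab)
  }
  if (!file.exists(groups))
    stop("parse_groups: group file not found: ", groups)
  lab <- readLines(groups, warn = FALSE)
  lab <- trimws(lab[nzchar(trimws(lab))])
  if (length(lab) == length(subjects) + 1L) lab <- lab[-1L]  # header line
  if (length(lab) != length(subjects))
    stop("parse_groups: ", length(lab), " labels for ", length(subjects),
         " subjects")
  lab
}

#' Normalize an intensity matrix
#'
#' Applies, in this order: log transformation (`log(x + pseudocount)`),
#' column scaling to relative proportions (each subject column divided by
#' its sum, so columns sum to 1), and optional row centering. Every applied
#' step is appended to the object's `transform_log`. With all flags off the
#' input is returned unchanged.
#'
#' @param m An [intensity_matrix()].
#' @param log_transform Apply the log step.
#' @param scale_columns Scale each column to sum 1.
#' @param center_rows Subtract each row's mean (off by default).
#' @param pseudocount Added before the log; must be positive when zeros are
#'   present and the log step is requested.
#' @param base Logarithm base (natural log by default).
#' @return The transformed [intensity_matrix()].
#' @export
normalize_matrix <- function(m, log_transform = TRUE, scale_columns = TRUE,
                             center_rows = FALSE, pseudocount = 1,
                             base = exp(1)) {
  stopifnot(inherits(m, "intensity_matrix"))
  v <- m$values
  if (log_transform) {
    if (any(v < 0)) stop("normalize_matrix: negative values; cannot log-transform")
    if (pseudocount < 0) stop("normalize_matrix: pseudocount must be >= 0")
    if (pseudocount == 0 && any(v == 0)) {
      bad <- which(v == 0, arr.ind = TRUE)
      bad <- utils::head(bad, 5L)
      stop("normalize_matrix: zero cells with log and pseudocount 0, e.g. ",
           paste(sprintf("[%s, %s]", rownames(v)[bad[, 1L]],
                         colnames(v)[bad[, 2L]]), collapse = ", "))
    }
    v <- log(v + pseudocount, base = base)
    m$transform_log <- c(m$transform_log,
                         sprintf("log(x + %g, base = %g)", pseudocount, base))
  }
  if (scale_columns) {
    cs <- colSums(v)
    if (any(cs == 0)) stop("normalize_matrix: column(s) sum to zero; cannot scale")
    v <- sweep(v, 2L, cs, "/")
    m$transform_log <- c(m$transform_log, "scale columns to sum 1")
  }
  if (center_rows) {
    v <- sweep(v, 1L, rowMeans(v), "-")
    m$transform_log <- c(m$transform_log, "center rows")
  }
  m$values <- v
  m
}
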
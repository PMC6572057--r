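#' Construct a mass spectrum
#'
#' A mass spectrum is a named vector of fragment intensities on an m/z axis.
#' Peaks are stored sorted by ascending m/z; duplicate m/z values are combined
#' by summing their intensities.
#'
#' @param name Metabolite label (single string).
#' @param mz Numeric vector of positive m/z values.
#' @param intensity Numeric vector of non-negative abundances, same length as
#'   `mz`. At least one intensity must be positive.
#' @param area Optional non-negative scalar peak area. When `NULL` the total
#'   ion count (sum of intensities) is used wherever an area is required.
#' @return An object of class `mass_spectrum`: a list with elements `name`,
#'   `mz`, `intensity` and `area` (possibly `NA`).
#' @examples
#' s <- mass_spectrum("alanine", c(70, 116, 190), c(999, 250, 120))
#' s$area  # defaults to the total ion count
#' @export
mass_spectrum <- function(name, mz, intensity, area = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mass_spectrum '", name, "': mz and intensity lengths differ (",
         length(mz), " vs ", length(intensity), ")")
  if (length(mz) == 0L)
    stop("mass_spectrum '", name, "': empty peak list")
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("mass_spectrum '", name, "': m/z values must be finite and positive")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("mass_spectrum '", name, "': intensities must be finite and non-negative")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  }
  if (!any(intensity > 0))
    stop("mass_spectrum '", name, "': all intensities are zero")
  if (is.null(area)) area <- NA_real_
  area <- as.numeric(area)
  if (!is.na(area) && area < 0)
    stop("mass_spectrum '", name, "': area must be non-negative")
  structure(list(name = name, mz = mz, intensity = intensity, area = area),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("<mass_spectrum> ", x$name, ": ", length(x$mz), " peaks, m/z ",
      min(x$mz), "-", max(x$mz),
      if (!is.na(x$area)) paste0(", area ", signif(x$area, 6)), "\n", sep = "")
  invisible(x)
}

spectrum_area <- function(spec) {
  if (is.na(spec$area)) sum(spec$intensity) else spec$area
}

#' Construct a peak table
#'
#' A peak table is an ordered collection of mass spectra, possibly with
#' repeated metabolite names (e.g., multiple detected peaks of one compound
#' prior to merging).
#'
#' @param records List of [mass_spectrum()] objects; must be non-empty.
#' @return An object of class `peak_table` (a list of spectra).
#' @export
peak_table <- function(records) {
  if (!is.list(records) || length(records) == 0L)
    stop("peak_table: 'records' must be a non-empty list of mass spectra")
  ok <- vapply(records, inherits, logical(1), what = "mass_spectrum")
  if (!all(ok))
    stop("peak_table: records ", paste(which(!ok), collapse = ", "),
         " are not mass_spectrum objects")
  structure(unname(records), class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  nm <- peak_names(x)
  cat("<peak_table> ", length(x), " spectra (", length(unique(casefold_name(nm))),
      " distinct names)\n", sep = "")
  invisible(x)
}

#' @export
length.peak_table <- function(x) length(unclass(x))

#' Metabolite names of a peak table
#' @param peaks A [peak_table()].
#' @return Character vector of record names, in table order.
#' @export
peak_names <- function(peaks) {
  vapply(unclass(peaks), function(s) s$name, character(1))
}

# canonical key for name-based merging: trimmed, case-folded
casefold_name <- function(x) tolower(trimws(x))

#' Read an MSP-format spectral library
#'
#' Parses the NIST-style MSP text dialect: records separated by blank lines,
#' each starting with a `Name:` line, optionally carrying `Num Peaks:` and
#' `Area:` fields, followed by peak lines. Both common pair syntaxes are
#' accepted: whitespace-separated `mz intensity` pairs (several per line) and
#' the `mz:intensity;` form. Other `Key: value` header lines are ignored.
#'
#' When a record has no `Area:` field its area defaults to the total ion
#' count (sum of intensities); a single warning reports how many records were
#' affected.
#'
#' @param path Path to an MSP text file.
#' @return A [peak_table()] with one [mass_spectrum()] per record, peaks
#'   sorted by ascending m/z.
#' @seealso [write_msp()], [merge_peaks()]
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("read_msp: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blank <- grepl("^\\s*$", lines)
  if (all(blank)) stop("read_msp: no records in ", path)
  # group contiguous non-blank runs into records
  rec_id <- cumsum(blank)
  groups <- split(seq_along(lines)[!blank], rec_id[!blank])
  records <- vector("list", length(groups))
  n_missing_area <- 0L
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    rec_lines <- lines[idx]
    name <- NULL; num_peaks <- NA_integer_; area <- NULL
    mz <- numeric(0); intensity <- numeric(0)
    for (k in seq_along(rec_lines)) {
      ln <- trimws(rec_lines[k])
      if (grepl("^[0-9.]", ln)) {
        tok <- strsplit(gsub("[;:,]", " ", ln), "\\s+")[[1]]
        tok <- tok[nzchar(tok)]
        vals <- suppressWarnings(as.numeric(tok))
        if (anyNA(vals) || length(vals) %% 2L != 0L)
          stop("read_msp: record ", g, ", line ", idx[k],
               ": malformed peak line '", rec_lines[k], "'")
        sel <- seq(1L, length(vals), by = 2L)
        mz <- c(mz, vals[sel]); intensity <- c(intensity, vals[sel + 1L])
      } else if (grepl("^[A-Za-z][^:]*:", ln)) {
        key <- tolower(trimws(sub(":.*$", "", ln)))
        val <- trimws(sub("^[^:]*:", "", ln))
        if (key == "name") name <- val
        else if (key == "num peaks") num_peaks <- as.integer(val)
        else if (key == "area") area <- as.numeric(val)
        # other metadata keys are ignored
      } else {
        stop("read_msp: record ", g, ", line ", idx[k],
             ": unrecognized line '", rec_lines[k], "'")
      }
    }
    if (is.null(name))
      stop("read_msp: record ", g, " (starting line ", idx[1],
           "): missing 'Name:' field")
    if (!is.na(num_peaks) && num_peaks != length(mz))
      stop("read_msp: record ", g, " ('", name, "', starting line ", idx[1],
           "): Num Peaks declares ", num_peaks, " but ", length(mz),
           " pairs were read")
    if (is.null(area)) n_missing_area <- n_missing_area + 1L
    records[[g]] <- mass_spectrum(name, mz, intensity, area = area)
  }
  if (n_missing_area > 0L)
    warning("read_msp: ", n_missing_area, " record(s) without an Area field; ",
            "using total ion count as area")
  # fill TIC areas so downstream merging always has a defined area
  records <- lapply(records, function(s) {
    if (is.na(s$area)) s$area <- sum(s$intensity)
    s
  })
  peak_table(records)
}

#' Write spectra to an MSP file
#'
#' Inverse of [read_msp()]: writes `Name:`, `Area:`, `Num Peaks:` and one
#' `mz intensity` pair per line, records separated by a blank line. Numbers
#' are written with full precision so a read/write cycle round-trips up to
#' float formatting.
#'
#' @param peaks A [peak_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_msp <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (s in unclass(peaks)) {
    writeLines(paste0("Name: ", s$name), con)
    if (!is.na(s$area))
      writeLines(paste0("Area: ", format(s$area, digits = 17)), con)
    writeLines(paste0("Num Peaks: ", length(s$mz)), con)
    writeLines(paste(format(s$mz, digits = 17, trim = TRUE),
                     format(s$intensity, digits = 17, trim = TRUE)), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Merge redundant peaks by metabolite identity
#'
#' Detected peak lists often carry several entries for one metabolite. For
#' each distinct name (compared after whitespace trimming and case folding)
#' the single record with the largest peak area is kept. Ties on area keep
#' the first occurrence. The relative input order of the surviving names is
#' preserved. The operation is idempotent.
#'
#' @param peaks A [peak_table()]; every record must have a defined area (as
#'   produced by [read_msp()], which falls back to the total ion count).
#' @return A [peak_table()] with exactly one record per distinct name.
#' @examples
#' pt <- peak_table(list(
#'   mass_spectrum("A", 1:3, c(1, 2, 3), area = 5),
#'   mass_spectrum("A", 1:3, c(2, 2, 2), area = 9),
#'   mass_spectrum("B", 2:4, c(1, 1, 1), area = 2)))
#' merged <- merge_peaks(pt)
#' peak_names(merged)  # "A" (area 9 survivor), "B"
#' @export
merge_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_table"))
  recs <- unclass(peaks)
  areas <- vapply(recs, function(s) {
    if (is.na(s$area)) {
      if (length(s$intensity) == 0L)
        stop("merge_peaks: record '", s$name,
             "' has no area and no intensities to fall back on")
      sum(s$intensity)
    } else s$area
  }, numeric(1))
  key <- casefold_name(vapply(recs, function(s) s$name, character(1)))
  keep <- integer(0)
  for (k in unique(key)) {  # unique() preserves first-occurrence order
    idx <- which(key == k)
    # stable max: first index attaining the maximal area
    keep <- c(keep, idx[which.max(areas[idx])])
  }
  peak_table(recs[keep])
}

#' Write a result table as CSV
#'
#' Writes any non-empty data frame as a UTF-8 CSV with a header row, without
#' row names, so that it round-trips through [utils::read.csv()].
#'
#' @param rows A non-empty data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("write_table: 'rows' must be a non-empty data frame")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}
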
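#' Project two spectra onto a common binned m/z axis
#'
#' Before an inner product can be taken, two spectra must live on the same
#' coordinate system. Peaks are assigned to m/z bins of width `bin_width`
#' (bin k covers `[k*bin_width, (k+1)*bin_width)`); intensities falling in
#' the same bin are summed. Both spectra are then evaluated on the union of
#' occupied bins, index-aligned.
#'
#' @param a,b [mass_spectrum()] objects.
#' @param bin_width Positive bin width in m/z units; the default 1 m/z
#'   corresponds to nominal-mass binning.
#' @return A list with numeric vectors `a` and `b` of equal length and `bins`,
#'   the bin indices they are evaluated on. Disjoint m/z supports are legal
#'   and yield orthogonal vectors.
#' @export
binned_vectors <- function(a, b, bin_width = 1) {
  stopifnot(inherits(a, "mass_spectrum"), inherits(b, "mass_spectrum"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("binned_vectors: bin_width must be a positive scalar")
  bin_a <- floor(a$mz / bin_width)
  bin_b <- floor(b$mz / bin_width)
  bins <- sort(unique(c(bin_a, bin_b)))
  va <- vapply(bins, function(k) sum(a$intensity[bin_a == k]), numeric(1))
  vb <- vapply(bins, function(k) sum(b$intensity[bin_b == k]), numeric(1))
  list(a = va, b = vb, bins = bins)
}

#' Cosine-angle dissimilarity between two intensity vectors
#'
#' The dissimilarity score between two non-negative spectrum vectors is the
#' angle between them in degrees,
#' \deqn{s = \frac{180}{\pi}\arccos\frac{\langle a,b\rangle}{\|a\|\,\|b\|},}
#' which lies in \[0, 90\] for non-negative vectors: 0 means the spectra are
#' positive scalar multiples of each other (identical relative pattern) and
#' 90 means they share no fragments. Smaller scores mean higher similarity.
#'
#' @param a,b Non-negative numeric vectors of equal length, each with a
#'   positive norm.
#' @return The angle in degrees.
#' @examples
#' cosine_score(c(1, 1), c(1, 0))  # 45
#' @export
cosine_score <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("cosine_score: vectors differ in length")
  if (any(a < 0) || any(b < 0))
    stop("cosine_score: vectors must be non-negative")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stop("cosine_score: zero-norm vector; angle undefined")
  # numerically stable angle: 2 atan2(|x - y|, |x + y|) on the unit vectors
  # agrees with arccos(<a,b>/(|a||b|)) but is exact at 0 for identical input
  x <- a / na; y <- b / nb
  ang <- 2 * atan2(sqrt(sum((x - y)^2)), sqrt(sum((x + y)^2)))
  (180 / pi) * ang
}

# score one sample spectrum against one library spectrum on a shared binning
pair_score <- function(lib_spec, sam_spec, bin_width) {
  v <- binned_vectors(lib_spec, sam_spec, bin_width = bin_width)
  cosine_score(v$a, v$b)
}

#' Match sample spectra against a spectral library
#'
#' Every sample metabolite is matched to the library metabolite with the
#' smallest cosine-angle dissimilarity score (argmin over the whole library;
#' ties go to the lowest library index). Several sample metabolites may pick
#' the same library entry; that entry is then matched (`z = 1`) with retained
#' score equal to the minimal score among the sample spectra that selected
#' it. Library entries selected by no sample spectrum are unmatched
#' (`z = 0`). No score threshold is applied: a sample spectrum dissimilar to
#' everything is still assigned its argmin (possibly at 90 degrees); the
#' downstream identification model absorbs such matches as incorrect.
#'
#' @param sample,library [peak_table()] objects (both non-empty).
#' @param bin_width Bin width passed to [binned_vectors()].
#' @return A list with
#'   \describe{
#'     \item{matches}{data frame with one row per library entry:
#'       `library_index`, `name`, `z` (0/1 matched indicator),
#'       `sample_index` (NA when unmatched), `score` (NA when unmatched).}
#'     \item{scores}{long-format data frame of all candidate pair scores:
#'       `sample_index`, `sample_name`, `library_index`, `library_name`,
#'       `score` — kept for diagnostics.}
#'   }
#' @export
match_library <- function(sample, library, bin_width = 1) {
  stopifnot(inherits(sample, "peak_table"), inherits(library, "peak_table"))
  ns <- length(sample); nl <- length(library)
  lib_names <- peak_names(library); sam_names <- peak_names(sample)
  smat <- matrix(NA_real_, nrow = nl, ncol = ns)
  for (j in seq_len(nl)) {
    for (i in seq_len(ns)) {
      smat[j, i] <- tryCatch(
        pair_score(library[[j]], sample[[i]], bin_width),
        error = function(e) stop("match_library: scoring library '",
                                 lib_names[j], "' vs sample '", sam_names[i],
                                 "': ", conditionMessage(e)))
    }
  }
  # each sample spectrum selects its argmin library entry (lowest index wins)
  pick <- apply(smat, 2L, which.min)
  z <- integer(nl); best_score <- rep(NA_real_, nl); best_sample <- rep(NA_integer_, nl)
  for (i in seq_len(ns)) {
    j <- pick[i]
    s <- smat[j, i]
    if (z[j] == 0L || s < best_score[j]) {
      best_score[j] <- s
      best_sample[j] <- i
    }
    z[j] <- 1L
  }
  matches <- data.frame(
    library_index = seq_len(nl),
    name = lib_names,
    z = z,
    sample_index = best_sample,
    score = best_score,
    stringsAsFactors = FALSE
  )
  scores <- data.frame(
    sample_index = rep(seq_len(ns), each = nl),
    sample_name = rep(sam_names, each = nl),
    library_index = rep(seq_len(nl), times = ns),
    library_name = rep(lib_names, times = ns),
    score = as.vector(smat),
    stringsAsFactors = FALSE
  )
  list(matches = matches, scores = scores)
}
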
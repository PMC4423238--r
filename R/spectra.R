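#' sersga: GA band selection and LDA classification for serum SERS spectra
#'
#' Tools for two-class diagnostic analysis of surface-enhanced Raman spectra:
#' baseline correction, smoothing and area normalization; a segment-encoded
#' genetic algorithm maximizing LOOCV-LDA accuracy with consensus band
#' counting; LDA and PCA-LDA classifiers; ROC/AUC and band-level t-tests; and
#' a synthetic spectrum generator with planted class effects.
#'
#' @useDynLib sersga, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

CLASS_LEVELS <- c("normal", "cancer")

#' Default wavenumber grid
#'
#' Evenly spaced Raman-shift axis covering the fingerprint region measured at
#' roughly 1 cm^-1 resolution: 1270 points on 400-1800 cm^-1.
#'
#' @param lo,hi Range endpoints in cm^-1.
#' @param n_points Number of spectral variables.
#' @return Strictly increasing numeric vector of wavenumbers.
#' @export
default_grid <- function(lo = 400, hi = 1800, n_points = 1270) {
  stopifnot(is.numeric(lo), is.numeric(hi), hi > lo, n_points >= 2)
  seq(lo, hi, length.out = n_points)
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2) {
    stop("grid must be a numeric vector with at least 2 points", call. = FALSE)
  }
  if (anyNA(grid) || any(!is.finite(grid))) stop("grid contains non-finite values", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid wavenumbers must be strictly increasing", call. = FALSE)
  invisible(grid)
}

#' Construct a labelled set of spectra on a shared wavenumber grid
#'
#' The central container of the package: an `n_spectra x n_points` intensity
#' matrix, one class label and one sample id per row, and the common
#' wavenumber axis. Labels, when present, must come from the two diagnostic
#' classes `"normal"` and `"cancer"`; `"cancer"` is the positive class in all
#' downstream metrics.
#'
#' @param grid Strictly increasing numeric wavenumber vector (cm^-1).
#' @param spectra Numeric matrix, one spectrum per row, `ncol == length(grid)`.
#' @param labels Character/factor vector of per-row class labels, or `NULL`
#'   for unlabelled spectra.
#' @param ids Character vector of per-row sample identifiers (generated as
#'   `s1, s2, ...` when omitted).
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(grid, spectra, labels = NULL, ids = NULL) {
  check_grid(grid)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (ncol(spectra) != length(grid)) {
    stop(sprintf("spectra have %d columns but grid has %d points",
                 ncol(spectra), length(grid)), call. = FALSE)
  }
  if (anyNA(spectra) || any(!is.finite(spectra))) {
    bad <- which(!is.finite(spectra), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite intensity at row %d, column %d", bad[1], bad[2]),
         call. = FALSE)
  }
  n <- nrow(spectra)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids length must equal number of spectra", call. = FALSE)
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels length must equal number of spectra", call. = FALSE)
    bad <- setdiff(unique(labels), CLASS_LEVELS)
    if (length(bad)) {
      stop(sprintf("unknown label(s) %s; expected %s",
                   paste(sQuote(bad), collapse = ", "),
                   paste(sQuote(CLASS_LEVELS), collapse = ", ")), call. = FALSE)
    }
    labels <- factor(labels, levels = CLASS_LEVELS)
  }
  dimnames(spectra) <- NULL
  structure(list(grid = as.numeric(grid), spectra = spectra,
                 labels = labels, ids = ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d variables, %.6g-%.6g cm^-1\n",
              nrow(x$spectra), ncol(x$spectra), min(x$grid), max(x$grid)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else {
    cat("  labels: none\n")
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$spectra)

# subset rows, keeping grid
subset_rows <- function(set, i) {
  spectra_set(set$grid, set$spectra[i, , drop = FALSE],
              labels = if (is.null(set$labels)) NULL else as.character(set$labels[i]),
              ids = set$ids[i])
}

check_two_classes <- function(set, min_per_class = 2) {
  if (is.null(set$labels)) stop("spectra set has no class labels", call. = FALSE)
  tab <- table(set$labels)
  if (any(tab == 0)) {
    stop(sprintf("both classes must be present; missing %s",
                 sQuote(names(tab)[tab == 0][1])), call. = FALSE)
  }
  if (any(tab < min_per_class)) {
    lim <- names(tab)[which.min(tab)]
    stop(sprintf("class %s has %d sample(s); need at least %d",
                 sQuote(lim), min(tab), min_per_class), call. = FALSE)
  }
  invisible(set)
}

#' Partition the spectral axis into contiguous equal-length segments
#'
#' The genetic algorithm selects bands at the granularity of short contiguous
#' blocks of spectral variables ("segments"). For the default 1270-variable
#' grid and 5-variable segments this yields 254 segments.
#'
#' @param n_points Number of spectral variables; must be divisible by
#'   `seg_len`.
#' @param seg_len Number of contiguous variables per segment.
#' @param grid Optional wavenumber vector of length `n_points`; when supplied,
#'   each segment also carries its closed wavenumber interval.
#' @return A `segment_index`: data frame with one row per segment and columns
#'   `segment` (1-based id), `start`, `end` (1-based inclusive variable
#'   indices) and, with a grid, `wn_lo`, `wn_hi`.
#' @export
build_segment_index <- function(n_points, seg_len = 5, grid = NULL) {
  stopifnot(length(n_points) == 1, length(seg_len) == 1)
  n_points <- as.integer(n_points); seg_len <- as.integer(seg_len)
  if (n_points <= 0 || seg_len <= 0) stop("n_points and seg_len must be positive", call. = FALSE)
  if (n_points %% seg_len != 0) {
    stop(sprintf("n_points %d not divisible by seg_len %d", n_points, seg_len),
         call. = FALSE)
  }
  n_seg <- n_points %/% seg_len
  idx <- data.frame(segment = seq_len(n_seg),
                    start = (seq_len(n_seg) - 1L) * seg_len + 1L,
                    end = seq_len(n_seg) * seg_len)
  if (!is.null(grid)) {
    check_grid(grid)
    if (length(grid) != n_points) stop("grid length must equal n_points", call. = FALSE)
    idx$wn_lo <- grid[idx$start]
    idx$wn_hi <- grid[idx$end]
  }
  structure(idx, class = c("segment_index", "data.frame"),
            seg_len = seg_len, n_points = n_points, n_segments = n_seg)
}

n_segments <- function(idx) attr(idx, "n_segments")

#' Expand a chromosome to the spectral variable indices it selects
#'
#' @param chrom Integer vector of unique segment ids (a GA chromosome).
#' @param idx A `segment_index` from [build_segment_index()].
#' @return Sorted integer vector of 1-based variable indices, of length
#'   `length(chrom) * seg_len`.
#' @export
expand_chromosome <- function(chrom, idx) {
  chrom <- as.integer(chrom)
  if (anyDuplicated(chrom)) stop("chromosome segment ids must be unique", call. = FALSE)
  if (any(chrom < 1L) || any(chrom > n_segments(idx))) {
    stop(sprintf("segment id out of range 1..%d: %d", n_segments(idx),
                 chrom[which(chrom < 1L | chrom > n_segments(idx))[1]]), call. = FALSE)
  }
  sort(unlist(lapply(chrom, function(s) idx$start[s]:idx$end[s]), use.names = FALSE))
}

#' Locate the segment containing a wavenumber
#'
#' A wavenumber maps to the segment holding its nearest grid point, so every
#' value inside the grid range has a segment even though consecutive
#' segments' closed wavenumber intervals are separated by one grid spacing.
#'
#' @param wn Numeric vector of wavenumbers (cm^-1).
#' @param idx A `segment_index` built with a grid.
#' @param grid The wavenumber grid the index was built over.
#' @return Integer vector of segment ids (NA where outside the grid range).
#' @export
segment_of <- function(wn, idx, grid = NULL) {
  if (is.null(idx$wn_lo)) stop("segment index was built without a grid", call. = FALSE)
  if (is.null(grid)) {
    # reconstruct grid points only at segment boundaries is not enough for
    # nearest-point lookup; interpolate within the segment spans instead
    seg_len <- attr(idx, "seg_len")
    vapply(wn, function(w) {
      if (w < idx$wn_lo[1] || w > idx$wn_hi[nrow(idx)]) return(NA_integer_)
      inside <- which(idx$wn_lo <= w & w <= idx$wn_hi)
      if (length(inside)) return(inside[1])
      # in the gap between two segments: assign to the nearer boundary
      after <- which(idx$wn_hi < w)
      k <- after[length(after)]
      if ((w - idx$wn_hi[k]) <= (idx$wn_lo[k + 1] - w)) k else k + 1L
    }, integer(1))
  } else {
    check_grid(grid)
    if (length(grid) != attr(idx, "n_points")) {
      stop("grid length does not match the segment index", call. = FALSE)
    }
    vapply(wn, function(w) {
      if (w < grid[1] || w > grid[length(grid)]) return(NA_integer_)
      j <- which.min(abs(grid - w))
      which(idx$start <= j & j <= idx$end)
    }, integer(1))
  }
}
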
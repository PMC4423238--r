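#' Preprocessing configuration
#'
#' Parameters for the three-stage spectral cleanup: iterative fifth-order
#' polynomial autofluorescence baseline removal, Savitzky-Golay smoothing,
#' and normalization to unit area under the curve.
#'
#' @param poly_order Degree of the baseline polynomial.
#' @param max_iterations Cap on baseline peak-clipping iterations.
#' @param tol Convergence tolerance: maximum change of the working signal
#'   between iterations, relative to the input's intensity scale.
#' @param window Savitzky-Golay window length (odd, greater than `sg_order`).
#' @param sg_order Local polynomial order of the smoother.
#' @param normalize Normalization mode; only `"area"` (unit trapezoidal area).
#' @param normalize_before_smoothing Swap the last two stages (default order
#'   is baseline, smooth, normalize).
#' @return A validated `preprocess_config` list.
#' @export
preprocess_config <- function(poly_order = 5, max_iterations = 100, tol = 1e-6,
                              window = 5, sg_order = 3,
                              normalize = "area",
                              normalize_before_smoothing = FALSE) {
  cfg <- list(poly_order = as.integer(poly_order),
              max_iterations = as.integer(max_iterations), tol = tol,
              window = as.integer(window), sg_order = as.integer(sg_order),
              normalize = match.arg(normalize),
              normalize_before_smoothing = isTRUE(normalize_before_smoothing))
  if (cfg$poly_order < 1) stop("poly_order must be >= 1", call. = FALSE)
  if (cfg$max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (cfg$tol <= 0) stop("tol must be positive", call. = FALSE)
  if (cfg$window %% 2 == 0) stop(sprintf("smoothing window must be odd, got %d", cfg$window), call. = FALSE)
  if (cfg$window <= cfg$sg_order) {
    stop(sprintf("smoothing window (%d) must exceed the local polynomial order (%d)",
                 cfg$window, cfg$sg_order), call. = FALSE)
  }
  class(cfg) <- "preprocess_config"
  cfg
}

# Orthogonal polynomial basis (with intercept) on a scaled copy of the grid;
# QR once, projection reused across iterations.
baseline_projector <- function(grid, order) {
  u <- 2 * (grid - mean(range(grid))) / diff(range(grid))
  B <- cbind(1, stats::poly(u, degree = order))
  qr(B)
}

#' Fit the autofluorescence baseline of one spectrum
#'
#' Iterative modified polynomial fitting: a polynomial of `poly_order` is fit
#' to the working signal by least squares; every point above the fit is
#' clipped down to the fitted value; the fit is repeated on the clipped
#' signal. Peaks are progressively excluded while the smooth fluorescence
#' background is retained. Iteration stops when the working signal changes by
#' less than `tol` (relative to the input's intensity scale) or after
#' `max_iterations`, in which case the last iterate is returned with a
#' `converged = FALSE` attribute rather than an error.
#'
#' @param x Numeric intensity vector.
#' @param grid Matching wavenumber vector.
#' @param config A [preprocess_config()].
#' @return Numeric baseline vector (the final fitted polynomial on the grid)
#'   with attributes `iterations` and `converged`.
#' @export
fit_baseline <- function(x, grid, config = preprocess_config()) {
  check_grid(grid)
  x <- as.numeric(x)
  if (length(x) != length(grid)) stop("spectrum and grid lengths differ", call. = FALSE)
  if (any(!is.finite(x))) stop("spectrum contains non-finite intensities", call. = FALSE)
  if (length(x) <= config$poly_order + 1) {
    stop("grid length must exceed poly_order + 1", call. = FALSE)
  }
  qr_b <- baseline_projector(grid, config$poly_order)
  scale <- max(abs(x))
  if (scale == 0) {
    out <- numeric(length(x))
    attr(out, "iterations") <- 0L; attr(out, "converged") <- TRUE
    return(out)
  }
  working <- x
  fitted <- qr.fitted(qr_b, working)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    clipped <- pmin(working, fitted)
    delta <- max(abs(clipped - working)) / scale
    working <- clipped
    fitted <- qr.fitted(qr_b, working)
    if (delta < config$tol) { converged <- TRUE; break }
  }
  attr(fitted, "iterations") <- iter
  attr(fitted, "converged") <- converged
  fitted
}

#' Subtract a fitted baseline from a spectrum
#'
#' @param x Numeric intensity vector.
#' @param baseline Baseline of the same length (negatives in the result are
#'   permitted).
#' @return Numeric vector `x - baseline`.
#' @export
subtract_baseline <- function(x, baseline) {
  if (length(x) != length(baseline)) {
    stop(sprintf("spectrum length %d != baseline length %d",
                 length(x), length(baseline)), call. = FALSE)
  }
  as.numeric(x) - as.numeric(baseline)
}

#' Savitzky-Golay smoothing of one spectrum
#'
#' Local least-squares polynomial smoothing; any input that is globally a
#' polynomial of degree at most `sg_order` is reproduced exactly.
#'
#' @inheritParams fit_baseline
#' @return Smoothed numeric vector.
#' @export
smooth_spectrum <- function(x, config = preprocess_config()) {
  x <- as.numeric(x)
  if (config$window >= length(x)) {
    stop(sprintf("smoothing window %d must be smaller than the spectrum length %d",
                 config$window, length(x)), call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(x, p = config$sg_order, n = config$window))
}

#' Normalize a spectrum to unit area under the curve
#'
#' Divides by the trapezoidal integral of intensity over the wavenumber grid,
#' removing per-spectrum global intensity variability. Idempotent and
#' invariant to positive rescaling.
#'
#' @inheritParams fit_baseline
#' @param sample_id Identifier used in the error message when the area is not
#'   positive.
#' @return Numeric vector with trapezoidal area 1 over `grid`.
#' @export
area_normalize <- function(x, grid, sample_id = "<spectrum>") {
  check_grid(grid)
  x <- as.numeric(x)
  if (length(x) != length(grid)) stop("spectrum and grid lengths differ", call. = FALSE)
  area <- pracma::trapz(grid, x)
  if (!is.finite(area) || area <= 0) {
    stop(sprintf("sample %s: area under the curve is %.4g (must be > 0)",
                 sample_id, area), call. = FALSE)
  }
  x / area
}

#' Preprocess every spectrum of a set
#'
#' Applies, independently per row: baseline fit and subtraction, smoothing,
#' and area normalization (stage order switchable via the config). Row
#' order, labels and ids are unchanged.
#'
#' @param set A [spectra_set()].
#' @param config A [preprocess_config()].
#' @return A [spectra_set()] with attributes `baseline_iterations` and
#'   `baseline_converged` (per row).
#' @export
preprocess_set <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"))
  n <- nrow(set$spectra)
  out <- matrix(0, n, ncol(set$spectra))
  iters <- integer(n); conv <- logical(n)
  for (i in seq_len(n)) {
    xi <- set$spectra[i, ]
    res <- tryCatch({
      bl <- fit_baseline(xi, set$grid, config)
      iters[i] <- attr(bl, "iterations"); conv[i] <- attr(bl, "converged")
      y <- subtract_baseline(xi, bl)
      if (config$normalize_before_smoothing) {
        y <- area_normalize(y, set$grid, set$ids[i])
        smooth_spectrum(y, config)
      } else {
        y <- smooth_spectrum(y, config)
        area_normalize(y, set$grid, set$ids[i])
      }
    }, error = function(e) {
      stop(sprintf("sample %s: %s", set$ids[i], conditionMessage(e)), call. = FALSE)
    })
    out[i, ] <- res
  }
  res_set <- spectra_set(set$grid, out,
                         labels = if (is.null(set$labels)) NULL else as.character(set$labels),
                         ids = set$ids)
  attr(res_set, "baseline_iterations") <- iters
  attr(res_set, "baseline_converged") <- conv
  res_set
}
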
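# Deterministic substream derivation: stream k of master seed m gets its own
# 32-bit seed; depends only on (m, k) so adding later streams never perturbs
# earlier ones. Constants are the Knuth multiplicative-hash pair.
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(stream))
  (((master %% 2147483647) * 2654435761) %% 2147483647 + stream * 40503) %% 2147483647
}

#' Default peak table for synthetic serum-like SERS spectra
#'
#' Fifteen Lorentzian peaks at the Raman shifts typical of serum SERS spectra
#' (glycogen, aromatic amino acids, nucleic-acid and lipid modes). The five
#' strongest serum bands (481, 1135, 1219, 1445, 1585 cm^-1) get the larger
#' base amplitude. Eight peaks carry a class effect: amplitude is lower in the
#' cancer class at 481, 1219, 1445 and 1585 cm^-1 and higher at 683, 1025,
#' 1314 and 1640 cm^-1; the rest are class-neutral.
#'
#' @param effect_size Magnitude of the relative amplitude change in the cancer
#'   class at the eight diagnostic peaks.
#' @param width Lorentzian half-width at half-maximum, cm^-1.
#' @return Data frame with columns `center`, `width`, `amplitude`, `effect`.
#' @export
default_peaks <- function(effect_size = 0.15, width = 9) {
  centers <- c(481, 650, 683, 725, 830, 859, 915, 1025, 1135, 1219,
               1314, 1346, 1445, 1585, 1640)
  strong <- c(481, 1135, 1219, 1445, 1585)
  neg <- c(481, 1219, 1445, 1585)
  pos <- c(683, 1025, 1314, 1640)
  data.frame(
    center = centers,
    width = width,
    amplitude = ifelse(centers %in% strong, 1.0, 0.55),
    effect = ifelse(centers %in% neg, -effect_size,
                    ifelse(centers %in% pos, effect_size, 0))
  )
}

#' Configuration of the synthetic two-class SERS cohort
#'
#' Describes a study-like cohort: 36 normal and 55 cancer spectra on a
#' 1270-point 400-1800 cm^-1 grid, built as (per-spectrum positive
#' fifth-order polynomial fluorescence baseline) + (Lorentzian peaks with
#' class-dependent amplitudes) + (white noise), with a lognormal global
#' intensity scale per spectrum and per-peak amplitude jitter.
#'
#' @param n_normal,n_cancer Class sizes.
#' @param grid_lo,grid_hi,n_points Wavenumber grid parameters (cm^-1).
#' @param peaks Peak table as from [default_peaks()].
#' @param peak_jitter_sd SD of the per-spectrum, per-peak relative amplitude
#'   jitter (fraction).
#' @param baseline_coef_sd SD of the random baseline polynomial coefficients
#'   (orders 1-5, on a scaled axis).
#' @param baseline_offset_range Uniform range for the positive baseline
#'   offset (a.u.); the baseline is shifted to be strictly positive.
#' @param scale_sdlog SD of the lognormal per-spectrum global scale.
#' @param noise_sd SD of the additive white noise (a.u.).
#' @param seed Master RNG seed; every spectrum uses its own substream.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_normal = 36, n_cancer = 55,
                             grid_lo = 400, grid_hi = 1800, n_points = 1270,
                             peaks = default_peaks(),
                             peak_jitter_sd = 0.08,
                             baseline_coef_sd = 2,
                             baseline_offset_range = c(2, 6),
                             scale_sdlog = 0.2,
                             noise_sd = 0.06,
                             seed = 1) {
  cfg <- list(n_normal = as.integer(n_normal), n_cancer = as.integer(n_cancer),
              grid_lo = grid_lo, grid_hi = grid_hi, n_points = as.integer(n_points),
              peaks = as.data.frame(peaks), peak_jitter_sd = peak_jitter_sd,
              baseline_coef_sd = baseline_coef_sd,
              baseline_offset_range = as.numeric(baseline_offset_range),
              scale_sdlog = scale_sdlog, noise_sd = noise_sd, seed = seed)
  if (cfg$n_normal <= 0 || cfg$n_cancer <= 0) stop("class sizes must be positive", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$peak_jitter_sd < 0 || cfg$scale_sdlog < 0) {
    stop("noise/jitter/scale variability must be >= 0", call. = FALSE)
  }
  pk <- cfg$peaks
  need <- c("center", "width", "amplitude", "effect")
  if (!all(need %in% names(pk))) {
    stop("peaks must have columns center, width, amplitude, effect", call. = FALSE)
  }
  if (any(pk$width <= 0)) stop("peak widths must be positive", call. = FALSE)
  if (any(pk$amplitude < 0)) stop("peak amplitudes must be non-negative", call. = FALSE)
  if (any(abs(pk$effect) >= 1)) stop("|effect| must be < 1", call. = FALSE)
  if (length(cfg$baseline_offset_range) != 2 || any(cfg$baseline_offset_range <= 0) ||
      diff(cfg$baseline_offset_range) < 0) {
    stop("baseline_offset_range must be a positive increasing pair", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

config_grid <- function(config) {
  default_grid(config$grid_lo, config$grid_hi, config$n_points)
}

lorentzian <- function(wn, center, width) {
  width^2 / ((wn - center)^2 + width^2)
}

# One spectrum from substream `stream` of the config's master seed.
# Draw order (fixed; part of the reproducibility contract): global scale,
# 5 baseline coefficients, baseline offset, per-peak jitter, per-point noise.
#' Simulate one serum-like SERS spectrum
#'
#' @param config A [synthetic_config()].
#' @param label `"normal"` or `"cancer"`; cancer spectra have peak amplitudes
#'   scaled by `1 + effect`.
#' @param stream Substream index of the master seed (each spectrum of a
#'   dataset uses its row number).
#' @return Numeric intensity vector of length `config$n_points`, with
#'   attributes `scale` (the drawn global scale factor) and `baseline`.
#' @export
simulate_spectrum <- function(config, label = c("normal", "cancer"), stream = 0) {
  stopifnot(inherits(config, "synthetic_config"))
  label <- match.arg(label)
  wn <- config_grid(config)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(substream_seed(config$seed, stream))

  scale <- if (config$scale_sdlog > 0) stats::rlnorm(1, 0, config$scale_sdlog) else 1
  u <- 2 * (wn - mean(range(wn))) / diff(range(wn))  # scaled axis in [-1, 1]
  coefs <- stats::rnorm(5, 0, config$baseline_coef_sd)
  raw <- drop(outer(u, 1:5, `^`) %*% coefs)
  offset <- stats::runif(1, config$baseline_offset_range[1], config$baseline_offset_range[2])
  baseline <- raw - min(raw) + offset  # still a 5th-order polynomial; > 0 on grid

  pk <- config$peaks
  jitter <- if (config$peak_jitter_sd > 0) stats::rnorm(nrow(pk), 0, config$peak_jitter_sd) else rep(0, nrow(pk))
  eff <- 1 + pk$effect * (label == "cancer")
  amp <- pk$amplitude * scale * eff * (1 + jitter)
  if (any(amp < 0)) {
    stop(sprintf("negative peak amplitude drawn at %g cm^-1; reduce peak_jitter_sd",
                 pk$center[which(amp < 0)[1]]), call. = FALSE)
  }
  signal <- baseline
  for (p in seq_len(nrow(pk))) {
    signal <- signal + amp[p] * lorentzian(wn, pk$center[p], pk$width[p])
  }
  if (config$noise_sd > 0) signal <- signal + stats::rnorm(length(wn), 0, config$noise_sd)
  attr(signal, "scale") <- scale
  attr(signal, "baseline") <- baseline
  signal
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a two-class cohort of spectra
#'
#' Rows are the `n_normal` normal spectra followed by the `n_cancer` cancer
#' spectra; row `i` always uses substream `i` of the master seed, so the same
#' config reproduces the dataset bit-identically and enlarging the cohort
#' never changes earlier rows.
#'
#' @param config A [synthetic_config()].
#' @return A [spectra_set()] with attributes `truth` (the config) and
#'   `scale_factors` (per-row global scale draws).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  wn <- config_grid(config)
  labels <- c(rep("normal", config$n_normal), rep("cancer", config$n_cancer))
  n <- length(labels)
  mat <- matrix(0, n, length(wn))
  scales <- numeric(n)
  for (i in seq_len(n)) {
    s <- simulate_spectrum(config, labels[i], stream = i)
    mat[i, ] <- as.numeric(s)
    scales[i] <- attr(s, "scale")
  }
  ids <- c(paste0("norm", seq_len(config$n_normal)),
           paste0("canc", seq_len(config$n_cancer)))
  out <- spectra_set(wn, mat, labels = labels, ids = ids)
  attr(out, "scale_factors") <- scales
  attr(out, "truth") <- config
  out
}

#' Segments carrying a planted class effect
#'
#' Ground truth for band-recovery experiments: the ids of the segments whose
#' wavenumber interval contains the center of a peak with nonzero class
#' effect.
#'
#' @param config A [synthetic_config()].
#' @param idx Optional [build_segment_index()] consistent with the config grid
#'   (built from the config when omitted).
#' @return Sorted integer vector of segment ids.
#' @export
planted_truth <- function(config, idx = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(idx)) {
    idx <- build_segment_index(config$n_points, 5, grid = config_grid(config))
  }
  centers <- config$peaks$center[config$peaks$effect != 0]
  segs <- segment_of(centers, idx)
  if (anyNA(segs)) {
    stop("a planted peak center lies outside the segment index range", call. = FALSE)
  }
  sort(unique(segs))
}
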
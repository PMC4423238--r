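#' ROC curve and AUC from discriminant scores
#'
#' Thresholds sweep the distinct observed scores (plus sentinels); at each
#' threshold a sample is called positive (cancer) when its score is >= the
#' threshold. The AUC is the trapezoidal area under the resulting curve,
#' which equals the tie-corrected pair-counting probability that a random
#' cancer sample outscores a random normal sample (ties counted half).
#'
#' @param scores Numeric vector of per-sample scores (higher = more
#'   cancer-like), e.g. held-out LOOCV discriminant scores.
#' @param labels Matching class labels (`"normal"`/`"cancer"`).
#' @return A `roc_result` list: `thresholds` (decreasing, starting at `Inf`),
#'   `fpr`, `tpr` (both non-decreasing, from (0,0) to (1,1)), `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  if (anyNA(labels) || anyNA(scores)) stop("scores/labels contain NA", call. = FALSE)
  n_pos <- sum(labels == "cancer"); n_neg <- sum(labels == "normal")
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == "cancer") / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == "normal") / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d thresholds, AUC %.3f\n", length(x$thresholds), x$auc))
  invisible(x)
}

#' Two-sample t-test on a spectral band
#'
#' Each spectrum is summarized by its mean intensity over the band's
#' variables; the classes are compared with a classical pooled-variance
#' (Student) unpaired two-sided t-test. The reported sign is the sign of
#' `mean(cancer) - mean(normal)`.
#'
#' @param data Labelled [spectra_set()].
#' @param band Numeric length-2 wavenumber interval `c(lo, hi)` in cm^-1; it
#'   must overlap the grid.
#' @return List: `sign` (`"+"`, `"-"` or `"0"`), `mean_diff`, `t`, `df`, `p`.
#' @export
band_ttest <- function(data, band) {
  stopifnot(inherits(data, "spectra_set"), length(band) == 2)
  check_two_classes(data)
  band <- sort(as.numeric(band))
  vars <- which(data$grid >= band[1] & data$grid <= band[2])
  if (!length(vars)) {
    stop(sprintf("band [%g, %g] does not overlap the grid [%g, %g]",
                 band[1], band[2], min(data$grid), max(data$grid)), call. = FALSE)
  }
  intensity <- rowMeans(data$spectra[, vars, drop = FALSE])
  x_c <- intensity[data$labels == "cancer"]
  x_n <- intensity[data$labels == "normal"]
  tt <- tryCatch(stats::t.test(x_c, x_n, var.equal = TRUE),
                 error = function(e) {
                   stop(sprintf("band [%g, %g]: zero pooled variance, t-test undefined",
                                band[1], band[2]), call. = FALSE)
                 })
  md <- mean(x_c) - mean(x_n)
  list(sign = if (md > 0) "+" else if (md < 0) "-" else "0",
       mean_diff = md,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Band-wise t-test report
#'
#' Applies [band_ttest()] to each row of a band table (as returned by
#' [top_bands()]), producing the usual band / intensity-change-sign / p-value
#' summary.
#'
#' @param data Labelled [spectra_set()].
#' @param bands Data frame with `wn_lo` and `wn_hi` columns.
#' @return Data frame: `wn_lo`, `wn_hi`, `sign`, `t`, `p`.
#' @export
band_ttest_table <- function(data, bands) {
  stopifnot(all(c("wn_lo", "wn_hi") %in% names(bands)))
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    r <- band_ttest(data, c(bands$wn_lo[i], bands$wn_hi[i]))
    data.frame(wn_lo = bands$wn_lo[i], wn_hi = bands$wn_hi[i],
               sign = r$sign, t = r$t, p = r$p)
  })
  do.call(rbind, rows)
}

#' Mean difference spectrum (cancer - normal)
#'
#' @param data Labelled [spectra_set()].
#' @return Data frame with columns `wavenumber` and `difference`
#'   (pointwise `mean(cancer) - mean(normal)`).
#' @export
difference_spectrum <- function(data) {
  stopifnot(inherits(data, "spectra_set"))
  check_two_classes(data, min_per_class = 1)
  mc <- colMeans(data$spectra[data$labels == "cancer", , drop = FALSE])
  mn <- colMeans(data$spectra[data$labels == "normal", , drop = FALSE])
  data.frame(wavenumber = data$grid, difference = mc - mn)
}
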
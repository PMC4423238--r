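#' Fit a two-class Fisher linear discriminant
#'
#' The weight vector is `(Sw + lambda I)^-1 (mu_cancer - mu_normal)` where
#' `Sw` is the pooled within-class scatter matrix and
#' `lambda = ridge * trace(Sw) / p` is a small stabilizer; the decision
#' threshold is the midpoint of the projected class means (equal priors), and
#' the orientation is fixed so that the cancer class scores higher.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Class labels (`"normal"`/`"cancer"`), one per row; both classes
#'   need at least 2 samples.
#' @param ridge Relative ridge added to the scatter diagonal; `0` for the
#'   exact Fisher solution (errors on singular scatter).
#' @return An `lda_model`: list with `w`, `threshold`, `mu_normal`,
#'   `mu_cancer`, `ridge`.
#' @export
fit_lda <- function(X, y, ridge = 1e-8) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- factor(as.character(y), levels = CLASS_LEVELS)
  if (anyNA(y)) stop("labels must be 'normal' or 'cancer'", call. = FALSE)
  if (nrow(X) != length(y)) stop("X rows and label length differ", call. = FALSE)
  tab <- table(y)
  if (any(tab < 2)) {
    stop(sprintf("class %s has %d sample(s); need >= 2 per class",
                 sQuote(names(tab)[which.min(tab)]), min(tab)), call. = FALSE)
  }
  p <- ncol(X)
  if (p < 1) stop("need at least one variable", call. = FALSE)
  X0 <- X[y == "normal", , drop = FALSE]
  X1 <- X[y == "cancer", , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  C0 <- sweep(X0, 2, mu0); C1 <- sweep(X1, 2, mu1)
  Sw <- crossprod(C0) + crossprod(C1)
  if (ridge > 0) Sw <- Sw + diag(ridge * sum(diag(Sw)) / p, p)
  d <- mu1 - mu0
  w <- tryCatch(solve(Sw, d), error = function(e) {
    stop("singular within-class scatter matrix; refit with a positive ridge",
         call. = FALSE)
  })
  if (sum(w * d) < 0) w <- -w
  structure(list(w = as.numeric(w),
                 threshold = 0.5 * (sum(w * mu1) + sum(w * mu0)),
                 mu_normal = mu0, mu_cancer = mu1, ridge = ridge),
            class = "lda_model")
}

#' Score and classify spectra with a fitted discriminant
#'
#' @param object An `lda_model`.
#' @param newdata Numeric vector (one sample) or matrix (samples in rows)
#'   with as many variables as the model.
#' @param ... Unused.
#' @return Data frame with columns `score` (`w . x`) and `predicted`
#'   (`"cancer"` iff score strictly exceeds the threshold; a tie is called
#'   `"normal"`).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w)) {
    stop(sprintf("model has %d variables but newdata has %d",
                 length(object$w), ncol(newdata)), call. = FALSE)
  }
  score <- as.numeric(newdata %*% object$w)
  data.frame(score = score,
             predicted = factor(ifelse(score > object$threshold, "cancer", "normal"),
                                levels = CLASS_LEVELS))
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d variables, threshold %.4g, ridge %.3g\n",
              length(x$w), x$threshold, x$ridge))
  invisible(x)
}

as_Xy <- function(data, y = NULL) {
  if (inherits(data, "spectra_set")) {
    check_two_classes(data)
    list(X = data$spectra, y = data$labels, ids = data$ids)
  } else {
    X <- as.matrix(data)
    if (is.null(y)) stop("labels y required when data is a matrix", call. = FALSE)
    list(X = X, y = factor(as.character(y), levels = CLASS_LEVELS),
         ids = paste0("s", seq_len(nrow(X))))
  }
}

#' Leave-one-spectrum-out cross-validated LDA
#'
#' Each sample is scored by a discriminant trained on all other samples;
#' an optional variable subset is applied before every fold's fit. The fast
#' compiled path and the plain-R path (`engine = "r"`, one [fit_lda()] per
#' fold) compute the same folds and agree on predictions.
#'
#' @param data A labelled [spectra_set()] or a numeric matrix.
#' @param y Labels when `data` is a matrix.
#' @param variables Optional integer vector of column indices to restrict to.
#' @param ridge Relative ridge, as in [fit_lda()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @return A `cv_result` data frame: `id`, `label`, `score` (held-out
#'   discriminant score minus the fold threshold, so 0 is the decision line),
#'   `predicted`.
#' @export
loocv <- function(data, y = NULL, variables = NULL, ridge = 1e-8,
                  engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  d <- as_Xy(data, y)
  X <- d$X
  if (!is.null(variables)) X <- X[, variables, drop = FALSE]
  yf <- d$y
  if (anyNA(yf)) stop("labels must be 'normal' or 'cancer'", call. = FALSE)
  tab <- table(yf)
  if (any(tab < 3)) {
    lim <- names(tab)[which.min(tab)]
    stop(sprintf("class %s has %d samples; leave-one-out needs >= 3 so every fold keeps >= 2",
                 sQuote(lim), min(tab)), call. = FALSE)
  }
  n <- nrow(X)
  if (engine == "cpp") {
    sc <- .cpp_loocv_scores(X, as.integer(yf == "cancer"), ridge)
    score <- sc[, 1] - sc[, 2]
  } else {
    score <- numeric(n)
    for (i in seq_len(n)) {
      fit <- fit_lda(X[-i, , drop = FALSE], yf[-i], ridge = ridge)
      score[i] <- sum(fit$w * X[i, ]) - fit$threshold
    }
  }
  out <- data.frame(id = d$ids, label = yf,
                    score = score,
                    predicted = factor(ifelse(score > 0, "cancer", "normal"),
                                       levels = CLASS_LEVELS),
                    stringsAsFactors = FALSE)
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Confusion-matrix metrics of a cross-validation result
#'
#' Cancer is the positive class: sensitivity = TP/(TP+FN) over cancer
#' samples, specificity = TN/(TN+FP) over normal samples.
#'
#' @param cv A `cv_result` from [loocv()] or [pca_lda_loocv()], or any data
#'   frame with `label` and `predicted` columns.
#' @return A `class_metrics` list: `TP`, `FN`, `TN`, `FP`, `sensitivity`,
#'   `specificity`, `accuracy` (fractions in `[0, 1]`).
#' @export
compute_metrics <- function(cv) {
  stopifnot(all(c("label", "predicted") %in% names(cv)))
  truth <- factor(as.character(cv$label), levels = CLASS_LEVELS)
  pred <- factor(as.character(cv$predicted), levels = CLASS_LEVELS)
  if (length(unique(truth)) < 2) stop("both classes must be present", call. = FALSE)
  TP <- sum(truth == "cancer" & pred == "cancer")
  FN <- sum(truth == "cancer" & pred == "normal")
  TN <- sum(truth == "normal" & pred == "normal")
  FP <- sum(truth == "normal" & pred == "cancer")
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP,
                 sensitivity = TP / (TP + FN),
                 specificity = TN / (TN + FP),
                 accuracy = (TP + TN) / (TP + TN + FP + FN)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FN=%d TN=%d FP=%d\n", x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

#' Principal-component scores of a spectra matrix
#'
#' Column-mean-centered PCA (no variance scaling), via the singular value
#' decomposition.
#'
#' @param X Numeric matrix, samples in rows.
#' @param n_components Number of leading components, at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return List with `scores` (n x n_components), `explained`
#'   (per-component variance fractions, non-increasing), `cum_explained`,
#'   `rotation`, `center`.
#' @export
pca_scores <- function(X, n_components) {
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1, ncol(X))
  if (n_components < 1 || n_components > kmax) {
    stop(sprintf("n_components must be in 1..%d (min(n-1, p)), got %d",
                 kmax, n_components), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(n_components)
  list(scores = pc$x[, k, drop = FALSE],
       explained = varfrac[k],
       cum_explained = cumsum(varfrac)[k],
       rotation = pc$rotation[, k, drop = FALSE],
       center = pc$center)
}

#' PCA-LDA with leave-one-spectrum-out cross-validation
#'
#' The comparator model: project onto the leading principal components, then
#' run LOOCV-LDA in component space. By default the PCA is fitted once on the
#' full matrix before cross-validation — the conventional chemometric
#' shortcut, which leaks the held-out sample into the projection and is
#' therefore optimistically biased; set `refit_per_fold = TRUE` for the
#' unbiased variant that refits the PCA inside every fold.
#'
#' @inheritParams loocv
#' @param n_components Number of principal components retained.
#' @param refit_per_fold Refit the PCA on each training fold.
#' @return A `cv_result` data frame (see [loocv()]) with attribute
#'   `cum_explained` (full-fit cumulative variance fraction of the retained
#'   components).
#' @export
pca_lda_loocv <- function(data, y = NULL, n_components = 20, ridge = 1e-8,
                          refit_per_fold = FALSE) {
  d <- as_Xy(data, y)
  X <- d$X; yf <- d$y
  pc_full <- pca_scores(X, n_components)
  if (!refit_per_fold) {
    out <- loocv(pc_full$scores, yf, ridge = ridge)
    out$id <- d$ids
  } else {
    n <- nrow(X)
    score <- numeric(n)
    for (i in seq_len(n)) {
      Xt <- X[-i, , drop = FALSE]
      pc <- pca_scores(Xt, min(n_components, nrow(Xt) - 1))
      fit <- fit_lda(pc$scores, yf[-i], ridge = ridge)
      z <- (X[i, ] - pc$center) %*% pc$rotation
      score[i] <- sum(fit$w * z) - fit$threshold
    }
    out <- data.frame(id = d$ids, label = yf, score = score,
                      predicted = factor(ifelse(score > 0, "cancer", "normal"),
                                         levels = CLASS_LEVELS),
                      stringsAsFactors = FALSE)
    class(out) <- c("cv_result", "data.frame")
  }
  attr(out, "cum_explained") <- pc_full$cum_explained[n_components]
  out
}
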
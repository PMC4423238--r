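# Independent oracles and small fixtures shared across the suite.

# Fold-by-fold LOOCV-LDA written from scratch (explicit scatter sums, direct
# solve), independent of the package's loocv()/fit_lda() internals.
naive_loocv_predictions <- function(X, y, ridge = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  pred <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]; yt <- y[-i]
    mu0 <- colMeans(Xt[yt == "normal", , drop = FALSE])
    mu1 <- colMeans(Xt[yt == "cancer", , drop = FALSE])
    Sw <- matrix(0, p, p)
    for (j in seq_len(nrow(Xt))) {
      mu <- if (yt[j] == "cancer") mu1 else mu0
      v <- Xt[j, ] - mu
      Sw <- Sw + outer(v, v)
    }
    if (ridge > 0) Sw <- Sw + diag(ridge * sum(diag(Sw)) / p, p)
    w <- solve(Sw, mu1 - mu0)
    if (sum(w * (mu1 - mu0)) < 0) w <- -w
    thr <- 0.5 * (sum(w * mu1) + sum(w * mu0))
    score[i] <- sum(w * X[i, ]) - thr
    pred[i] <- if (score[i] > 0) "cancer" else "normal"
  }
  list(score = score, predicted = pred)
}

# Fisher criterion maximized by grid search over directions (2-D only).
brute_fisher_direction <- function(X, y, n_angles = 20000) {
  stopifnot(ncol(X) == 2)
  mu0 <- colMeans(X[y == "normal", , drop = FALSE])
  mu1 <- colMeans(X[y == "cancer", , drop = FALSE])
  d <- mu1 - mu0
  Sw <- crossprod(sweep(X[y == "normal", , drop = FALSE], 2, mu0)) +
        crossprod(sweep(X[y == "cancer", , drop = FALSE], 2, mu1))
  th <- seq(0, pi, length.out = n_angles)
  J <- vapply(th, function(t) {
    w <- c(cos(t), sin(t))
    (sum(w * d))^2 / drop(t(w) %*% Sw %*% w)
  }, numeric(1))
  t_best <- th[which.max(J)]
  c(cos(t_best), sin(t_best))
}

angle_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}

# Tie-corrected pair-counting AUC: P(score_cancer > score_normal) + 0.5 ties.
auc_paircount <- function(scores, labels) {
  sp <- scores[labels == "cancer"]; sn <- scores[labels == "normal"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random well-conditioned 2-class 2-D instance
random_lda_instance <- function() {
  n0 <- sample(5:15, 1); n1 <- sample(5:15, 1)
  A <- matrix(stats::rnorm(4), 2)
  Sig <- crossprod(A) + diag(0.5, 2)
  X <- rbind(MASS::mvrnorm(n0, c(0, 0), Sig),
             MASS::mvrnorm(n1, stats::runif(2, -2, 2), Sig))
  list(X = X, y = rep(c("normal", "cancer"), c(n0, n1)))
}

# Small fast synthetic cohort for GA/pipeline tests: 200-point grid,
# 40 segments, three peaks of which two carry a class effect.
tiny_config <- function(seed = 1, n_normal = 12, n_cancer = 14,
                        effect = 0.25, noise_sd = 0.02) {
  peaks <- data.frame(center = c(600, 1000, 1400),
                      width = 15,
                      amplitude = c(1, 0.8, 1),
                      effect = c(-effect, 0, effect))
  synthetic_config(n_normal = n_normal, n_cancer = n_cancer,
                   grid_lo = 400, grid_hi = 1800, n_points = 200,
                   peaks = peaks, noise_sd = noise_sd, seed = seed)
}

tiny_preprocessed <- function(seed = 1, ...) {
  preprocess_set(simulate_dataset(tiny_config(seed = seed, ...)),
                 preprocess_config())
}

# study-scale generator restricted to the six diagnostic bands: the two
# class-affected peaks outside the six selected bands are made class-neutral,
# so the planted truth is exactly six band locations
recovery_config <- function(seed) {
  pk <- default_peaks()
  pk$effect[pk$center %in% c(1219, 1640)] <- 0
  synthetic_config(peaks = pk, seed = seed)
}

# A consensus band covers a planted peak location if it comes within two
# segments (~11 cm^-1) of the segment holding the peak center — the matching
# latitude serum band tables conventionally use when assigning a selected
# band to a Raman line (e.g. a 1450-1459 band attributed to the 1445 line).
bands_cover <- function(bands, planted_segments, tol = 2) {
  vapply(planted_segments, function(s) {
    any(bands$seg_lo - tol <= s & s <= bands$seg_hi + tol)
  }, logical(1))
}
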
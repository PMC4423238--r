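test_that("the fitted discriminant matches the closed form in 2-D", {
  # identity within-class scatter, class means (0,0) and (2,0)
  base <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  X <- rbind(base, sweep(base, 2, c(2, 0), `+`))
  y <- rep(c("normal", "cancer"), each = 4)
  fit <- fit_lda(X, y, ridge = 0)
  expect_equal(fit$w[2], 0, tolerance = 1e-12)
  expect_gt(fit$w[1], 0)
  expect_equal(fit$threshold, fit$w[1] * 1, tolerance = 1e-12)

  pr <- predict(fit, rbind(c(2, 0), c(0, 0)))
  expect_equal(as.character(pr$predicted), c("cancer", "normal"))
})

test_that("the weight vector maximizes the Fisher criterion (grid oracle)", {
  set.seed(17)
  for (r in 1:25) {
    inst <- random_lda_instance()
    fit <- fit_lda(inst$X, inst$y, ridge = 0)
    wb <- brute_fisher_direction(inst$X, inst$y)
    expect_lt(angle_deg(fit$w, wb), 1)
  }
})

test_that("the direction agrees with an established LDA implementation", {
  set.seed(18)
  inst <- random_lda_instance()
  fit <- fit_lda(inst$X, inst$y, ridge = 0)
  v <- as.numeric(MASS::lda(inst$X, grouping = inst$y)$scaling)
  expect_lt(angle_deg(fit$w, v), 1e-4)
})

test_that("degenerate fits are rejected with guidance", {
  X <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2), ncol = 1)
  y <- rep(c("normal", "cancer"), each = 4)
  expect_error(fit_lda(X, y, ridge = 0), "ridge")
  expect_error(fit_lda(X[1:4, , drop = FALSE], rep("normal", 4)), "class")
  # duplicated feature column: singular without ridge, stable with it
  set.seed(3)
  Z <- matrix(rnorm(16), 8, 2); Z <- cbind(Z, Z[, 2])
  expect_error(fit_lda(Z, y, ridge = 0), "ridge")
  fit <- fit_lda(Z, y, ridge = 1e-8)
  expect_true(all(is.finite(fit$w)))
})

test_that("prediction uses a strict threshold with ties called normal", {
  base <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  X <- rbind(base, sweep(base, 2, c(2, 0), `+`))
  fit <- fit_lda(X, rep(c("normal", "cancer"), each = 4))
  expect_equal(as.character(predict(fit, fit$mu_cancer)$predicted), "cancer")
  # a point projecting exactly onto the threshold is called normal
  x_mid <- c(1, 0)
  expect_equal(predict(fit, x_mid)$score, fit$threshold)
  expect_equal(as.character(predict(fit, x_mid)$predicted), "normal")
  # monotone along +w
  steps <- t(sapply(0:4, function(k) x_mid + k * fit$w))
  expect_true(all(diff(predict(fit, steps)$score) > 0))
  expect_error(predict(fit, c(1, 2, 3)), "variables")
})

test_that("LOOCV matches a from-scratch fold-by-fold reimplementation", {
  set.seed(19)
  for (r in 1:10) {
    n0 <- sample(3:8, 1); n1 <- sample(3:8, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm((n0 + n1) * p), ncol = p)
    X[seq_len(n1) + n0, 1] <- X[seq_len(n1) + n0, 1] + 1
    y <- rep(c("normal", "cancer"), c(n0, n1))
    cv <- loocv(X, y)
    oracle <- naive_loocv_predictions(X, y)
    expect_identical(as.character(cv$predicted), oracle$predicted)
    expect_equal(cv$score, oracle$score, tolerance = 1e-8)
    # compiled and plain-R paths agree
    cv_r <- loocv(X, y, engine = "r")
    expect_identical(as.character(cv_r$predicted), as.character(cv$predicted))
    expect_equal(cv_r$score, cv$score, tolerance = 1e-10)
  }
})

test_that("well-separated data is classified perfectly by LOOCV", {
  X <- matrix(c(rnorm(6, 0, 0.01), rnorm(6, 10, 0.01)), ncol = 1)
  y <- rep(c("normal", "cancer"), each = 6)
  cv <- loocv(X, y)
  expect_true(all(cv$predicted == cv$label))
})

test_that("duplicating every sample leaves its fold prediction unchanged", {
  set.seed(20)
  X <- matrix(rnorm(24), 8, 3); X[5:8, 1] <- X[5:8, 1] + 2
  y <- rep(c("normal", "cancer"), each = 4)
  cv2 <- loocv(rbind(X, X), c(y, y))
  expect_identical(as.character(cv2$predicted[1:8]),
                   as.character(cv2$predicted[9:16]))
})

test_that("LOOCV is invariant to variable order and single-variable rescaling", {
  set.seed(23)
  X <- matrix(rnorm(36), 12, 3); X[7:12, 2] <- X[7:12, 2] + 1.5
  y <- rep(c("normal", "cancer"), each = 6)
  ref <- loocv(X, y, ridge = 0)
  perm <- loocv(X[, c(3, 1, 2)], y, ridge = 0)
  expect_identical(as.character(perm$predicted), as.character(ref$predicted))
  scaled <- X; scaled[, 1] <- 1000 * scaled[, 1]
  expect_identical(as.character(loocv(scaled, y, ridge = 0)$predicted),
                   as.character(ref$predicted))
})

test_that("LOOCV preconditions name the limiting class", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(loocv(X, c("normal", "normal", "normal", "cancer", "cancer")),
               "cancer")
})

test_that("confusion metrics reproduce the worked diagnostic example", {
  fake_cv <- function(TP, FN, TN, FP) {
    data.frame(label = rep(c("cancer", "normal"), c(TP + FN, TN + FP)),
               predicted = c(rep("cancer", TP), rep("normal", FN),
                             rep("normal", TN), rep("cancer", FP)))
  }
  # 55 cancer / 36 normal with 5 missed cancers and no false positives
  m <- compute_metrics(fake_cv(50, 5, 36, 0))
  expect_equal(round(100 * m$sensitivity, 1), 90.9)
  expect_equal(round(100 * m$specificity, 1), 100)
  expect_equal(round(100 * m$accuracy, 1), 94.5)

  m2 <- compute_metrics(fake_cv(41, 14, 35, 1))
  expect_equal(round(100 * m2$accuracy, 1), 83.5)
  expect_equal(round(100 * m2$specificity, 1), 97.2)

  m3 <- compute_metrics(fake_cv(10, 0, 10, 0))
  expect_equal(c(m3$sensitivity, m3$specificity, m3$accuracy), c(1, 1, 1))

  # identities on random confusion tables
  set.seed(24)
  for (r in 1:20) {
    k <- sample(1:20, 4, replace = TRUE)
    m <- compute_metrics(fake_cv(k[1], k[2], k[3], k[4]))
    expect_equal(m$sensitivity, k[1] / (k[1] + k[2]))
    expect_equal(m$specificity, k[3] / (k[3] + k[4]))
    expect_equal(m$accuracy, (k[1] + k[3]) / sum(k))
  }
})

test_that("PCA scores have the expected spectral structure", {
  # collinear points: one component explains everything
  t3 <- cbind(1:10, 2 * (1:10), -0.5 * (1:10))
  pc <- pca_scores(t3, 2)
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)

  set.seed(25)
  X <- matrix(rnorm(15 * 6), 15, 6)
  full <- pca_scores(X, 6)
  expect_equal(full$cum_explained[6], 1, tolerance = 1e-10)
  expect_true(all(diff(full$explained) <= 1e-12))

  # reconstruction error decreases monotonically with components
  err <- sapply(1:6, function(k) {
    pc <- pca_scores(X, k)
    Xhat <- pc$scores %*% t(pc$rotation)
    sum((sweep(X, 2, pc$center) - Xhat)^2)
  })
  expect_true(all(diff(err) <= 1e-8))
  expect_error(pca_scores(X, 15), "n_components")
})

test_that("PCA-LDA with all components reduces to plain LDA", {
  set.seed(26)
  X <- matrix(rnorm(20 * 4), 20, 4); X[11:20, 2] <- X[11:20, 2] + 1
  y <- rep(c("normal", "cancer"), each = 10)
  ref <- loocv(X, y, ridge = 0)
  pcacv <- pca_lda_loocv(X, y, n_components = 4, ridge = 0)
  expect_identical(as.character(pcacv$predicted), as.character(ref$predicted))

  # deterministic
  expect_identical(pca_lda_loocv(X, y, n_components = 2)$score,
                   pca_lda_loocv(X, y, n_components = 2)$score)
})

test_that("one component misses class structure orthogonal to top variance", {
  set.seed(27)
  n <- 40
  high_var <- rnorm(n, 0, 20)              # dominant but uninformative axis
  discr <- c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 1.5, 0.3))
  X <- cbind(high_var, discr)
  y <- rep(c("normal", "cancer"), each = n / 2)
  acc1 <- mean(pca_lda_loocv(X, y, n_components = 1)$predicted == y)
  acc2 <- mean(pca_lda_loocv(X, y, n_components = 2)$predicted == y)
  expect_lt(acc1, 0.7)
  expect_gt(acc2, 0.9)
})

test_that("per-fold PCA refitting gives valid, comparable results", {
  set.seed(28)
  X <- matrix(rnorm(18 * 5), 18, 5); X[10:18, 1] <- X[10:18, 1] + 2
  y <- rep(c("normal", "cancer"), c(9, 9))
  cv <- pca_lda_loocv(X, y, n_components = 3, refit_per_fold = TRUE)
  expect_equal(nrow(cv), 18)
  expect_true(mean(cv$predicted == cv$label) > 0.7)
})
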
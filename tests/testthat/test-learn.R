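test_that("PCA retains the automatic dimension for planted spectra", {
  set.seed(51)
  # 50 points exactly in a 2-D plane of a 10-D space
  basis <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  X <- matrix(rnorm(100), 50, 2) %*% t(basis)
  expect_equal(pca_fit(X, 0.95)$k, 2L)

  # isotropic 3-D sample needs full rank for 100% of the variance
  X3 <- matrix(rnorm(300), 100, 3)
  expect_equal(pca_fit(X3, 1.0)$k, 3L)

  # one dominant direction carrying ~99% of the variance
  Xd <- cbind(rnorm(200, sd = 10), rnorm(200, sd = 0.5), rnorm(200, sd = 0.5))
  expect_equal(pca_fit(Xd, 0.95)$k, 1L)

  expect_error(pca_fit(matrix(1, 5, 3)), "degenerate")
})

test_that("PCA matches a direct covariance eigendecomposition", {
  set.seed(52)
  X <- matrix(rnorm(200 * 50), 200, 50) %*% diag(seq(5, 0.5, length.out = 50))
  m <- pca_fit(X, 0.99)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  for (j in seq_len(m$k)) {
    align <- abs(sum(m$rotation[, j] * ev$vectors[, j]))
    expect_gt(align, 1 - 1e-6)
  }
  expect_equal(m$sdev^2, ev$values[seq_along(m$sdev)], tolerance = 1e-8)
  # components orthonormal
  G <- t(m$rotation) %*% m$rotation
  expect_equal(G, diag(m$k), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA projection obeys the reconstruction identity", {
  set.seed(53)
  X <- matrix(rnorm(80 * 12), 80, 12) %*% diag(c(6, 4, rep(0.3, 10)))
  m <- pca_fit(X, 0.9)
  # the training mean projects to the origin
  expect_equal(as.vector(pca_transform(m, matrix(m$center, 1))),
               rep(0, m$k), tolerance = 1e-10)
  # round-trip error bounded by the discarded variance (Pythagoras)
  Z <- pca_transform(m, X)
  recon <- sweep(Z %*% t(m$rotation), 2, m$center, "+")
  err <- sum((X - recon)^2)
  discarded <- sum(m$sdev[-seq_len(m$k)]^2) * (nrow(X) - 1)
  expect_lte(err, discarded * (1 + 1e-8))
  # zero-variance padding columns do not change the projection
  Xp <- cbind(X, 0, 0)
  mp <- pca_fit(Xp, 0.9)
  expect_equal(abs(pca_transform(mp, Xp)), abs(Z), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_transform(m, matrix(0, 2, 5)), "dimension")
})

test_that("boosting fits separable data in one round and beats one stump on XOR", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- rep(c("control", "case"), each = 3)
  m <- adaboost_train(x, y)
  expect_length(m$stumps, 1L)
  expect_equal(fuse_scores(m, x)$label, y)

  # XOR arrangement cannot be solved by any single stump
  set.seed(54)
  X <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2) + matrix(c(0, 0), 20, 2, TRUE),
             matrix(rnorm(40, 0, 0.3), 20, 2) + matrix(c(3, 3), 20, 2, TRUE),
             matrix(rnorm(40, 0, 0.3), 20, 2) + matrix(c(0, 3), 20, 2, TRUE),
             matrix(rnorm(40, 0, 0.3), 20, 2) + matrix(c(3, 0), 20, 2, TRUE))
  yy <- rep(c("case", "case", "control", "control"), each = 20)
  ypm <- ifelse(yy == "case", 1, -1)
  boosted <- adaboost_train(X, yy, rounds = 10)
  train_err <- mean(fuse_scores(boosted, X)$label != yy)
  single_err <- best_single_stump_error(X, ypm)
  expect_lt(train_err, single_err)

  expect_error(adaboost_train(X, rep("case", 80)), "both classes")
})

test_that("the exponential-loss bound holds at every boosting round", {
  set.seed(55)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- ifelse(X[, 1] + 0.8 * rnorm(60) > 0, "case", "control")
  m <- adaboost_train(X, y, rounds = 25)
  ypm <- ifelse(y == "case", 1, -1)
  score <- numeric(60)
  for (t in seq_along(m$stumps)) {
    s <- m$stumps[[t]]
    score <- score + m$alpha[t] *
      tsface:::stump_predict(X[, s$feature], s$threshold, s$polarity)
    train_err <- mean(sign(score) != ypm)
    bound <- prod(2 * sqrt(m$weighted_errors[1:t] *
                             (1 - m$weighted_errors[1:t])))
    expect_lte(train_err, bound + 1e-12)
    expect_lt(m$weighted_errors[t], 0.5)
  }
})

test_that("fusion scores equal the brute-force stump sum and ties go to control", {
  set.seed(56)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- ifelse(rowSums(X[, 1:2]) > 0, "case", "control")
  m <- adaboost_train(X, y, rounds = 15)
  got <- fuse_scores(m, X)
  manual <- numeric(40)
  for (t in seq_along(m$stumps)) {
    s <- m$stumps[[t]]
    h <- ifelse(X[, s$feature] > s$threshold, 1, -1) * s$polarity
    manual <- manual + m$alpha[t] * h
  }
  expect_equal(got$score, manual, tolerance = 1e-12)
  # zero score resolves to control
  m0 <- m; m0$alpha <- rep(0, length(m0$alpha))
  z <- fuse_scores(m0, X)
  expect_true(all(z$score == 0))
  expect_true(all(z$label == "control"))
  expect_error(fuse_scores(list(), X), "fusion_model")
})

test_that("stratified folds partition the data with balanced sizes", {
  y <- rep(c("case", "control"), c(20, 60))
  cv <- cv_plan(y, k = 10, seed = 9)
  idx <- sort(unname(unlist(cv$folds)))
  expect_equal(idx, 1:80)
  sizes <- lengths(cv$folds)
  expect_lte(diff(range(sizes)), 1)
  case_per_fold <- vapply(cv$folds, function(f) sum(y[f] == "case"), numeric(1))
  expect_lte(diff(range(case_per_fold)), 1)
  expect_warning(cv_plan(rep(c("case", "control"), c(3, 30)), k = 10),
                 "reducing fold count")
})

test_that("the SVM selector is exact on wide-margin blobs and standardization-invariant", {
  set.seed(57)
  X <- rbind(matrix(rnorm(60, 0, 0.2), 30, 2),
             matrix(rnorm(60, 5, 0.2), 30, 2))
  y <- rep(c("case", "control"), each = 30)
  fit <- suppressWarnings(svm_train(X, y, seed = 3))
  expect_equal(fit$cv_balanced_accuracy, 1.0)
  expect_equal(predict(fit, X), y)

  # shifting and rescaling a column changes nothing
  X2 <- X; X2[, 1] <- X2[, 1] * 250 - 1000
  fit2 <- suppressWarnings(svm_train(X2, y, seed = 3))
  expect_equal(fit2$cv_table$cv_balanced_accuracy,
               fit$cv_table$cv_balanced_accuracy, tolerance = 1e-6)

  # duplicated feature columns leave RBF predictions unchanged
  grid_rbf <- data.frame(kernel = "radial", cost = 10, gamma = 1)
  f1 <- suppressWarnings(svm_train(X, y, grid = grid_rbf, seed = 3))
  f2 <- suppressWarnings(svm_train(cbind(X, X), y, grid = grid_rbf, seed = 3))
  expect_equal(predict(f2, cbind(X, X)), predict(f1, X))
})

test_that("label permutation drives CV accuracy to chance", {
  set.seed(58)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(c("case", "control"), each = 30)
  accs <- vapply(1:15, function(i) {
    yp <- sample(y)
    suppressWarnings(svm_train(X, yp, seed = i))$cv_balanced_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("method selection ranks the family carrying the planted signal first", {
  set.seed(59)
  n <- 60
  y <- rep(c("case", "control"), each = n / 2)
  noise <- function(p) matrix(rnorm(n * p), n)
  # signal only in the local block
  lf_sig <- noise(10); lf_sig[, 3] <- lf_sig[, 3] + ifelse(y == "case", 2.5, 0)
  sel <- suppressWarnings(select_method(
    list(ggf = noise(30), gtf = noise(30), lf = lf_sig), y, k = 5, seed = 2))
  expect_equal(sel$feature[1], "Fusion of local features")
  expect_gt(sel$cv_balanced_accuracy[1], 0.75)

  # identical features for both classes: nothing beats chance by much
  null_sel <- suppressWarnings(select_method(
    list(ggf = noise(20), gtf = noise(20), lf = noise(10)), y, k = 5, seed = 2))
  expect_lt(max(null_sel$cv_balanced_accuracy), 0.75)

  # a single separating landmark distance puts the geometric family first
  # fully separable on one distance column
  ggf_sig <- noise(30); ggf_sig[, 7] <- ggf_sig[, 7] + ifelse(y == "case", 8, 0)
  geo_sel <- suppressWarnings(select_method(
    list(ggf = ggf_sig, gtf = noise(30), lf = noise(10)), y, k = 5, seed = 2))
  expect_equal(geo_sel$feature[1], "Global geometrical features")
  expect_gte(geo_sel$cv_balanced_accuracy[1], 0.9)
})
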
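# SVM training/prediction contracts: dual feasibility and KKT conditions,
# agreement with an exhaustive QP oracle and with an independent libsvm
# implementation, decision-function behaviors, SWLDA classifier oracle.

test_that("well-separated blobs are classified perfectly", {
  blob <- two_blobs()
  m <- train_svm(blob$X, blob$y)
  expect_equal(accuracy(blob$y, predict(m, blob$X)), 100)
  expect_gte(accuracy(blob$y, predict(m, blob$X)),
             100 * max(table(blob$y)) / length(blob$y))
})

test_that("dual feasibility holds at every fit", {
  blob <- two_blobs(n_per = 8, sep = 1.5)          # overlapping classes
  for (C in c(0.1, 1, 10)) {
    m <- train_svm(blob$X, blob$y, svm_params(C = C))
    expect_lt(abs(sum(m$coef)), 1e-6)              # sum alpha_m y_m = 0
    expect_true(all(m$alpha >= -1e-9 & m$alpha <= C + 1e-9))
  }
})

test_that("flipping all labels flips the decision values", {
  blob <- two_blobs(n_per = 6, sep = 2)
  m1 <- train_svm(blob$X, blob$y)
  m2 <- train_svm(blob$X, -blob$y)
  f1 <- predict(m1, blob$X, type = "decision")
  f2 <- predict(m2, blob$X, type = "decision")
  expect_equal(f1, -f2, tolerance = 1e-6)
})

test_that("the dual solution matches an exhaustive active-set QP solve", {
  set.seed(11)
  X <- rbind(matrix(rnorm(6, -1), 3, 2), matrix(rnorm(6, 1), 3, 2))
  y <- rep(c(-1, 1), each = 3)
  for (prm in list(svm_params(C = 1, kernel = "linear"),
                   svm_params(C = 0.5, sigma = 1.5, kernel = "rbf"))) {
    m <- train_svm(X, y, prm)
    prm$sigma <- m$params$sigma
    K <- rtmseeg:::svm_kernel_matrix(X, X, m$params)
    oracle <- brute_force_svm_qp(K, y, prm$C)
    expect_false(is.null(oracle))
    alpha_full <- numeric(6)
    alpha_full[m$sv_index] <- m$alpha
    expect_lt(max(abs(alpha_full - oracle$alpha)), 1e-4)
  }
})

test_that("the decision function agrees with an independent libsvm fit", {
  skip_if_not_installed("e1071")
  set.seed(12)
  blob <- two_blobs(n_per = 7, sep = 2)
  prm <- svm_params(C = 2, sigma = 1.2)
  m <- train_svm(blob$X, blob$y, prm)
  ref <- e1071::svm(blob$X, factor(blob$y), kernel = "radial",
                    cost = 2, gamma = 1 / (2 * 1.2^2), scale = FALSE)
  pr <- predict(ref, blob$X, decision.values = TRUE)
  f_ref <- attr(pr, "decision.values")[, 1]
  f <- predict(m, blob$X, type = "decision")
  # orientations fixed to +1 = positive class; compare up to that orientation
  s <- sign(sum(sign(f) * sign(f_ref)))
  expect_lt(max(abs(f - s * f_ref)), 1e-3)
})

test_that("KKT margin condition holds for unbounded support vectors", {
  blob <- two_blobs(n_per = 10, sep = 3, seed = 5)
  m <- train_svm(blob$X, blob$y, svm_params(C = 10))
  f_sv <- predict(m, m$sv, type = "decision")
  free <- m$alpha > 1e-6 & m$alpha < 10 - 1e-6
  if (any(free)) {
    expect_lt(max(abs(abs(f_sv[free]) - 1)), 1e-3)
  }
})

test_that("points far from every support vector decide by the bias sign", {
  blob <- two_blobs(n_per = 5, sep = 2, seed = 7)
  m <- train_svm(blob$X, blob$y, svm_params(sigma = 0.5))
  far <- matrix(1e3, 1, 2)
  f <- predict(m, far, type = "decision")
  expect_equal(f, m$b, tolerance = 1e-8)
  if (m$b != 0) {
    expect_equal(predict(m, far), sign(m$b))
  }
})

test_that("increasing C on separable data never decreases training accuracy", {
  blob <- two_blobs(n_per = 8, sep = 4, seed = 9)
  accs <- vapply(c(0.01, 0.1, 1, 10, 100), function(C) {
    m <- train_svm(blob$X, blob$y, svm_params(C = C))
    accuracy(blob$y, predict(m, blob$X))
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("degenerate inputs are rejected with clear errors", {
  blob <- two_blobs(n_per = 4)
  expect_error(train_svm(blob$X, rep(1, 8)), "single class")
  m <- train_svm(blob$X, blob$y)
  expect_error(predict(m, matrix(0, 1, 5)), "columns")
})

test_that("a constant column added after standardization leaves RBF decisions unchanged", {
  blob <- two_blobs(n_per = 6, sep = 2, seed = 13)
  std <- fit_standardizer(blob$X)
  Xs <- apply_standardizer(std, blob$X)
  m1 <- train_svm(Xs, blob$y, svm_params(sigma = 1))
  # a constant raw column standardizes to all zeros (zero-variance guard)
  Xc <- cbind(blob$X, 7)
  stdc <- fit_standardizer(Xc)
  Xsc <- apply_standardizer(stdc, Xc)
  expect_true(all(Xsc[, 3] == 0))
  m2 <- train_svm(Xsc, blob$y, svm_params(sigma = 1))
  expect_equal(predict(m1, Xs, type = "decision"),
               predict(m2, Xsc, type = "decision"), tolerance = 1e-6)
})

test_that("accuracy is the percentage of matches", {
  expect_equal(accuracy(c(1, 1, -1), c(1, 1, -1)), 100)
  expect_equal(accuracy(c(1, 1, -1, -1), c(-1, -1, 1, 1)), 0)
  expect_equal(accuracy(c(1, 1, -1, -1), c(1, -1, -1, -1)), 75)
  expect_equal(accuracy(rep(c("a", "b"), 3), rep(c("a", "a"), 3)), 50)
  expect_error(accuracy(1:3, 1:2))
})

test_that("the SWLDA classifier matches the least-squares discriminant", {
  set.seed(14)
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- rep(c(-1, 1), 4)
  m <- train_swlda_classifier(X, y, alpha_in = 0.99, alpha_out = 0.995)
  # dense normal-equations solve on the selected columns
  A <- cbind(1, X[, m$selected, drop = FALSE])
  beta <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(predict(m, X, type = "score"), as.numeric(A %*% beta),
               tolerance = 1e-8)
  # perfect separator feature: 100% training accuracy
  Xp <- cbind(y, matrix(rnorm(8 * 2), 8, 2))
  mp <- train_swlda_classifier(Xp, y)
  expect_equal(accuracy(y, predict(mp, Xp)), 100)
})

test_that("SVM models survive a JSON round trip exactly", {
  blob <- two_blobs(n_per = 5, sep = 2, seed = 15)
  m <- train_svm(blob$X, blob$y, svm_params(C = 3, sigma = 0.8))
  path <- tempfile(fileext = ".json")
  write_svm_model(m, path)
  m2 <- read_svm_model(path)
  expect_equal(predict(m2, blob$X, type = "decision"),
               predict(m, blob$X, type = "decision"), tolerance = 1e-12)
})
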
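# Feature-selection routes: PCA against a dense eigensolver, the wavelet
# system's perfect reconstruction and energy optimality, stepwise selection
# against a naive lm() reference, SVM weight algebra, band restriction.

test_that("db4 decomposition matches the reference wavelet library values", {
  # frozen pywt.dwt(x, "db4", mode="periodization") output for this input
  x <- c(1.764052, 0.400157, 0.978738, 2.240893, 1.867558, -0.977278,
         0.950088, -0.151357, -0.103219, 0.410599, 0.144044, 1.454274,
         0.761038, 0.121675, 0.443863, 0.333674)
  a_ref <- c(0.515707240133, 1.159228946793, 2.361513594385, 1.245237373140,
             0.328826308990, -0.102878078838, 1.076948770937, 0.938182761041)
  d_ref <- c(0.867330975353, -2.024542028418, -0.274475871709, 0.392085517913,
             0.717033061757, -0.491494711543, -0.273197747519, -1.015338887362)
  dec <- dwt_db4(x, level = 1)
  expect_equal(dec$coeffs, c(a_ref, d_ref), tolerance = 1e-10)
})

test_that("the wavelet transform is orthonormal: perfect reconstruction and energy", {
  set.seed(1)
  for (n in c(16, 64, 120)) {
    x <- rnorm(n)
    dec <- dwt_db4(x)
    expect_equal(idwt_db4(dec), x, tolerance = 1e-10)
    expect_equal(sum(dec$coeffs^2), sum(x^2), tolerance = 1e-10)
  }
})

test_that("a single wavelet atom is ranked first", {
  n <- 64
  coeffs0 <- dwt_db4(numeric(n))
  coeffs0$coeffs[17] <- 1                 # one atom
  atom_signal <- idwt_db4(coeffs0)
  prov <- data.frame(channel = "C3", band = "theta", window = 1:n)
  sel <- wavelet_select(matrix(atom_signal, 1), prov, keep_fraction = 1 / n)
  expect_equal(sel$positions, 17)
})

test_that("retained coefficients maximize energy among same-size subsets", {
  set.seed(2)
  n <- 64
  X <- matrix(rnorm(3 * n), 3)
  prov <- data.frame(channel = "C3", band = "theta", window = 1:n)
  sel <- wavelet_select(X, prov, keep_fraction = 0.1)
  C <- rtmseeg:::wavelet_transform_rows(X, sel$blocks)
  energy <- colSums(C^2)
  k <- length(sel$positions)
  chosen <- sum(energy[sel$positions])
  # exhaustive-in-spirit check: the selection beats 2000 random subsets and
  # equals the top-k of the exact energy ordering
  for (r in 1:2000) {
    other <- sample(n, k)
    expect_gte(chosen + 1e-9, sum(energy[other]))
  }
  # ranking is by mean |coef|, which for these rows coincides with top-k energy
  expect_setequal(sel$positions, order(colMeans(abs(C)), decreasing = TRUE)[1:k])
})

test_that("retained energy is non-decreasing in keep_fraction, full keep reconstructs", {
  set.seed(3)
  X <- matrix(rnorm(4 * 32), 4)
  prov <- data.frame(channel = "Cz", band = "alpha", window = 1:32)
  fracs <- c(0.05, 0.1, 0.25, 0.5, 1)
  energies <- vapply(fracs, function(fr) {
    wavelet_select(X, prov, keep_fraction = fr)$fit_stats$retained_energy_fraction
  }, numeric(1))
  expect_true(all(diff(energies) >= -1e-12))
  expect_equal(energies[length(energies)], 1, tolerance = 1e-12)
  # keep_fraction 1: coefficients invert back to the data row by row
  sel <- wavelet_select(X, prov, keep_fraction = 1)
  C <- wavelet_transform(sel, X)
  dec <- dwt_db4(X[2, ])
  dec$coeffs <- C[2, ]
  expect_equal(idwt_db4(dec), X[2, ], tolerance = 1e-8)
})

test_that("PCA matches a dense eigendecomposition of the covariance", {
  set.seed(4)
  X <- matrix(rnorm(10 * 6), 10, 6)
  red <- pca_reduce(X, k = 3)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(red$eigenvalues, ev, tolerance = 1e-8)
  # orthonormal projection
  expect_equal(unname(crossprod(red$projection)), diag(3), tolerance = 1e-10)
  # explained-variance fractions non-increasing, sum <= 1
  fr <- red$eigenvalues / sum(red$eigenvalues)
  expect_true(all(diff(fr) <= 1e-12) && sum(fr) <= 1 + 1e-12)
})

test_that("PCA reconstructs exactly at the true rank and errors when k too large", {
  set.seed(5)
  B <- matrix(rnorm(12 * 3), 12, 3) %*% matrix(rnorm(3 * 8), 3, 8)
  red <- pca_reduce(B, k = 3)
  recon <- red$transformed %*% t(red$projection) +
    matrix(red$center, 12, 8, byrow = TRUE)
  expect_lt(max(abs(recon - B)), 1e-8)
  expect_error(pca_reduce(B, k = 9), "exceeds")
  # default k = 20 yields 20 columns when feasible
  X <- matrix(rnorm(30 * 40), 30, 40)
  expect_equal(ncol(pca_reduce(X, 20)$transformed), 20)
})

test_that("stepwise selection picks a perfect separator first and respects the cap", {
  set.seed(6)
  n <- 16
  y <- rep(c(-1, 1), each = n / 2)
  X <- cbind(y + rnorm(n, 0, 1e-3), matrix(rnorm(n * 20), n, 20))
  fit <- swlda_select(X, y)
  expect_equal(fit$selected[1], 1)
  expect_lte(length(fit$selected), n)
  # max_features equal to the training count is never exceeded
  set.seed(7)
  Xn <- matrix(rnorm(8 * 60), 8, 60)
  yn <- rep(c(-1, 1), 4)
  expect_lte(length(swlda_select(Xn, yn, alpha_in = 0.9, alpha_out = 0.95)$selected), 8)
})

test_that("stepwise selection agrees with a naive lm()-based reference", {
  for (s in 1:25) {
    set.seed(100 + s)
    n <- 14
    X <- matrix(rnorm(n * 15), n, 15)
    y <- rep(c(-1, 1), length.out = n)
    fit <- swlda_select(X, y, max_features = 6)
    ref <- naive_stepwise(X, y, max_features = 6)
    expect_equal(fit$selected, ref)
  }
})

test_that("no feature passing alpha_in returns an empty selection, not an error", {
  set.seed(8)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rep(c(-1, 1), 5)
  fit <- swlda_select(X, y, alpha_in = 1e-9)
  expect_equal(fit$status, "empty")
  expect_length(fit$selected, 0)
  expect_true(all(predict(fit, X) == fit$majority))
})

test_that("linear-SVM weights obey the primal algebra", {
  set.seed(9)
  blob <- two_blobs(n_per = 8, d = 6)
  X <- cbind(blob$X, matrix(rnorm(16 * 3), 16, 3), 0)  # last column all zero
  prov <- data.frame(channel = "C3",
                     band = rep(c("theta", "alpha"), each = 5),
                     window = 1:10)
  m <- train_svm(X, blob$y, svm_params(kernel = "linear"))
  rep_ <- svm_weight_ranking(m, prov)
  expect_equal(rep_$weights$weight[10], 0)               # zero column
  expect_true(is.character(names(rep_$band_weights)))
  expect_equal(sum(rep_$band_weights), sum(rep_$weights$weight))
  expect_setequal(rep_$ranking, 1:10)                    # a permutation
  # duplicated columns receive identical weights (symmetry of the optimum)
  X2 <- cbind(X, X[, 1])
  m2 <- train_svm(X2, blob$y, svm_params(kernel = "linear"))
  w2 <- abs(crossprod(m2$sv, m2$coef))
  expect_equal(w2[1], w2[11], tolerance = 1e-6)
  # primal-weight algebra oracle: w agrees with an independent libsvm fit
  skip_if_not_installed("e1071")
  ref <- e1071::svm(X, factor(blob$y, levels = c(-1, 1)), kernel = "linear",
                    cost = 1, scale = FALSE, tolerance = 1e-7)
  w_ref <- abs(crossprod(ref$SV, -ref$coefs))     # first level is +1 in libsvm
  w_mine <- abs(crossprod(m$sv, m$coef))
  expect_lt(max(abs(w_mine - w_ref)), 1e-3)
  # weight reading requires a linear kernel
  mr <- train_svm(X, blob$y, svm_params(kernel = "rbf"))
  expect_error(svm_weight_ranking(mr, prov), "linear kernel")
})

test_that("band restriction keeps exactly the requested block and is idempotent", {
  fs <- toy_feature_set(n_windows = 3)
  br <- band_restrict(fs$X, fs$provenance, "theta")
  expect_equal(ncol(br$X), ncol(fs$X) / 5)
  expect_true(all(br$provenance$band == "theta"))
  br2 <- band_restrict(br$X, br$provenance, "theta")
  expect_identical(br2$X, br$X)
  expect_error(band_restrict(fs$X, fs$provenance, "mu"), "unknown band")
})

test_that("selectors are deterministic on refit (idempotent fit-transform)", {
  fs <- toy_feature_set(effect = 1, seed = 3)
  y <- fs$subjects$label
  for (method in c("pca", "wavelet", "band_restrict", "swlda")) {
    params <- switch(method, pca = list(k = 4),
                     band_restrict = list(band = "theta"), list())
    s1 <- fit_selector(method, fs$X, y, fs$provenance, params)
    s2 <- fit_selector(method, fs$X, y, fs$provenance, params)
    expect_equal(apply_selector(s1, fs$X), apply_selector(s2, fs$X))
  }
})
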
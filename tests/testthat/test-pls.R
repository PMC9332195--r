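test_that("a noiseless rank-1 problem is solved by one component", {
  set.seed(1)
  v <- rnorm(50); y <- rnorm(30)
  X <- outer(y, v)
  m <- fit_pls(X, y, 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-10)
})

test_that("full-rank PLS agrees with directly solved least squares", {
  set.seed(10)
  X <- matrix(rnorm(30 * 8), 30, 8)
  b <- rnorm(8)
  y <- drop(X %*% b)
  m <- fit_pls(X, y, 8)
  # independent oracle: normal equations on the centered problem
  Xc <- scale(X, center = TRUE, scale = FALSE)
  beta <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  ols <- drop(Xc %*% beta) + mean(y)
  expect_lt(max(abs(predict(m, X) - ols)), 1e-8)
})

test_that("centering makes the fit translation-invariant in y", {
  set.seed(11)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rnorm(40)
  m1 <- fit_pls(X, y, 4)
  m2 <- fit_pls(X, y + 5, 4)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
  expect_equal(m2$y_mean - m1$y_mean, 5, tolerance = 1e-12)
  # a spectrum equal to the training mean predicts the training mean response
  expect_equal(unname(predict(m1, matrix(m1$x_mean, 1))), mean(y),
               tolerance = 1e-10)
})

test_that("successive score vectors are orthogonal and training error is monotone", {
  set.seed(12)
  X <- matrix(rnorm(50 * 30), 50, 30)
  y <- rnorm(50)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  fit <- ramanpls:::nipals_pls1(Xc, y - mean(y), 8)
  # recompute scores by deflation to check mutual orthogonality
  T <- matrix(0, 50, 8)
  Xd <- Xc
  for (k in 1:8) {
    T[, k] <- Xd %*% fit$W[, k]
    Xd <- Xd - tcrossprod(T[, k], fit$P[, k])
  }
  G <- crossprod(T)
  off <- max(abs(G[upper.tri(G)])) / min(diag(G))
  expect_lt(off, 1e-8)

  rmses <- vapply(1:8, function(a) {
    m <- fit_pls(X, y, a)
    rmse(predict(m, X), y)
  }, numeric(1))
  expect_true(all(diff(rmses) <= 1e-10))
})

test_that("sample order does not affect the fitted model", {
  set.seed(13)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- rnorm(30)
  perm <- sample(30)
  m1 <- fit_pls(X, y, 5)
  m2 <- fit_pls(X[perm, ], y[perm], 5)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)
  expect_equal(predict(m1, X)[perm], predict(m2, X[perm, ]), tolerance = 1e-8)
})

test_that("degenerate fits are rejected", {
  set.seed(14)
  X <- matrix(rnorm(20 * 5), 20, 5)
  expect_error(fit_pls(X, rep(1, 20), 2), "zero-variance")
  # rank-1 X cannot support 3 components
  X1 <- outer(rnorm(20), rnorm(5))
  expect_error(fit_pls(X1, drop(X1[, 1]) + 0, 3), "supports only")
  expect_error(fit_pls(X, rnorm(20), 25), "n_lv")
})

test_that("cross-validation resolves the latent dimension of 2-factor data", {
  prob <- two_factor_problem()
  cv <- cv_config(folds = 5, max_lv = 6, seed = 99)
  curve <- cross_validate(prob$X, prob$y, prob$groups, cv)
  expect_true(all(is.finite(curve)) && all(curve >= 0))
  expect_lt(curve[2], 0.01 * curve[1])
  # determinism
  expect_identical(curve, cross_validate(prob$X, prob$y, prob$groups, cv))
  # too few groups
  expect_error(cross_validate(prob$X, prob$y, rep("g1", 40),
                              cv_config(folds = 5)), "groups")
})

test_that("the parsimony rule picks the smallest near-optimal LV count", {
  expect_identical(select_latent_variables(c(5, 2, 1, 1.001, 0.999)), 3L)
  expect_identical(select_latent_variables(c(9, 5, 1)), 3L)
  expect_identical(select_latent_variables(4.2), 1L)
  expect_error(select_latent_variables(numeric(0)), "empty")
})

test_that("train/test splits keep whole batches together", {
  prof <- quiet_profile()
  specs <- list(list(name = "s", profile = prof, n_batches = 10,
                     spectra_per_batch = 10))
  set <- generate_multisite_dataset(specs, seed = 8)$s
  sp <- split_train_test(set, 0.7, seed = 21)
  expect_identical(n_samples(sp$train), 70L)
  expect_identical(n_samples(sp$test), 30L)
  tb <- unique(sp$train$reference$batch_id)
  eb <- unique(sp$test$reference$batch_id)
  expect_length(intersect(tb, eb), 0)
  expect_setequal(c(tb, eb), unique(set$reference$batch_id))
  # reproducible under the same seed
  sp2 <- split_train_test(set, 0.7, seed = 21)
  expect_identical(rownames(sp$train$intensities), rownames(sp2$train$intensities))
  expect_error(split_train_test(set, 1.2), "fraction")
})

test_that("prediction refuses incompatible preprocessing", {
  dil <- generate_dilution_series(levels = c(20, 10, 5, 3), replicates = 3,
                                  seed = 6)
  std <- standardize_set(dil)
  pp <- preprocess_set(std)
  m <- fit_pls(pp$intensities, pp$reference$glucose_g_L, 2,
               analyte = "glucose", fingerprint = pp$fingerprint, grid = pp$grid)
  other <- preprocess_set(std, preprocess_config(sg_window = 21))
  expect_error(predict(m, other), "fingerprint")
  expect_error(predict(m, matrix(0, 2, 10)), "channel count")
})

test_that("serialized models reproduce predictions bit-identically", {
  set.seed(15)
  X <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  m <- fit_pls(X, y, 3, analyte = "glucose")
  f <- withr::local_tempfile(fileext = ".json")
  write_pls_model(m, f)
  m2 <- read_pls_model(f)
  expect_identical(predict(m, X), predict(m2, X))
  expect_identical(m2$n_lv, m$n_lv)
  expect_identical(m2$rmsecv, m$rmsecv)
})
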
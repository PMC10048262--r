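# Shared small fixture: informative low-dimensional regression problem.
model_fixture <- function(seed = 50, n = 60, p = 12) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% c(4, -3, 2, rep(0, p - 3))) + rnorm(n, sd = 0.2)
  list(X = X, y = y)
}

test_that("all three regressors satisfy the shared fit/predict contract", {
  fx <- model_fixture()
  for (name in c("plsr", "svr", "gbm")) {
    spec <- regressor_spec(name)
    fm <- fit_model(spec, fx$X, fx$y, seed = 3)
    yhat <- model_predict(fm, fx$X)
    expect_length(yhat, nrow(fx$X))
    expect_true(all(is.finite(yhat)))
    # row equivariance
    perm <- sample(nrow(fx$X))
    expect_equal(model_predict(fm, fx$X[perm, ]), yhat[perm],
                 tolerance = 1e-12)
    # determinism under refit with the same seed
    fm2 <- fit_model(spec, fx$X, fx$y, seed = 3)
    expect_equal(model_predict(fm2, fx$X), yhat, tolerance = 1e-10)
    # dimension mismatch rejected
    expect_error(model_predict(fm, fx$X[, 1:5]), "columns")
  }
})

test_that("variable masks restrict training and prediction consistently", {
  fx <- model_fixture(51)
  mask <- c(1, 2, 3, 7)
  fm <- fit_model(regressor_spec("plsr", components = 3), fx$X, fx$y,
                  variables = mask)
  full_width <- model_predict(fm, fx$X)
  masked_width <- model_predict(fm, fx$X[, mask])
  expect_equal(full_width, masked_width, tolerance = 1e-12)
  expect_error(fit_model(regressor_spec("plsr"), fx$X, fx$y,
                         variables = c(0, 5)), "out of range")
})

test_that("gbm on a constant response predicts that constant", {
  fx <- model_fixture(52)
  fm <- fit_model(regressor_spec("gbm"), fx$X, rep(7.5, nrow(fx$X)),
                  seed = 1)
  expect_equal(model_predict(fm, fx$X), rep(7.5, nrow(fx$X)),
               tolerance = 1e-6)
})

test_that("gbm training RMSE is non-increasing in the tree count", {
  fx <- model_fixture(53)
  rmse_at <- vapply(c(1, 10, 100), function(k) {
    fm <- fit_model(regressor_spec("gbm", n_estimators = k), fx$X, fx$y,
                    seed = 2)
    compute_metrics(fx$y, model_predict(fm, fx$X))$rmse
  }, numeric(1))
  expect_true(all(diff(rmse_at) <= 1e-10))
})

test_that("plsr at full rank matches the OLS oracle through fit_model", {
  fx <- linear_fixture(n = 25, p = 5, seed = 54)
  fm <- fit_model(regressor_spec("plsr", components = 5), fx$X, fx$y)
  ls <- ols_oracle(fx$X, fx$y)
  expect_equal(model_predict(fm, fx$X),
               as.numeric(cbind(1, fx$X) %*% ls), tolerance = 1e-8)
})

test_that("auto plsr picks its component count by cross-validation", {
  fx <- model_fixture(55)
  fm <- fit_model(regressor_spec("plsr"), fx$X, fx$y, seed = 9)
  expect_true(fm$fit$ncomp >= 1)
  r2 <- compute_metrics(fx$y, model_predict(fm, fx$X))$r_squared
  expect_gte(r2, 0.95)
})

test_that("gbm importance is a normalized distribution peaking on signal", {
  ok <- 0
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(80 * 10), 80, 10)
    y <- 5 * X[, 4] + rnorm(80, sd = 0.1)
    fm <- fit_model(regressor_spec("gbm"), X, y, seed = s)
    imp <- gbm_importance(fm)
    expect_true(all(imp$importance >= 0))
    expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
    expect_false(imp$degenerate)
    ok <- ok + as.numeric(which.max(imp$importance) == 4)
  }
  expect_equal(ok, 5)
})

test_that("importance of a splitless model is flagged uniform", {
  fx <- model_fixture(56)
  fm <- fit_model(regressor_spec("gbm"), fx$X, rep(1, nrow(fx$X)),
                  seed = 1)
  imp <- gbm_importance(fm)
  expect_true(imp$degenerate)
  expect_equal(unname(imp$importance),
               rep(1 / ncol(fx$X), ncol(fx$X)))
  expect_error(gbm_importance(fit_model(regressor_spec("plsr",
                                                       components = 2),
                                        fx$X, fx$y)), "gbm")
})

test_that("fitted models survive a save/load round trip", {
  fx <- model_fixture(57)
  for (name in c("plsr", "svr", "gbm")) {
    fm <- fit_model(regressor_spec(name), fx$X, fx$y, seed = 6)
    path <- tempfile(fileext = ".rds")
    save_fitted_model(fm, path)
    back <- load_fitted_model(path)
    expect_equal(model_predict(back, fx$X), model_predict(fm, fx$X),
                 tolerance = 1e-12)
  }
})

test_that("unknown names and hyperparameters are rejected", {
  expect_error(regressor_spec("tree"), "arg")
  expect_error(regressor_spec("gbm", foo = 1), "unknown hyperparameter")
  expect_error(regressor_spec("gbm", boosting_type = "dart"), "gbdt")
})

test_that("every model reaches high accuracy on a noiseless fixture", {
  # four groups give the RBF support vectors enough concentration spread
  cfg <- noiseless_sim_config(
    n_groups = 4, n_per_group = 12,
    group_means = rbind(Cd = c(1, 20, 60, 90), Cu = c(3, 40, 100, 180),
                        Pb = c(1, 30, 80, 150)),
    group_sds = rbind(Cd = c(0.3, 3, 8, 9), Cu = c(1, 5, 8, 16),
                      Pb = c(0.2, 4, 7, 14)))
  ds <- generate_dataset(cfg, seed = 60)
  norm <- area_normalize(ds$spectra)
  y <- ds$concentrations$Cd_mgkg
  for (name in c("plsr", "svr", "gbm")) {
    fm <- fit_model(regressor_spec(name), norm$intensities, y, seed = 4)
    r2 <- compute_metrics(y, model_predict(fm, norm$intensities))$r_squared
    expect_gte(r2, 0.99)
  }
})
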
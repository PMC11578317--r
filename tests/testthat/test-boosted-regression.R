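# CART tree, residual boosting and the baseline regressors.

test_that("the stump fixture splits at 1.5 with pure leaves", {
  X <- matrix(c(0, 1, 2, 3), 4, 1)
  y <- c(0, 0, 1, 1)
  tr <- fit_tree(X, y, max_depth = 1L, min_samples_leaf = 1L)
  root <- tr$nodes[1, ]
  expect_equal(root$feature, 1L)
  expect_equal(root$threshold, 1.5)
  pred <- predict(tr, X)
  expect_equal(pred, y)
})

test_that("constant responses and depth 0 give a single mean leaf", {
  X <- matrix(rnorm(20), 10, 2)
  tr <- fit_tree(X, rep(2.5, 10))
  expect_equal(nrow(tr$nodes), 1L)
  expect_equal(tr$nodes$value[1], 2.5)
  y <- rnorm(10)
  tr0 <- fit_tree(X, y, max_depth = 0L)
  expect_equal(nrow(tr0$nodes), 1L)
  expect_equal(predict(tr0, X), rep(mean(y), 10))
})

test_that("the greedy split matches exhaustive search on small fixtures", {
  for (case in 1:40) {
    n <- sample(4:12, 1)
    d <- sample(1:3, 1)
    fx <- random_int_fixture(n, d, seed = 1000 + case)
    oracle <- oracle_best_split(fx$X, fx$y)
    if (is.null(oracle)) next
    tr <- fit_tree(fx$X, fx$y, max_depth = 1L)
    root <- tr$nodes[1, ]
    if (is.na(root$feature)) {
      # implementation refused to split: only legal when no split reduces SSE
      expect_lte(sum((fx$y - mean(fx$y))^2), oracle$sse + 1e-9)
      next
    }
    left <- fx$X[, root$feature] < root$threshold
    sse <- sum((fx$y[left] - mean(fx$y[left]))^2) +
           sum((fx$y[!left] - mean(fx$y[!left]))^2)
    expect_equal(sse, oracle$sse, tolerance = 1e-9)
    if (oracle_split_margin(fx$X, fx$y) > 1e-9) {
      expect_equal(root$feature, oracle$feature)
      expect_equal(root$threshold, oracle$threshold)
    }
  }
})

test_that("boosting matches a hand-run sequential-residual oracle", {
  X <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8,
                2, 1, 4, 3, 6, 5, 8, 7), 8, 2)
  y <- c(4.5, 4.7, 5.1, 5.0, 5.9, 6.1, 6.4, 6.6)
  model <- fit_gbdt(X, y, n_rounds = 3L, learning_rate = 0.5, max_depth = 2L)
  Xnew <- rbind(X, c(2.5, 2.5), c(7.5, 7.5))
  expect_equal(predict(model, Xnew),
               oracle_gbdt_predict(X, y, Xnew, 3L, 0.5, 2L),
               tolerance = 1e-9)
  expect_length(model$residuals, 3L)
  expect_equal(model$residuals[[1]], y - mean(y))
})

test_that("zero rounds predict the response mean everywhere", {
  fx <- smooth_xy(30)
  model <- fit_gbdt(fx$X, fx$y, n_rounds = 0L)
  expect_equal(predict(model, fx$X), rep(mean(fx$y), 30))
})

test_that("a full-rate deep single round interpolates distinct rows", {
  fx <- smooth_xy(15)
  model <- fit_gbdt(fx$X, fx$y, n_rounds = 1L, learning_rate = 1,
                    max_depth = 30L, min_samples_leaf = 1L)
  expect_equal(predict(model, fx$X), fx$y, tolerance = 1e-10)
})

test_that("training MSE is non-increasing over boosting rounds", {
  for (s in 1:3) {
    fx <- smooth_xy(40, noise_sd = 0.3, seed = s)
    model <- fit_gbdt(fx$X, fx$y, n_rounds = 25L)
    mse <- vapply(model$residuals, function(r) mean(r^2), 0.0)
    expect_true(all(diff(mse) <= 1e-12))
  }
})

test_that("invalid boosting parameters and shapes are rejected", {
  fx <- smooth_xy(10)
  expect_error(fit_gbdt(fx$X, fx$y[-1]), class = "ppg_validation_error")
  expect_error(fit_gbdt(fx$X, fx$y, learning_rate = 0),
               class = "ppg_validation_error")
  expect_error(fit_gbdt(fx$X, fx$y, n_rounds = -1),
               class = "ppg_validation_error")
  model <- fit_gbdt(fx$X, fx$y, n_rounds = 2L)
  expect_error(predict(model, fx$X[, 1:2]), class = "ppg_validation_error")
  expect_identical(predict(model, fx$X[0, , drop = FALSE]), numeric())
})

test_that("prediction clipping is off by default and bounded when on", {
  X <- matrix(1:6, 6, 1)
  y <- c(40, 40, 40, 40, 40, 40)
  model <- fit_gbdt(X, y, n_rounds = 1L)
  expect_equal(predict(model, X), y)
  expect_true(all(predict(model, X, clip = TRUE) <= 30))
})

test_that("linear and ridge baselines solve the normal equations", {
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3)
  beta <- c(1.5, -2, 0.5)
  y <- drop(2 + X %*% beta)
  lin <- fit_baseline("linear", X, y)
  expect_equal(lin$coefficients, c(2, beta), tolerance = 1e-8)
  ridge0 <- fit_baseline("ridge", X, y, params = list(lambda = 1e-10))
  expect_equal(predict(ridge0, X), predict(lin, X), tolerance = 1e-6)
  ridge <- fit_baseline("ridge", X, y, params = list(lambda = 5))
  expect_lt(sum(ridge$coefficients[-1]^2), sum(lin$coefficients[-1]^2))
})

test_that("knn with k = n predicts the global mean", {
  fx <- smooth_xy(12)
  knn <- fit_baseline("knn", fx$X, fx$y, params = list(k = 12L))
  expect_equal(predict(knn, fx$X), rep(mean(fx$y), 12))
})

test_that("unknown baseline names list the options", {
  fx <- smooth_xy(10)
  expect_error(fit_baseline("svm", fx$X, fx$y), "linear.*ridge.*knn",
               class = "ppg_validation_error")
})

test_that("deterministic models ignore training-row order", {
  fx <- smooth_xy(40, noise_sd = 0.1, seed = 4)
  perm <- sample(40)
  Xnew <- smooth_xy(10, seed = 5)$X
  for (nm in c("linear", "ridge", "knn")) {
    a <- fit_baseline(nm, fx$X, fx$y)
    b <- fit_baseline(nm, fx$X[perm, ], fx$y[perm])
    expect_equal(predict(a, Xnew), predict(b, Xnew), tolerance = 1e-9,
                 label = nm)
  }
  g1 <- fit_gbdt(fx$X, fx$y, n_rounds = 10L)
  g2 <- fit_gbdt(fx$X[perm, ], fx$y[perm], n_rounds = 10L)
  expect_equal(predict(g1, Xnew), predict(g2, Xnew), tolerance = 1e-9)
})

test_that("boosted models serialize to JSON and back", {
  fx <- smooth_xy(25, noise_sd = 0.1)
  model <- fit_gbdt(fx$X, fx$y, n_rounds = 5L)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path, seed = 3L)
  back <- read_model(path)
  expect_equal(predict(back, fx$X), predict(model, fx$X), tolerance = 1e-12)
})

test_that("affine personal calibration removes a constant offset", {
  fx <- smooth_xy(200, noise_sd = 0.02, seed = 6)
  model <- fit_gbdt(fx$X, fx$y, n_rounds = 150L)
  person <- smooth_xy(10, noise_sd = 0, seed = 7)
  person$y <- person$y + 1  # constant +1 mmol/L offset
  cal <- calibrate_personal(model, person$X, person$y, strategy = "affine")
  held <- smooth_xy(20, noise_sd = 0, seed = 8)
  err <- mean(predict(cal, held$X) - (held$y + 1))
  expect_lt(abs(err), 0.1)
})

test_that("one calibration pair fixes only the intercept", {
  fx <- smooth_xy(30, seed = 9)
  model <- fit_gbdt(fx$X, fx$y, n_rounds = 20L)
  cal <- calibrate_personal(model, fx$X[1, , drop = FALSE], fx$y[1] + 2,
                            strategy = "affine")
  expect_equal(cal$slope, 1)
  # an intercept-only correction maps the calibration point onto its target
  expect_equal(predict(cal, fx$X[1, , drop = FALSE]), fx$y[1] + 2)
  expect_error(calibrate_personal(model, fx$X[0, , drop = FALSE], numeric()),
               class = "ppg_validation_error")
})

test_that("boost-strategy calibration barely moves an in-distribution person", {
  fx <- smooth_xy(80, noise_sd = 0.1, seed = 10)
  model <- fit_gbdt(fx$X, fx$y, n_rounds = 80L)
  person <- smooth_xy(10, noise_sd = 0.1, seed = 11)
  cal <- calibrate_personal(model, person$X, person$y, strategy = "boost",
                            n_rounds = 10L)
  held <- smooth_xy(30, noise_sd = 0.1, seed = 12)
  mard <- function(m) compute_metrics(held$y, predict(m, held$X))$mard
  expect_lt(abs(mard(cal) - mard(model)), 1)
})
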
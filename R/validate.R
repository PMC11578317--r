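# Monte Carlo cross-validation, the model-comparison harness and
# aleatoric/epistemic uncertainty estimation.

# Accept either a feature data.frame (from extract_cohort_features) or a
# list(X, y); returns list(X = matrix, y = numeric).
as_xy <- function(dataset, use_p_features = TRUE) {
  if (is.list(dataset) && !is.data.frame(dataset) &&
      all(c("X", "y") %in% names(dataset)))
    return(list(X = as.matrix(dataset$X), y = dataset$y))
  if (!is.data.frame(dataset) || !"y_glucose" %in% names(dataset))
    ppg_stop("dataset must be a feature data.frame with 'y_glucose' or a list(X, y)",
             "ppg_validation_error")
  cols <- feature_names()
  if (use_p_features)
    cols <- c(cols, intersect(c("p_age", "p_sex", "p_height", "p_weight"),
                              names(dataset)))
  X <- as.matrix(dataset[, cols, drop = FALSE])
  keep <- colSums(is.na(X)) < nrow(X)
  X <- X[, keep, drop = FALSE]
  # impute remaining missing covariates with the column median
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- median(X[, j], na.rm = TRUE)
  }
  list(X = X, y = dataset$y_glucose)
}

#' Monte Carlo cross-validation
#'
#' `n_repeats` independent random train/test splits; the model named by
#' `spec` is refit on each training part and all error metrics are
#' computed on the held-out part. The summary reports the mean, minimum
#' and maximum MARD over repeats.
#'
#' @param dataset Feature data.frame (with `y_glucose`) or `list(X, y)`.
#' @param spec A [model_spec()].
#' @param n_repeats Number of random splits (>= 1).
#' @param test_fraction Held-out fraction in (0, 1).
#' @param seed Seed; identical seeds give identical splits and results.
#' @param use_p_features Include the subject covariates as predictors?
#' @return Object of class `mc_cv`: per-repeat `metrics` data.frame and
#'   `summary` list (`mard_mean`, `mard_min`, `mard_max`, ...).
#' @export
monte_carlo_cv <- function(dataset, spec = model_spec("gbdt"),
                           n_repeats = 50L, test_fraction = 0.2,
                           seed = NULL, use_p_features = TRUE) {
  if (n_repeats < 1L)
    ppg_stop("'n_repeats' must be >= 1", "ppg_validation_error")
  if (test_fraction <= 0 || test_fraction >= 1)
    ppg_stop("'test_fraction' must be in (0, 1)", "ppg_validation_error")
  dat <- as_xy(dataset, use_p_features)
  n <- length(dat$y)
  n_test <- round(test_fraction * n)
  if (n_test < 1L || n_test >= n)
    ppg_stop("test set would be empty (or the training set would be)",
             "ppg_validation_error")
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(n_repeats), function(r) {
    test <- sample.int(n, n_test)
    fit <- fit_model(spec, dat$X[-test, , drop = FALSE], dat$y[-test])
    m <- compute_metrics(dat$y[test], predict(fit, dat$X[test, , drop = FALSE]))
    data.frame(repeat_id = r, mse = m$mse, rmse = m$rmse, mae = m$mae,
               mard = m$mard, r2 = m$r2)
  })
  metrics <- do.call(rbind, reps)
  structure(list(
    metrics = metrics,
    summary = list(mard_mean = mean(metrics$mard),
                   mard_min = min(metrics$mard),
                   mard_max = max(metrics$mard),
                   rmse_mean = mean(metrics$rmse),
                   mae_mean = mean(metrics$mae),
                   r2_mean = mean(metrics$r2)),
    n_repeats = n_repeats, test_fraction = test_fraction, spec = spec),
    class = "mc_cv")
}

#' @export
print.mc_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<mc_cv> %d repeats (%.0f%% held out): average MARD %.2f%%, minimum %.2f%%, maximum %.2f%%\n",
              x$n_repeats, 100 * x$test_fraction,
              s$mard_mean, s$mard_min, s$mard_max))
  invisible(x)
}

#' K-fold cross-validated predictions
#'
#' Utility used by the acceptance pipeline: deterministic shuffled folds,
#' one held-out prediction per row.
#'
#' @param dataset Feature data.frame or `list(X, y)`.
#' @param spec A [model_spec()].
#' @param k Number of folds.
#' @param seed Seed for the fold shuffle.
#' @param use_p_features Include subject covariates?
#' @return list with `y_ref`, `y_pred` (aligned to the input rows) and
#'   `fold` assignments.
#' @export
kfold_predictions <- function(dataset, spec = model_spec("gbdt"), k = 5L,
                              seed = NULL, use_p_features = TRUE) {
  dat <- as_xy(dataset, use_p_features)
  n <- length(dat$y)
  if (k < 2L || k > n)
    ppg_stop("'k' must be between 2 and n", "ppg_validation_error")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    fit <- fit_model(spec, dat$X[-test, , drop = FALSE], dat$y[-test])
    pred[test] <- predict(fit, dat$X[test, , drop = FALSE])
  }
  list(y_ref = dat$y, y_pred = pred, fold = fold)
}

#' Compare regression models on one held-out split
#'
#' Fits every implemented model on a common training part and reports MSE,
#' RMSE, MAE, MARD and R-squared on the held-out part. Models from the
#' wider comparison whose details are not implementable (CNN, SVM,
#' AdaBoost, extra-trees) appear as all-`NA` rows so the table shape is
#' complete.
#'
#' @param dataset Feature data.frame or `list(X, y)` with >= 20 rows.
#' @param test_fraction Held-out fraction.
#' @param seed Seed for the split and the resampling models.
#' @param use_p_features Include subject covariates?
#' @return data.frame with one row per model and the five metric columns.
#' @export
benchmark_models <- function(dataset, test_fraction = 0.25, seed = NULL,
                             use_p_features = TRUE) {
  dat <- as_xy(dataset, use_p_features)
  n <- length(dat$y)
  if (n < 20L)
    ppg_stop("benchmark needs >= 20 rows", "ppg_validation_error")
  if (!is.null(seed)) set.seed(seed)
  test <- sample.int(n, max(1L, round(test_fraction * n)))
  Xtr <- dat$X[-test, , drop = FALSE]; ytr <- dat$y[-test]
  Xte <- dat$X[test, , drop = FALSE]; yte <- dat$y[test]
  implemented <- c("gbdt", BASELINE_NAMES)
  seeds <- derive_seeds(if (is.null(seed)) 1L else seed, length(implemented))
  rows <- lapply(seq_along(implemented), function(i) {
    nm <- implemented[i]
    fit <- fit_model(model_spec(nm), Xtr, ytr, seed = seeds[[i]])
    m <- compute_metrics(yte, predict(fit, Xte))
    data.frame(model = nm, mse = m$mse, rmse = m$rmse, mae = m$mae,
               mard = m$mard, r2 = m$r2)
  })
  absent <- data.frame(model = c("svm", "adaboost", "etr", "cnn"),
                       mse = NA_real_, rmse = NA_real_, mae = NA_real_,
                       mard = NA_real_, r2 = NA_real_)
  rbind(do.call(rbind, rows), absent)
}

#' Aleatoric and epistemic uncertainty of a model on a dataset
#'
#' Epistemic uncertainty (model-knowledge spread) is the mean over data
#' points of the standard deviation of predictions across an ensemble of
#' `n_ensemble` models trained on bootstrap resamples. Aleatoric
#' uncertainty (data-inherent variability) is summarized from Monte Carlo
#' cross-validation: for every point tested in at least two repeats, the
#' standard deviation of its held-out residuals is computed, and the mean
#' and spread of those per-point values are reported (mean +/- sd,
#' mmol/L).
#'
#' @param dataset Feature data.frame or `list(X, y)`.
#' @param spec A [model_spec()].
#' @param n_ensemble Bootstrap ensemble size (>= 2).
#' @param n_repeats MC-CV repeats feeding the aleatoric estimate.
#' @param test_fraction MC-CV held-out fraction.
#' @param seed Seed.
#' @param use_p_features Include subject covariates?
#' @return Object of class `uncertainty_report`: `aleatoric_mean`,
#'   `aleatoric_sd`, `epistemic` (all mmol/L, non-negative).
#' @export
estimate_uncertainty <- function(dataset, spec = model_spec("gbdt"),
                                 n_ensemble = 20L, n_repeats = 30L,
                                 test_fraction = 0.2, seed = NULL,
                                 use_p_features = TRUE) {
  if (n_ensemble < 2L)
    ppg_stop("'n_ensemble' must be >= 2", "ppg_validation_error")
  dat <- as_xy(dataset, use_p_features)
  n <- length(dat$y)
  if (!is.null(seed)) set.seed(seed)

  # epistemic: bootstrap ensemble spread
  preds <- matrix(NA_real_, n, n_ensemble)
  for (b in seq_len(n_ensemble)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- fit_model(spec, dat$X[idx, , drop = FALSE], dat$y[idx])
    preds[, b] <- predict(fit, dat$X)
  }
  epistemic <- mean(apply(preds, 1L, sd))

  # aleatoric: per-point held-out residual variability across MC-CV repeats
  n_test <- max(1L, round(test_fraction * n))
  resid <- vector("list", n)
  for (r in seq_len(n_repeats)) {
    test <- sample.int(n, n_test)
    fit <- fit_model(spec, dat$X[-test, , drop = FALSE], dat$y[-test])
    e <- predict(fit, dat$X[test, , drop = FALSE]) - dat$y[test]
    for (j in seq_along(test))
      resid[[test[j]]] <- c(resid[[test[j]]], e[j])
  }
  per_point <- vapply(resid, function(v)
    if (length(v) >= 2L) sd(v) else NA_real_, 0.0)
  per_point <- per_point[!is.na(per_point)]
  structure(list(aleatoric_mean = mean(per_point),
                 aleatoric_sd = sd(per_point),
                 epistemic = epistemic,
                 n_points = length(per_point),
                 n_ensemble = n_ensemble, n_repeats = n_repeats),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("<uncertainty_report> aleatoric %.3f +/- %.3f mmol/L, epistemic %.3f mmol/L\n",
              x$aleatoric_mean, x$aleatoric_sd, x$epistemic))
  invisible(x)
}
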
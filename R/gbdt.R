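# Residual-boosting tree ensemble: F_0 = mean(y); each round fits a tree to
# the current residuals and the model advances by a learning-rate step.

#' Fit a gradient-boosted decision-tree regressor
#'
#' `F_0 = mean(y)`; for `k = 1 ... n_rounds` a regression tree `T_k` is fit
#' to the residuals `r_k = y - F_{k-1}(X)` and `F_k = F_{k-1} +
#' learning_rate * T_k`. The per-round residual vectors are retained for
#' diagnostics. Training MSE is non-increasing in the round number for any
#' learning rate in (0, 1].
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response (glucose, mmol/L).
#' @param n_rounds Number of boosting rounds N (>= 0; 0 predicts `mean(y)`).
#' @param learning_rate Shrinkage in (0, 1].
#' @param max_depth,min_samples_leaf Weak-learner tree limits.
#' @return Object of class `ppg_gbdt`: `f0`, `trees`, `learning_rate`,
#'   `residuals` (list of length `n_rounds`), `feature_names`.
#' @export
fit_gbdt <- function(X, y, n_rounds = 200L, learning_rate = 0.1,
                     max_depth = 3L, min_samples_leaf = 2L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    ppg_stop("X and y lengths differ", "ppg_validation_error")
  if (!is.numeric(n_rounds) || length(n_rounds) != 1L || n_rounds < 0 ||
      n_rounds != round(n_rounds))
    ppg_stop("'n_rounds' must be a non-negative integer", "ppg_validation_error")
  if (!is.numeric(learning_rate) || length(learning_rate) != 1L ||
      learning_rate <= 0 || learning_rate > 1)
    ppg_stop("'learning_rate' must be in (0, 1]", "ppg_validation_error")
  f0 <- mean(y)
  fit <- rep(f0, length(y))
  trees <- vector("list", n_rounds)
  residuals <- vector("list", n_rounds)
  for (k in seq_len(n_rounds)) {
    r <- y - fit
    residuals[[k]] <- r
    trees[[k]] <- fit_tree(X, r, max_depth = max_depth,
                           min_samples_leaf = min_samples_leaf)
    fit <- fit + learning_rate * predict(trees[[k]], X)
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate,
                 n_rounds = as.integer(n_rounds),
                 max_depth = max_depth, min_samples_leaf = min_samples_leaf,
                 residuals = residuals,
                 feature_names = colnames(X)),
            class = "ppg_gbdt")
}

#' Predict glucose from a boosted model
#'
#' @param object A [fit_gbdt()] model (or one extended by
#'   [calibrate_personal()]).
#' @param newdata Feature matrix with the training feature count.
#' @param clip Clip predictions to `clip_range`? Default off.
#' @param clip_range Physiological clipping range, mmol/L.
#' @param ... Unused.
#' @return Numeric predictions (mmol/L).
#' @export
predict.ppg_gbdt <- function(object, newdata, clip = FALSE,
                             clip_range = c(2, 30), ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric())
  out <- rep(object$f0, nrow(newdata))
  for (tr in object$trees)
    out <- out + object$learning_rate * predict(tr, newdata)
  if (clip) out <- pmin(pmax(out, clip_range[1]), clip_range[2])
  out
}

#' Personalize a population model with a few calibration pairs
#'
#' Default strategy `"boost"` freezes the population trees and fits
#' additional boosting rounds on the person's residuals. Strategy
#' `"affine"` fits an output correction `y = a + b * y_hat` on the k pairs
#' (with `k = 1` the slope is fixed at 1 and only the intercept is
#' corrected).
#'
#' @param model A fitted [fit_gbdt()] model.
#' @param X,y The person's k >= 1 calibration rows and reference values.
#' @param strategy `"boost"` or `"affine"`.
#' @param n_rounds Extra boosting rounds for `"boost"`.
#' @param learning_rate Learning rate for the extra rounds (defaults to the
#'   model's own).
#' @return A personalized model (`ppg_gbdt` for `"boost"`,
#'   `ppg_calibrated` wrapper for `"affine"`).
#' @export
calibrate_personal <- function(model, X, y,
                               strategy = c("boost", "affine"),
                               n_rounds = 25L, learning_rate = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(model, "ppg_gbdt"))
  X <- as.matrix(X)
  if (length(y) < 1L || nrow(X) != length(y))
    ppg_stop("calibration needs k >= 1 (X, y) pairs", "ppg_validation_error")
  if (strategy == "boost") {
    lr <- if (is.null(learning_rate)) model$learning_rate else learning_rate
    fit <- predict(model, X)
    new <- model
    for (k in seq_len(n_rounds)) {
      r <- y - fit
      tr <- fit_tree(X, r, max_depth = model$max_depth,
                     min_samples_leaf = min(model$min_samples_leaf,
                                            max(1L, floor(length(y) / 2))))
      # extra rounds share the model's learning rate so prediction stays
      # F0 + lr * sum(trees)
      new$trees <- c(new$trees, list(tr))
      fit <- fit + model$learning_rate * predict(tr, X)
    }
    new$n_rounds <- length(new$trees)
    new
  } else {
    pred <- predict(model, X)
    if (length(y) == 1L) {
      a <- y - pred; b <- 1
    } else if (sd(pred) == 0) {
      a <- mean(y) - mean(pred); b <- 1
    } else {
      b <- cov(pred, y) / var(pred)
      a <- mean(y) - b * mean(pred)
    }
    structure(list(base = model, intercept = a, slope = b),
              class = "ppg_calibrated")
  }
}

#' @export
predict.ppg_calibrated <- function(object, newdata, ...) {
  object$intercept + object$slope * predict(object$base, newdata, ...)
}

#' Serialize a boosted model to JSON
#'
#' Trees are written as nested node tables with metadata (package version,
#' feature names). [read_model()] restores an equivalent model.
#'
#' @param model A `ppg_gbdt`.
#' @param path Output path.
#' @param seed Optional seed to record in the metadata.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, seed = NULL) {
  stopifnot(inherits(model, "ppg_gbdt"))
  obj <- list(
    format = "ppgglucose_gbdt",
    version = as.character(utils::packageVersion("ppgglucose")),
    seed = seed,
    f0 = model$f0, learning_rate = model$learning_rate,
    n_rounds = model$n_rounds, max_depth = model$max_depth,
    min_samples_leaf = model$min_samples_leaf,
    feature_names = model$feature_names,
    trees = lapply(model$trees, function(tr)
      list(n_features = tr$n_features, nodes = tr$nodes)))
  write_json_canonical(obj, path)
}

#' Restore a boosted model written by [write_model()]
#' @param path JSON path.
#' @return A `ppg_gbdt` model.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "ppgglucose_gbdt"))
    ppg_stop("not a ppgglucose model file", "ppg_parse_error")
  num <- function(x) vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0.0)
  trees <- lapply(obj$trees, function(tr) {
    nodes <- data.frame(
      feature = as.integer(num(lapply(tr$nodes, `[[`, "feature"))),
      threshold = num(lapply(tr$nodes, `[[`, "threshold")),
      left = as.integer(num(lapply(tr$nodes, `[[`, "left"))),
      right = as.integer(num(lapply(tr$nodes, `[[`, "right"))),
      value = num(lapply(tr$nodes, `[[`, "value")),
      n = as.integer(num(lapply(tr$nodes, `[[`, "n"))))
    structure(list(nodes = nodes, n_features = tr$n_features,
                   max_depth = obj$max_depth,
                   min_samples_leaf = obj$min_samples_leaf),
              class = "ppg_tree")
  })
  structure(list(f0 = obj$f0, trees = trees,
                 learning_rate = obj$learning_rate,
                 n_rounds = obj$n_rounds, max_depth = obj$max_depth,
                 min_samples_leaf = obj$min_samples_leaf,
                 residuals = NULL,
                 feature_names = unlist(obj$feature_names)),
            class = "ppg_gbdt")
}
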
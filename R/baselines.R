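# Baseline regressors for the model-comparison harness: linear and ridge
# via normal equations, k-nearest-neighbours, a single tree, bagged trees
# and a random forest. All are from scratch on top of fit_tree().

BASELINE_NAMES <- c("linear", "ridge", "knn", "dtr", "rfr", "bagging")

#' Fit a baseline regressor
#'
#' * `linear`, `ridge`: normal equations, ridge penalizing all non-intercept
#'   coefficients with `lambda`.
#' * `knn`: mean response of the `k` nearest training rows by Euclidean
#'   distance, distance ties broken by training-row order.
#' * `dtr`: a single [fit_tree()] (default depth 6).
#' * `bagging`: `n_trees` trees on bootstrap resamples.
#' * `rfr`: bagging plus `mtry = floor(sqrt(d))` feature sampling per split.
#'
#' @param name One of `"linear"`, `"ridge"`, `"knn"`, `"dtr"`, `"rfr"`,
#'   `"bagging"`.
#' @param X,y Training features and response.
#' @param params Named list of hyperparameters (`lambda`, `k`, `max_depth`,
#'   `min_samples_leaf`, `n_trees`, `mtry`).
#' @param seed Seed for the bootstrap/feature sampling models.
#' @return A fitted model with a `predict()` method.
#' @export
fit_baseline <- function(name, X, y, params = list(), seed = NULL) {
  if (!is.character(name) || length(name) != 1L || !name %in% BASELINE_NAMES)
    ppg_stop(sprintf("unknown baseline '%s'; options: %s",
                     paste(name, collapse = ","),
                     paste(BASELINE_NAMES, collapse = ", ")),
             "ppg_validation_error")
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    ppg_stop("X and y lengths differ", "ppg_validation_error")
  p <- function(key, default) if (!is.null(params[[key]])) params[[key]] else default
  if (!is.null(seed)) set.seed(seed)
  switch(name,
    linear = fit_linear(X, y, lambda = 0),
    ridge = fit_linear(X, y, lambda = p("lambda", 1)),
    knn = structure(list(X = X, y = y, k = p("k", 5L)), class = "ppg_knn"),
    dtr = fit_tree(X, y, max_depth = p("max_depth", 6L),
                   min_samples_leaf = p("min_samples_leaf", 2L)),
    rfr = fit_forest(X, y, n_trees = p("n_trees", 100L),
                     max_depth = p("max_depth", 8L),
                     min_samples_leaf = p("min_samples_leaf", 2L),
                     mtry = p("mtry", max(1L, floor(sqrt(ncol(X)))))),
    bagging = fit_forest(X, y, n_trees = p("n_trees", 100L),
                         max_depth = p("max_depth", 8L),
                         min_samples_leaf = p("min_samples_leaf", 2L),
                         mtry = NULL))
}

fit_linear <- function(X, y, lambda = 0) {
  Xb <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, ncol(X))), ncol(Xb))
  beta <- tryCatch(
    solve(crossprod(Xb) + pen, crossprod(Xb, y)),
    error = function(e) {
      # rank-deficient design (e.g. constant covariates in a single-subject
      # cohort): pivoted least squares, dropped directions get coefficient 0
      b <- qr.coef(qr(Xb), y)
      b[is.na(b)] <- 0
      b
    })
  structure(list(coefficients = as.vector(beta), lambda = lambda,
                 n_features = ncol(X)),
            class = "ppg_linear")
}

#' @export
predict.ppg_linear <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric())
  if (ncol(newdata) != object$n_features)
    ppg_stop("feature count differs from training", "ppg_validation_error")
  as.vector(cbind(1, newdata) %*% object$coefficients)
}

#' @export
predict.ppg_knn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric())
  if (ncol(newdata) != ncol(object$X))
    ppg_stop("feature count differs from training", "ppg_validation_error")
  k <- min(object$k, nrow(object$X))
  vapply(seq_len(nrow(newdata)), function(i) {
    d2 <- colSums((t(object$X) - newdata[i, ])^2)
    mean(object$y[order(d2, seq_along(d2))[seq_len(k)]])
  }, 0.0)
}

fit_forest <- function(X, y, n_trees, max_depth, min_samples_leaf, mtry) {
  n <- nrow(X)
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_tree(X[idx, , drop = FALSE], y[idx], max_depth = max_depth,
             min_samples_leaf = min_samples_leaf, mtry = mtry)
  })
  structure(list(trees = trees, n_features = ncol(X), mtry = mtry),
            class = "ppg_forest")
}

#' @export
predict.ppg_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric())
  preds <- vapply(object$trees, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  if (is.matrix(preds)) rowMeans(preds) else mean(preds)
}

#' Model specification used by the evaluation harness
#'
#' @param name `"gbdt"` or a [fit_baseline()] name.
#' @param params Hyperparameter list.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name = "gbdt", params = list()) {
  if (!name %in% c("gbdt", BASELINE_NAMES))
    ppg_stop(sprintf("unknown model '%s'; options: %s", name,
                     paste(c("gbdt", BASELINE_NAMES), collapse = ", ")),
             "ppg_validation_error")
  structure(list(name = name, params = params), class = "model_spec")
}

# Fit any model named by a model_spec (seed only matters for the
# resampling-based models).
fit_model <- function(spec, X, y, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$name == "gbdt") {
    p <- spec$params
    g <- function(key, default) if (!is.null(p[[key]])) p[[key]] else default
    fit_gbdt(X, y, n_rounds = g("n_rounds", 200L),
             learning_rate = g("learning_rate", 0.1),
             max_depth = g("max_depth", 3L),
             min_samples_leaf = g("min_samples_leaf", 2L))
  } else {
    fit_baseline(spec$name, X, y, spec$params, seed = seed)
  }
}
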
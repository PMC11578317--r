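# From-scratch CART regression tree: greedy variance-reduction splits over
# all (feature, midpoint-threshold) candidates, deterministic tie-breaking.

# Best split at a node. Maximizing sum_L^2/n_L + sum_R^2/n_R is equivalent
# to maximizing variance reduction (the parent term is constant). Ties are
# broken by lowest feature index, then lowest threshold (which.max over a
# sorted axis returns the first, i.e. lowest, threshold; features are
# scanned in ascending order and only a strictly better score replaces the
# incumbent).
best_split <- function(X, y, min_samples_leaf, features) {
  n <- length(y)
  best <- NULL
  for (j in features) {
    xj <- X[, j]
    o <- order(xj, method = "radix")
    xs <- xj[o]; ys <- y[o]
    cs <- cumsum(ys)
    nl <- seq_len(n - 1L)
    ok <- (xs[-1L] != xs[-n]) & nl >= min_samples_leaf &
      (n - nl) >= min_samples_leaf
    if (!any(ok)) next
    score <- cs[nl]^2 / nl + (cs[n] - cs[nl])^2 / (n - nl)
    score[!ok] <- -Inf
    i <- which.max(score)
    if (is.null(best) || score[i] > best$score)
      best <- list(feature = j, threshold = (xs[i] + xs[i + 1L]) / 2,
                   score = score[i])
  }
  best
}

#' Fit a CART regression tree
#'
#' Greedy binary splits maximizing variance reduction, candidate thresholds
#' at midpoints between consecutive sorted unique values, ties broken by
#' lowest feature index then lowest threshold. Splitting stops at the depth
#' or leaf-size limits or at zero-variance nodes; every leaf stores the
#' mean of its training responses.
#'
#' @param X Numeric matrix (n x d) of features.
#' @param y Numeric response vector of length n.
#' @param max_depth Maximum tree depth (0 gives a single leaf).
#' @param min_samples_leaf Minimum rows in each child.
#' @param mtry Number of features sampled (without replacement) per split;
#'   `NULL` considers all features (random-forest-style subspace sampling
#'   when set).
#' @return Object of class `ppg_tree` (node table).
#' @export
fit_tree <- function(X, y, max_depth = 3L, min_samples_leaf = 2L,
                     mtry = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    ppg_stop("X and y lengths differ", "ppg_validation_error")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    ppg_stop("X and y must be finite", "ppg_validation_error")
  d <- ncol(X)
  nodes <- list()

  grow <- function(idx, depth) {
    id <- length(nodes) + 1L
    yi <- y[idx]
    node <- list(id = id, feature = NA_integer_, threshold = NA_real_,
                 left = NA_integer_, right = NA_integer_,
                 value = mean(yi), n = length(idx))
    nodes[[id]] <<- node
    pure <- (max(yi) - min(yi)) <= 1e-12
    if (depth >= max_depth || length(idx) < 2L * min_samples_leaf || pure)
      return(id)
    feats <- if (is.null(mtry)) seq_len(d)
             else sort(sample.int(d, min(mtry, d)))
    sp <- best_split(X[idx, , drop = FALSE], yi, min_samples_leaf, feats)
    if (is.null(sp)) return(id)
    go_left <- X[idx, sp$feature] < sp$threshold
    nodes[[id]]$feature <<- sp$feature
    nodes[[id]]$threshold <<- sp$threshold
    nodes[[id]]$left <<- grow(idx[go_left], depth + 1L)
    nodes[[id]]$right <<- grow(idx[!go_left], depth + 1L)
    id
  }
  grow(seq_along(y), 0L)
  tab <- do.call(rbind, lapply(nodes, function(nd)
    data.frame(feature = nd$feature, threshold = nd$threshold,
               left = nd$left, right = nd$right, value = nd$value, n = nd$n)))
  structure(list(nodes = tab, n_features = d,
                 max_depth = max_depth, min_samples_leaf = min_samples_leaf),
            class = "ppg_tree")
}

#' Predict from a regression tree
#' @param object A [fit_tree()] model.
#' @param newdata Numeric matrix with the training feature count.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.ppg_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric())
  if (ncol(newdata) != object$n_features)
    ppg_stop("feature count differs from training", "ppg_validation_error")
  nd <- object$nodes
  feat <- nd$feature; thr <- nd$threshold
  left <- nd$left; right <- nd$right; val <- nd$value
  vapply(seq_len(nrow(newdata)), function(i) {
    k <- 1L
    while (!is.na(feat[k]))
      k <- if (newdata[i, feat[k]] < thr[k]) left[k] else right[k]
    val[k]
  }, 0.0)
}
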
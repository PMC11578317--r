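# Independent oracles, written against the definitions (not the package
# code paths), used to cross-check the tree learner, the boosting loop and
# the Clarke grid.

# Exhaustive best split: every feature, every midpoint between consecutive
# sorted distinct values; minimizes total child SSE; ties prefer the lowest
# feature index, then the lowest threshold.
oracle_best_split <- function(X, y, min_samples_leaf = 2L) {
  best <- NULL
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2L) next
    for (i in seq_len(length(vals) - 1L)) {
      thr <- (vals[i] + vals[i + 1L]) / 2
      left <- X[, j] < thr
      if (sum(left) < min_samples_leaf || sum(!left) < min_samples_leaf) next
      s <- sse(y[left]) + sse(y[!left])
      if (is.null(best) || s < best$sse - 1e-12 ||
          (abs(s - best$sse) <= 1e-12 &&
           (j < best$feature ||
            (j == best$feature && thr < best$threshold)))) {
        best <- list(feature = j, threshold = thr, sse = s)
      }
    }
  }
  best
}

# How many candidate splits tie with the best (within tolerance)? Used to
# decide whether the oracle pick is unique enough to compare coordinates.
oracle_split_margin <- function(X, y, min_samples_leaf = 2L) {
  sses <- c()
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2L) next
    for (i in seq_len(length(vals) - 1L)) {
      thr <- (vals[i] + vals[i + 1L]) / 2
      left <- X[, j] < thr
      if (sum(left) < min_samples_leaf || sum(!left) < min_samples_leaf) next
      sses <- c(sses, sse(y[left]) + sse(y[!left]))
    }
  }
  if (length(sses) < 2L) return(Inf)
  s <- sort(sses)
  s[2] - s[1]
}

# Plain recursive exhaustive-search regression tree (list-of-lists form).
oracle_fit_tree <- function(X, y, max_depth, min_samples_leaf = 2L) {
  if (max_depth <= 0L || length(y) < 2L * min_samples_leaf ||
      (max(y) - min(y)) <= 1e-12)
    return(list(leaf = TRUE, value = mean(y)))
  sp <- oracle_best_split(X, y, min_samples_leaf)
  if (is.null(sp)) return(list(leaf = TRUE, value = mean(y)))
  left <- X[, sp$feature] < sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       l = oracle_fit_tree(X[left, , drop = FALSE], y[left],
                           max_depth - 1L, min_samples_leaf),
       r = oracle_fit_tree(X[!left, , drop = FALSE], y[!left],
                           max_depth - 1L, min_samples_leaf))
}

oracle_tree_predict <- function(tree, X) {
  one <- function(node, x) {
    while (!node$leaf)
      node <- if (x[node$feature] < node$threshold) node$l else node$r
    node$value
  }
  apply(X, 1L, one, node = tree)
}

# Hand-run sequential-residual boosting loop on top of the oracle tree.
oracle_gbdt_predict <- function(X, y, Xnew, n_rounds, learning_rate,
                                max_depth, min_samples_leaf = 2L) {
  fit <- rep(mean(y), length(y))
  out <- rep(mean(y), nrow(Xnew))
  for (k in seq_len(n_rounds)) {
    tr <- oracle_fit_tree(X, y - fit, max_depth, min_samples_leaf)
    fit <- fit + learning_rate * oracle_tree_predict(tr, X)
    out <- out + learning_rate * oracle_tree_predict(tr, Xnew)
  }
  out
}

# Independent transcription of the 1987 Clarke grid inequalities (mg/dL),
# structured as the widely circulated reference implementation: checks in
# the order A, E, C, D with non-strict region bounds, else B. Agrees with
# the package everywhere off the region boundaries.
oracle_clarke_mgdl <- function(x, y) {
  if ((x <= 70 && y <= 70) || (y <= 1.2 * x && y >= 0.8 * x)) return("A")
  if ((x >= 180 && y <= 70) || (x <= 70 && y >= 180)) return("E")
  if ((x >= 70 && x <= 290 && y >= x + 110) ||
      (x >= 130 && x <= 180 && y <= (7 / 5) * x - 182)) return("C")
  if ((x >= 240 && y >= 70 && y <= 180) ||
      (x <= 175 / 3 && y >= 70 && y <= 180) ||
      (x >= 175 / 3 && x <= 70 && y >= (6 / 5) * x)) return("D")
  "B"
}
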
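# Independent brute-force oracles, deliberately written as element-wise
# loops so they share no code path with the package implementations.

oracle_regression_metrics <- function(y, yhat) {
  n <- length(y)
  sse <- 0; sae <- 0; sre <- 0; ybar <- sum(y) / n
  for (i in seq_len(n)) {
    sse <- sse + (y[i] - yhat[i])^2
    sae <- sae + abs(y[i] - yhat[i])
    sre <- sre + abs(y[i] - yhat[i]) / abs(y[i])
  }
  sst <- 0
  for (i in seq_len(n)) sst <- sst + (y[i] - ybar)^2
  list(mre = sre / n, mse = sse / n, mae = sae / n, r2 = 1 - sse / sst)
}

oracle_classification_metrics <- function(y, yhat) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && yhat[i] == 1) tp <- tp + 1
    if (y[i] == 0 && yhat[i] == 1) fp <- fp + 1
    if (y[i] == 0 && yhat[i] == 0) tn <- tn + 1
    if (y[i] == 1 && yhat[i] == 0) fn <- fn + 1
  }
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       f1 = if (tp > 0) 2 * (tp / (tp + fp)) * (tp / (tp + fn)) /
              (tp / (tp + fp) + tp / (tp + fn)) else 0,
       fpr = if (tn + fp > 0) fp / (tn + fp) else 0,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# Mann-Whitney AUC over all positive-negative pairs, ties counted 1/2.
oracle_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    if (s[i] > s[j]) total <- total + 1
    else if (s[i] == s[j]) total <- total + 0.5
  }
  total / (length(pos) * length(neg))
}

# Phi via the correlation of reconstructed 0/1 vectors (an independent
# route: phi is the Pearson correlation of two binaries).
oracle_phi <- function(n11, n10, n01, n00) {
  a <- c(rep(1, n11), rep(1, n10), rep(0, n01), rep(0, n00))
  b <- c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00))
  suppressWarnings(cor(a, b))
}

# ---- brute-force Shapley for a parsed tree ensemble ---------------------

# Cover-weighted conditional expectation of one flattened tree given the
# feature subset S (indices into x) is known.
tree_cond_expect <- function(tr, node, x, S) {
  f <- tr$feature[node + 1]
  if (f < 0) return(tr$value[node + 1])
  l <- tr$left[node + 1]; r <- tr$right[node + 1]
  if ((f + 1) %in% S) {
    nxt <- if (x[f + 1] < tr$threshold[node + 1]) l else r
    tree_cond_expect(tr, nxt, x, S)
  } else {
    (tr$cover[l + 1] * tree_cond_expect(tr, l, x, S) +
       tr$cover[r + 1] * tree_cond_expect(tr, r, x, S)) / tr$cover[node + 1]
  }
}

# Exact Shapley values of an xgboost regressor for one sample, by
# enumerating all feature coalitions (feasible for p <= 4).
oracle_shapley <- function(model, x) {
  parsed <- qsarscreen:::parse_xgb_trees(model$fit, model$feature_names)
  p <- length(x)
  ntree <- length(parsed$tree_offset)
  slice_tree <- function(t) {
    from <- parsed$tree_offset[t] + 1
    to <- if (t < ntree) parsed$tree_offset[t + 1] else length(parsed$feature)
    lapply(parsed[c("feature", "threshold", "left", "right", "cover", "value")],
           function(v) v[from:to])
  }
  trees <- lapply(seq_len(ntree), slice_tree)
  v <- function(S) sum(vapply(trees, tree_cond_expect, numeric(1),
                              node = 0, x = x, S = S))
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  for (i in seq_len(p)) {
    for (S in subsets) {
      if (i %in% S) next
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[i] <- phi[i] + w * (v(c(S, i)) - v(S))
    }
  }
  list(phi = phi, base = v(integer(0)))
}

# Small named descriptor matrix of standard normals.
random_descriptors <- function(n, p, seed = 1, prefix = "D") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("CPD%04d", seq_len(n)),
                              sprintf("%s%03d", prefix, seq_len(p))))
  descriptor_matrix(m)
}
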
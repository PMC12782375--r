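# Versioned hyperparameter defaults and search spaces, one entry per
# regressor family. Defaults are the backends' published defaults (the
# histogram family mirrors the common leaf-wise booster defaults:
# 31 leaves, learning rate 0.1, 100 rounds).

#' Published-default hyperparameters per regressor family
#'
#' @param family a regressor family name.
#' @return named list of hyperparameters.
#' @export
default_hyperparams <- function(family) {
  switch(family,
    bagged_forest = list(num_trees = 500L, mtry_fraction = 1 / 3,
                         min_node_size = 5L),
    boosted_trees = list(nrounds = 100L, eta = 0.3, max_depth = 6L,
                         min_child_weight = 1, subsample = 1,
                         colsample_bytree = 1),
    hist_boosted_trees = list(nrounds = 100L, eta = 0.1, max_leaves = 31L,
                              max_depth = 6L, min_child_weight = 1,
                              subsample = 1, colsample_bytree = 1),
    cascade_forest = list(num_trees = 200L, max_layers = 4L,
                          early_stop_rounds = 1L),
    stop("unknown family: ", family))
}

# Draw one random candidate from the family's search space.
sample_hyperparams <- function(family) {
  runif_log <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  switch(family,
    bagged_forest = list(
      num_trees = sample(c(300L, 500L, 800L), 1L),
      mtry_fraction = sample(c(0.2, 1 / 3, 0.5, 0.8), 1L),
      min_node_size = sample(c(1L, 3L, 5L, 10L), 1L)),
    boosted_trees = list(
      nrounds = sample(50:400, 1L),
      eta = runif_log(0.01, 0.3),
      max_depth = sample(3:9, 1L),
      min_child_weight = runif_log(1, 10),
      subsample = runif(1, 0.6, 1),
      colsample_bytree = runif(1, 0.6, 1)),
    hist_boosted_trees = list(
      nrounds = sample(50:400, 1L),
      eta = runif_log(0.01, 0.3),
      max_leaves = sample(c(15L, 31L, 63L, 127L), 1L),
      max_depth = 6L,
      min_child_weight = runif_log(1, 10),
      subsample = runif(1, 0.6, 1),
      colsample_bytree = runif(1, 0.6, 1)),
    cascade_forest = list(
      num_trees = sample(c(100L, 200L, 300L), 1L),
      max_layers = sample(2:6, 1L),
      early_stop_rounds = 1L),
    stop("unknown family: ", family))
}

# Deterministic k-fold assignment of n rows.
make_folds <- function(n, folds, seed) {
  idx <- with_seed(seed, sample.int(n))
  split(idx, rep_len(seq_len(folds), n))
}

cv_score <- function(family, hp, X, y, fold_idx, metric, seed) {
  scores <- vapply(seq_along(fold_idx), function(i) {
    hold <- fold_idx[[i]]
    spec <- regressor_spec(family, hp, seed = fanout_seed(seed, i))
    fit <- fit_regressor(spec, X[-hold, , drop = FALSE], y[-hold])
    pred <- predict(fit, X[hold, , drop = FALSE])
    if (metric == "mse") mean((y[hold] - pred)^2)
    else mean(abs(y[hold] - pred) / abs(y[hold]))
  }, numeric(1))
  mean(scores)
}

#' Budgeted hyperparameter search with cross-validation
#'
#' Seeded random search over the family's declared space, scored by
#' k-fold cross-validated MSE (or MRE). Trial 1 always evaluates the
#' family's published defaults, so the tuned score can never be worse
#' than the default configuration's — tuning is monotone non-harmful.
#'
#' @param family a regressor family name.
#' @param X descriptor matrix (training partition).
#' @param y continuous target.
#' @param budget number of trials (>= 1); `budget = 1` returns the
#'   defaults.
#' @param folds number of cross-validation folds.
#' @param metric `"mse"` (default) or `"mre"`.
#' @param seed integer seed; drives the fold assignment and all candidate
#'   draws.
#' @return list with `best_hyperparams`, `best_score`, `default_score`,
#'   `trials` (data.frame of trial scores), `folds`, `metric`, `seed`.
#' @export
tune_hyperparameters <- function(family, X, y, budget = 100L, folds = 5L,
                                 metric = c("mse", "mre"), seed = 1L) {
  metric <- match.arg(metric)
  if (budget < 1L) stop("budget must be >= 1")
  if (folds < 2L) stop("folds must be >= 2")
  X <- as_plain_matrix(X)
  fold_idx <- make_folds(nrow(X), folds, fanout_seed(seed, 55L))
  candidates <- vector("list", budget)
  candidates[[1L]] <- default_hyperparams(family)
  if (budget > 1L)
    candidates[2:budget] <- with_seed(fanout_seed(seed, 56L),
      lapply(2:budget, function(i) sample_hyperparams(family)))
  scores <- vapply(seq_len(budget), function(i)
    cv_score(family, candidates[[i]], X, y, fold_idx, metric,
             seed = fanout_seed(seed, 200L + i)),
    numeric(1))
  best <- which.min(scores)
  list(best_hyperparams = candidates[[best]], best_score = scores[best],
       default_score = scores[1L],
       trials = data.frame(trial = seq_len(budget), score = scores),
       folds = as.integer(folds), metric = metric, seed = as.integer(seed))
}
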
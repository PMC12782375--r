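REGRESSOR_FAMILIES <- c("bagged_forest", "boosted_trees",
                        "hist_boosted_trees", "cascade_forest")

#' Specification of an ensemble regressor
#'
#' @param family one of `"bagged_forest"` (bootstrap-aggregated random
#'   forest), `"boosted_trees"` (depth-wise gradient boosting),
#'   `"hist_boosted_trees"` (histogram-binned, leaf-wise gradient
#'   boosting) or `"cascade_forest"` (layered forest cascade).
#' @param hyperparams named list overriding the family's published
#'   defaults (see [default_hyperparams()]).
#' @param seed integer seed; training is deterministic given the spec.
#' @return object of class `regressor_spec`.
#' @export
regressor_spec <- function(family = REGRESSOR_FAMILIES, hyperparams = list(),
                           seed = 1L) {
  family <- match.arg(family)
  hp <- modifyList(default_hyperparams(family), hyperparams)
  unknown <- setdiff(names(hyperparams), names(default_hyperparams(family)))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "))
  structure(list(family = family, hyperparams = hp, seed = as.integer(seed)),
            class = "regressor_spec")
}

as_plain_matrix <- function(X) {
  X <- unclass(X)
  storage.mode(X) <- "double"
  X
}

#' Fit an ensemble regression model
#'
#' Trains one of the four ensemble families on descriptors `X` against a
#' continuous target `y` (single-threaded, deterministic under
#' `spec$seed`). The returned handle supports [predict()].
#'
#' @param spec a [regressor_spec()].
#' @param X a [descriptor_matrix()] or numeric matrix with column names.
#' @param y numeric target, one value per row of `X`.
#' @return object of class `c("<family>", "qsar_regressor")`.
#' @export
fit_regressor <- function(spec, X, y) {
  if (!inherits(spec, "regressor_spec")) stop("spec must be a regressor_spec")
  if (nrow(X) != length(y)) stop("X rows must align with y")
  if (max(y) == min(y)) warning("target is constant; fitting anyway")
  X <- as_plain_matrix(X)
  hp <- spec$hyperparams
  fit <- switch(spec$family,
    bagged_forest = ranger::ranger(
      y = y, x = as.data.frame(X), num.trees = hp$num_trees,
      mtry = max(1L, floor(hp$mtry_fraction * ncol(X))),
      min.node.size = hp$min_node_size,
      seed = spec$seed, num.threads = 1L),
    boosted_trees = ,
    hist_boosted_trees = {
      params <- list(eta = hp$eta, max_depth = hp$max_depth,
                     min_child_weight = hp$min_child_weight,
                     subsample = hp$subsample,
                     colsample_bytree = hp$colsample_bytree,
                     nthread = 1L, seed = spec$seed,
                     objective = "reg:squarederror",
                     base_score = mean(y))
      if (spec$family == "hist_boosted_trees") {
        params$tree_method <- "hist"
        params$grow_policy <- "lossguide"
        params$max_leaves <- hp$max_leaves
        params$max_depth <- 0L  # leaf-wise growth, depth unbounded
      }
      xgboost::xgb.train(params, xgboost::xgb.DMatrix(X, label = y),
                         nrounds = hp$nrounds, verbose = 0L)
    },
    cascade_forest = fit_cascade_forest(
      X, y, layer_spec = list(num_trees = hp$num_trees),
      max_layers = hp$max_layers, early_stop_rounds = hp$early_stop_rounds,
      seed = spec$seed))
  structure(list(family = spec$family, fit = fit, spec = spec,
                 feature_names = colnames(X),
                 base_score = if (spec$family %in%
                                  c("boosted_trees", "hist_boosted_trees"))
                   mean(y) else NULL),
            class = "qsar_regressor")
}

# Align prediction input with the model's descriptor set.
align_features <- function(object, newdata) {
  newdata <- as_plain_matrix(newdata)
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss))
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
  newdata[, object$feature_names, drop = FALSE]
}

#' Predict from a fitted ensemble regressor
#'
#' @param object a `qsar_regressor` from [fit_regressor()].
#' @param newdata matrix or [descriptor_matrix()] carrying the model's
#'   descriptor columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.qsar_regressor <- function(object, newdata, ...) {
  X <- align_features(object, newdata)
  switch(object$family,
    bagged_forest = predict(object$fit, data = as.data.frame(X),
                            num.threads = 1L)$predictions,
    boosted_trees = ,
    hist_boosted_trees = predict(object$fit, X),
    cascade_forest = predict_cascade(object$fit, X))
}

#' @export
print.qsar_regressor <- function(x, ...) {
  cat("qsarscreen ensemble regressor:", x$family,
      "on", length(x$feature_names), "descriptors\n")
  invisible(x)
}

#' Compare feature sets under one regression configuration
#'
#' Fits the same regressor family with the same split and seed on each
#' named descriptor subset and reports test-set metrics, one row per set
#' (the design used to compare selection strategies).
#'
#' @param feature_sets named list of descriptor-name vectors.
#' @param X a [descriptor_matrix()] covering every listed descriptor.
#' @param y continuous target aligned with `X`.
#' @param spec a [regressor_spec()].
#' @param split a [split_train_test()] result; `NULL` draws an 8:2 split
#'   from `seed`.
#' @param seed integer seed.
#' @return data.frame with columns `feature_set`, `n_features`, `mre`,
#'   `mse`, `mae`, `r2`.
#' @export
compare_feature_sets <- function(feature_sets, X, y, spec, split = NULL,
                                 seed = 1L) {
  if (is.null(names(feature_sets)) || any(names(feature_sets) == ""))
    stop("feature_sets must be a named list")
  if (is.null(split)) split <- split_train_test(rownames(X), 0.8, seed)
  tr <- match(split$train_ids, rownames(X))
  te <- match(split$test_ids, rownames(X))
  rows <- lapply(names(feature_sets), function(nm) {
    feats <- feature_sets[[nm]]
    miss <- setdiff(feats, colnames(X))
    if (length(miss))
      stop("unknown descriptor(s) in set '", nm, "': ",
           paste(miss, collapse = ", "))
    Xs <- unclass(X)[, feats, drop = FALSE]
    fit <- fit_regressor(spec, Xs[tr, , drop = FALSE], y[tr])
    m <- evaluate_regression(y[te], predict(fit, Xs[te, , drop = FALSE]))
    data.frame(feature_set = nm, n_features = length(feats),
               mre = m$mre, mse = m$mse, mae = m$mae, r2 = m$r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
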
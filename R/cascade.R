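#' Fit a cascade forest regressor
#'
#' A layered forest ensemble in the deep-forest style, restricted to the
#' cascade (descriptors are unordered tabular features, so the
#' multi-grained scanning stage designed for sequential inputs is
#' omitted). Each layer holds four forests — two bootstrap-aggregated
#' random forests and two extremely-randomized forests — trained on the
#' original descriptors concatenated with the previous layer's per-forest
#' predictions. During training the augmented features are each forest's
#' out-of-bag predictions, so no layer sees its own training-row outputs.
#' Layer growth stops when the mean-squared error on an internal held-out
#' fifth of the training rows fails to improve for `early_stop_rounds`
#' consecutive layers, or at `max_layers`; the kept depth is the best
#' validated one. The model predicts with the mean of the final layer's
#' four forest outputs.
#'
#' @param X numeric matrix of descriptors (n >= 50).
#' @param y continuous target.
#' @param layer_spec list with `num_trees` per forest (default 200).
#' @param max_layers maximum cascade depth.
#' @param early_stop_rounds patience, in layers, of the early stop.
#' @param seed integer seed.
#' @return object of class `cascade_forest` with elements `layers` (list
#'   of 4-forest layers), `n_layers`, `val_mse` per layer.
#' @export
fit_cascade_forest <- function(X, y, layer_spec = list(num_trees = 200L),
                               max_layers = 10L, early_stop_rounds = 1L,
                               seed = 1L) {
  if (max_layers < 1L) stop("max_layers must be >= 1")
  if (nrow(X) < 50L) stop("cascade forest needs n >= 50 for internal validation")
  X <- as_plain_matrix(X)
  num_trees <- layer_spec$num_trees %||% 200L
  n <- nrow(X)
  val_idx <- with_seed(fanout_seed(seed, 9L),
                       sample.int(n, size = max(1L, floor(n / 5))))
  fit_idx <- setdiff(seq_len(n), val_idx)

  forest_kinds <- c("rf", "rf", "et", "et")
  aug_fit <- NULL; aug_val <- NULL
  layers <- list(); val_mse <- numeric(0)
  best_mse <- Inf; best_depth <- 0L; stall <- 0L
  for (l in seq_len(max_layers)) {
    Xf <- if (is.null(aug_fit)) X[fit_idx, , drop = FALSE]
          else cbind(X[fit_idx, , drop = FALSE], aug_fit)
    Xv <- if (is.null(aug_val)) X[val_idx, , drop = FALSE]
          else cbind(X[val_idx, , drop = FALSE], aug_val)
    layer <- vector("list", 4L)
    oob <- matrix(NA_real_, length(fit_idx), 4L)
    valp <- matrix(NA_real_, length(val_idx), 4L)
    for (f in 1:4) {
      fit <- ranger::ranger(
        y = y[fit_idx], x = as.data.frame(Xf), num.trees = num_trees,
        splitrule = if (forest_kinds[f] == "et") "extratrees" else "variance",
        replace = forest_kinds[f] != "et",
        sample.fraction = if (forest_kinds[f] == "et") 0.8 else 1,
        mtry = if (forest_kinds[f] == "et") max(1L, floor(sqrt(ncol(Xf))))
               else max(1L, floor(ncol(Xf) / 3)),
        seed = fanout_seed(seed, l * 10L + f), num.threads = 1L,
        oob.error = TRUE)
      layer[[f]] <- fit
      po <- fit$predictions
      po[is.na(po)] <- mean(y[fit_idx])  # rows never out of bag
      oob[, f] <- po
      valp[, f] <- predict(fit, data = as.data.frame(Xv),
                           num.threads = 1L)$predictions
    }
    layers[[l]] <- layer
    mse_l <- mean((y[val_idx] - rowMeans(valp))^2)
    val_mse <- c(val_mse, mse_l)
    if (mse_l < best_mse) {
      best_mse <- mse_l; best_depth <- l; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= early_stop_rounds) break
    }
    aug_fit <- oob
    aug_val <- valp
    colnames(aug_fit) <- colnames(aug_val) <- paste0(".cascade_", 1:4)
  }
  structure(list(layers = layers[seq_len(best_depth)],
                 n_layers = best_depth, val_mse = val_mse,
                 feature_names = colnames(X), seed = as.integer(seed)),
            class = "cascade_forest")
}

# Forward pass through the cascade.
predict_cascade <- function(model, X) {
  aug <- NULL
  for (layer in model$layers) {
    Xl <- if (is.null(aug)) X else cbind(X, aug)
    preds <- sapply(layer, function(f)
      predict(f, data = as.data.frame(Xl), num.threads = 1L)$predictions)
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
    aug <- preds
    colnames(aug) <- paste0(".cascade_", 1:4)
  }
  rowMeans(aug)
}

#' @export
predict.cascade_forest <- function(object, newdata, ...) {
  newdata <- as_plain_matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    miss <- setdiff(object$feature_names, colnames(newdata))
    if (length(miss))
      stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  predict_cascade(object, newdata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
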
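BASE_LEARNERS <- c("svm", "knn", "bagged_forest", "boosted_trees",
                   "hist_boosted_trees")

# Default base-learner menu per ADMET endpoint (the compositions found
# best for each property; the histogram booster is the leaf-wise member).
default_stacking_menu <- function(property) {
  switch(property,
    "Caco-2" = c("svm", "boosted_trees", "hist_boosted_trees"),
    "CYP3A4" = c("knn", "bagged_forest", "boosted_trees", "hist_boosted_trees"),
    "hERG"   = c("knn", "bagged_forest", "boosted_trees"),
    "HOB"    = c("knn", "boosted_trees"),
    "MN"     = c("boosted_trees", "hist_boosted_trees"),
    stop("unknown ADMET property: ", property))
}

#' Gate compounds by predicted activity
#'
#' The two-stage rule: a compound proceeds to ADMET modeling only when its
#' predicted pIC50 passes the activity threshold (default 6, inclusive).
#'
#' @param predictions named numeric vector of predicted pIC50 per
#'   compound id.
#' @param threshold activity threshold in pIC50 units.
#' @param inclusive if `TRUE` retain `pred >= threshold`, else strictly
#'   greater.
#' @param prediction_source provenance tag recorded in the result
#'   (`"out_of_fold"`, `"refit"` or `"true_labels"`).
#' @return object of class `gate_result` with `retained_ids`,
#'   `rejected_ids`, `threshold`, `inclusive`, `prediction_source`.
#' @export
gate_by_activity <- function(predictions, threshold = 6.0, inclusive = TRUE,
                             prediction_source = "refit") {
  if (any(!is.finite(predictions))) stop("predictions must be finite")
  ids <- names(predictions)
  if (is.null(ids)) ids <- as.character(seq_along(predictions))
  keep <- if (inclusive) predictions >= threshold else predictions > threshold
  structure(list(retained_ids = ids[keep], rejected_ids = ids[!keep],
                 threshold = threshold, inclusive = inclusive,
                 prediction_source = prediction_source,
                 n_retained = sum(keep), n_rejected = sum(!keep)),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("Activity gate (pIC50 %s %.3g, %s predictions): %d retained / %d rejected\n",
              if (x$inclusive) ">=" else ">", x$threshold,
              x$prediction_source, x$n_retained, x$n_rejected))
  invisible(x)
}

#' Configuration of a per-property stacking classifier
#'
#' @param property one of the five ADMET endpoints (Caco-2, CYP3A4, hERG,
#'   HOB, MN); fixes the default base-learner menu.
#' @param base_learners ordered subset of `svm`, `knn`, `bagged_forest`,
#'   `boosted_trees`, `hist_boosted_trees` (at least two).
#' @param folds number of stratified folds for the out-of-fold
#'   meta-features.
#' @param seed integer seed.
#' @return object of class `stacking_config`.
#' @export
stacking_config <- function(property, base_learners = NULL, folds = 5L,
                            seed = 1L) {
  if (is.null(base_learners)) base_learners <- default_stacking_menu(property)
  bad <- setdiff(base_learners, BASE_LEARNERS)
  if (length(bad)) stop("unknown base learner(s): ", paste(bad, collapse = ", "))
  if (length(base_learners) < 2L) stop("need at least 2 base learners")
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(property = property, base_learners = base_learners,
                 meta_learner = "gaussian_nb", folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "stacking_config")
}

fit_base_learner <- function(kind, X, y, seed) {
  yf <- factor(y, levels = c(0, 1))
  switch(kind,
    svm = with_seed(seed,  # probability model uses internal cross-validation
      e1071::svm(x = X, y = yf, kernel = "radial", probability = TRUE,
                 scale = TRUE)),
    knn = list(X = X, y = yf, k = 25L, seed = seed),
    bagged_forest = ranger::ranger(
      y = yf, x = as.data.frame(X), num.trees = 500L, probability = TRUE,
      seed = seed, num.threads = 1L),
    boosted_trees = ,
    hist_boosted_trees = {
      # shallow, slow-learning boosters estimate smooth class
      # probabilities far better than deep default trees at these sizes
      params <- list(eta = 0.04, max_depth = 3L, nthread = 1L, seed = seed,
                     subsample = 0.8, colsample_bytree = 0.5,
                     objective = "binary:logistic")
      nrounds <- 600L
      if (kind == "hist_boosted_trees") {
        params$tree_method <- "hist"
        params$eta <- 0.03; params$max_depth <- 2L
        nrounds <- 1000L
      }
      xgboost::xgb.train(params, xgboost::xgb.DMatrix(X, label = y),
                         nrounds = nrounds, verbose = 0L)
    },
    stop("unknown base learner: ", kind))
}

predict_base_prob <- function(kind, fit, X) {
  switch(kind,
    svm = {
      pr <- attr(predict(fit, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    knn = {
      pred <- with_seed(fit$seed,
        class::knn(train = fit$X, test = X, cl = fit$y, k = fit$k,
                   prob = TRUE))
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    },
    bagged_forest = predict(fit, data = as.data.frame(X),
                            num.threads = 1L)$predictions[, "1"],
    boosted_trees = ,
    hist_boosted_trees = predict(fit, X),
    stop("unknown base learner: ", kind))
}

# Bound probabilities away from 0/1 so the logit stays finite.
clamp_prob <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)

# Stratified fold assignment: each class is permuted and dealt round-robin
# so every fold carries both classes whenever class counts allow it.
stratified_folds <- function(y, folds, seed) {
  if (min(table(y)) < folds)
    stop("a class has fewer members than folds; cannot stratify")
  assign <- integer(length(y))
  with_seed(seed, for (cls in unique(y)) {
    idx <- which(y == cls)
    assign[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(length(idx))]
  })
  assign
}

#' Fit a stacked ADMET classifier
#'
#' Trains the configured base learners and a Gaussian naive Bayes
#' meta-learner by stacked generalization: the meta-feature matrix is
#' n x B of out-of-fold positive-class probabilities (stratified k-fold;
#' the meta-feature for row i always comes from base models whose
#' training folds exclude i), the meta-learner is fitted on those
#' meta-features, and the base learners are then refitted on all training
#' rows for inference. The meta-learner sees the probabilities on the
#' logit scale, where class-conditional Gaussians fit calibrated
#' classifier outputs far better than on the bounded \[0,1\] scale.
#'
#' @param cfg a [stacking_config()].
#' @param X a [descriptor_matrix()] or numeric matrix (training rows).
#' @param y 0/1 labels, both classes present.
#' @return object of class `stacking_model` with the refitted base
#'   learners, the meta-learner, and the out-of-fold meta-feature matrix
#'   (`oof_meta`).
#' @export
fit_stacking <- function(cfg, X, y) {
  if (!inherits(cfg, "stacking_config")) stop("cfg must be a stacking_config")
  if (nrow(X) != length(y)) stop("X rows must align with y")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("single-class labels; cannot fit a classifier")
  X <- as_plain_matrix(X)
  # canonicalize row order (by compound id) so the fit — fold assignment,
  # base fits and meta-features — is invariant to the input row order
  canon <- if (!is.null(rownames(X))) order(rownames(X)) else seq_len(nrow(X))
  X <- X[canon, , drop = FALSE]
  y <- y[canon]
  inv <- order(canon)
  B <- length(cfg$base_learners)
  fold_of <- stratified_folds(y, cfg$folds, fanout_seed(cfg$seed, 1L))
  oof <- matrix(NA_real_, nrow(X), B,
                dimnames = list(rownames(X), cfg$base_learners))
  for (f in seq_len(cfg$folds)) {
    hold <- which(fold_of == f)
    for (b in seq_len(B)) {
      kind <- cfg$base_learners[b]
      fit <- fit_base_learner(kind, X[-hold, , drop = FALSE], y[-hold],
                              seed = fanout_seed(cfg$seed, 10L * f + b))
      oof[hold, b] <- predict_base_prob(kind, fit, X[hold, , drop = FALSE])
    }
  }
  meta_df <- as.data.frame(qlogis(clamp_prob(oof)))
  names(meta_df) <- paste0("base_", seq_len(B))
  meta <- e1071::naiveBayes(meta_df, factor(y, levels = c(0, 1)))
  base_fits <- lapply(seq_len(B), function(b)
    fit_base_learner(cfg$base_learners[b], X, y,
                     seed = fanout_seed(cfg$seed, 1000L + b)))
  structure(list(config = cfg, base_fits = base_fits, meta_fit = meta,
                 oof_meta = oof[inv, , drop = FALSE],
                 feature_names = colnames(X),
                 classes = c(0L, 1L)),
            class = "stacking_model")
}

#' Predict from a stacked ADMET classifier
#'
#' @param object a `stacking_model` from [fit_stacking()].
#' @param newdata matrix carrying the model's descriptor columns.
#' @param ... unused.
#' @return data.frame with `probability` (positive class, in \[0,1\]) and
#'   `label` (probability >= 0.5).
#' @export
predict.stacking_model <- function(object, newdata, ...) {
  X <- align_features(object, newdata)
  B <- length(object$base_fits)
  meta_df <- as.data.frame(lapply(seq_len(B), function(b)
    qlogis(clamp_prob(predict_base_prob(object$config$base_learners[b],
                                        object$base_fits[[b]], X)))))
  names(meta_df) <- paste0("base_", seq_len(B))
  prob <- as.numeric(predict(object$meta_fit, meta_df, type = "raw",
                             threshold = 1e-9, eps = 1e-9)[, "1"])
  prob <- pmin(pmax(prob, 0), 1)
  data.frame(probability = prob, label = as.integer(prob >= 0.5))
}

#' @export
print.stacking_model <- function(x, ...) {
  cat("Stacked classifier for", x$config$property, "-",
      paste(x$config$base_learners, collapse = " + "),
      "-> gaussian_nb meta-learner\n")
  invisible(x)
}
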
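#' Rank descriptors by a single importance criterion
#'
#' Scores every descriptor against the target with one of three criteria
#' and converts scores to fractional ranks (1 = most important; tied
#' scores share their average rank, so every rank column sums to
#' p(p+1)/2):
#' \describe{
#'   \item{`mi`}{mutual information via [estimate_mutual_information()].}
#'   \item{`forest_impurity`}{mean impurity decrease (variance for a
#'     continuous target, Gini for a binary one) of a bagged-tree
#'     ensemble.}
#'   \item{`boosting_gain`}{cumulative split gain of a gradient-boosted
#'     tree ensemble; descriptors never used in a split score 0 and share
#'     the worst fractional rank.}
#' }
#' The forest and booster run with fixed published-default hyperparameters
#' so that selection does not depend on downstream tuning.
#'
#' @param m a [descriptor_matrix()].
#' @param target numeric target vector (continuous or 0/1), one value per
#'   row of `m`.
#' @param method `"mi"`, `"forest_impurity"` or `"boosting_gain"`.
#' @param seed integer seed (forest and booster are stochastic).
#' @param cfg an [mi_config()] for `method = "mi"`.
#' @return named numeric vector of fractional ranks over the descriptors.
#' @export
rank_features <- function(m, target,
                          method = c("mi", "forest_impurity", "boosting_gain"),
                          seed = 1L, cfg = mi_config()) {
  method <- match.arg(method)
  if (nrow(m) != length(target)) stop("target length must match rows of m")
  if (ncol(m) < 2L) stop("need at least 2 descriptors to rank")
  if (max(target) == min(target)) stop("target is constant")
  binary <- is_binary(target)
  scores <- switch(method,
    mi = apply(unclass(m), 2, function(x)
      estimate_mutual_information(x, target, cfg)),
    forest_impurity = {
      y <- if (binary) factor(target, levels = c(0, 1)) else target
      fit <- ranger::ranger(y = y, x = as.data.frame(unclass(m)),
                            num.trees = 300L, importance = "impurity",
                            seed = as.integer(seed), num.threads = 1L,
                            probability = FALSE)
      fit$variable.importance[colnames(m)]
    },
    boosting_gain = {
      params <- list(max_depth = 6L, eta = 0.3, nthread = 1L,
                     seed = as.integer(seed),
                     objective = if (binary) "binary:logistic" else "reg:squarederror")
      dm <- xgboost::xgb.DMatrix(unclass(m), label = target)
      booster <- xgboost::xgb.train(params, dm, nrounds = 100L, verbose = 0L)
      imp <- xgboost::xgb.importance(model = booster)
      gain <- setNames(numeric(ncol(m)), colnames(m))
      gain[imp$Feature] <- imp$Gain
      gain
    })
  rank(-scores, ties.method = "average")
}

#' Fuse per-method ranks into a feature ranking
#'
#' The fused score of each descriptor is the arithmetic mean of its
#' mutual-information, forest-impurity and boosting-gain ranks,
#' `(rank_mi + rank_forest + rank_gain) / 3`; a lower average rank means
#' higher overall importance. The averages are not re-ranked.
#'
#' @param r_mi,r_forest,r_gain named fractional rank vectors over the same
#'   descriptor set (from [rank_features()]).
#' @return a data.frame of class `feature_ranking` with columns
#'   `descriptor`, `rank_mi`, `rank_forest`, `rank_gain`, `average_rank`.
#' @export
aggregate_ranks <- function(r_mi, r_forest, r_gain) {
  nm <- names(r_mi)
  if (is.null(nm)) stop("rank vectors must be named by descriptor")
  if (!setequal(nm, names(r_forest)) || !setequal(nm, names(r_gain)))
    stop("rank vectors cover different descriptor sets")
  out <- data.frame(descriptor = nm,
                    rank_mi = as.numeric(r_mi),
                    rank_forest = as.numeric(r_forest[nm]),
                    rank_gain = as.numeric(r_gain[nm]),
                    stringsAsFactors = FALSE)
  out$average_rank <- (out$rank_mi + out$rank_forest + out$rank_gain) / 3
  class(out) <- c("feature_ranking", class(out))
  out
}

# Full dual-filter ranking against one target.
dffs_ranking <- function(m, target, seed, cfg = mi_config()) {
  aggregate_ranks(
    rank_features(m, target, "mi", seed = fanout_seed(seed, 1L), cfg = cfg),
    rank_features(m, target, "forest_impurity", seed = fanout_seed(seed, 2L)),
    rank_features(m, target, "boosting_gain", seed = fanout_seed(seed, 3L)))
}

#' Dual-filter feature selection
#'
#' Ranks every descriptor by mutual information, forest impurity and
#' boosting gain, fuses the three rankings by their average rank, and
#' returns the top `k` descriptors. With a single continuous target this
#' yields the activity descriptor set; with a matrix of five binary ADMET
#' targets, a ranking is computed per target and the final score is the
#' mean of the per-target average ranks (`fusion_mode =
#' "mean_across_targets"`), or selection can be done per property
#' (`fusion_mode = "per_target"`, returning one selection per column).
#' Ties at the selection boundary break lexicographically by descriptor
#' name, making selection deterministic.
#'
#' @param m a [descriptor_matrix()].
#' @param targets numeric vector (continuous target) or n x 5 binary
#'   matrix/data.frame with one column per ADMET property.
#' @param k number of descriptors to select.
#' @param fusion_mode `"single"` (inferred for a vector target),
#'   `"mean_across_targets"`, or `"per_target"`.
#' @param seed integer seed.
#' @param cfg an [mi_config()].
#' @return an object of class `selection_result`: list with
#'   `selected_names` (ordered by ascending fused rank), `k`, `ranking`
#'   (fused data.frame), `per_target_rankings`, `fusion_mode`, `seed`.
#' @export
select_features <- function(m, targets, k,
                            fusion_mode = c("auto", "single",
                                            "mean_across_targets", "per_target"),
                            seed = 1L, cfg = mi_config()) {
  fusion_mode <- match.arg(fusion_mode)
  if (k <= 0L) stop("k must be positive")
  if (k > ncol(m)) stop("k exceeds the number of descriptors")
  single <- is.null(dim(targets))
  if (fusion_mode == "auto")
    fusion_mode <- if (single) "single" else "mean_across_targets"
  if (single && fusion_mode != "single")
    stop("multi-target fusion requires a matrix of targets")

  if (fusion_mode == "single") {
    rk <- dffs_ranking(m, targets, seed = seed, cfg = cfg)
    final <- setNames(rk$average_rank, rk$descriptor)
    per_target <- list(target = rk)
  } else {
    targets <- as.matrix(targets)
    if (is.null(colnames(targets)))
      colnames(targets) <- paste0("target_", seq_len(ncol(targets)))
    per_target <- lapply(seq_len(ncol(targets)), function(j)
      dffs_ranking(m, targets[, j], seed = fanout_seed(seed, 100L + j), cfg = cfg))
    names(per_target) <- colnames(targets)
    if (fusion_mode == "per_target") {
      sel <- lapply(per_target, function(rk) {
        ord <- order(rk$average_rank, rk$descriptor)
        rk$descriptor[ord][seq_len(k)]
      })
      return(structure(list(selected_names = sel, k = as.integer(k),
                            ranking = NULL, per_target_rankings = per_target,
                            fusion_mode = fusion_mode, seed = as.integer(seed)),
                       class = "selection_result"))
    }
    avg <- sapply(per_target, function(rk)
      setNames(rk$average_rank, rk$descriptor)[colnames(m)])
    final <- setNames(rowMeans(avg), colnames(m))
  }
  ord <- order(final, names(final))
  ranking <- data.frame(descriptor = names(final)[ord],
                        final_rank = as.numeric(final)[ord],
                        stringsAsFactors = FALSE)
  structure(list(selected_names = ranking$descriptor[seq_len(k)],
                 k = as.integer(k), ranking = ranking,
                 per_target_rankings = per_target,
                 fusion_mode = fusion_mode, seed = as.integer(seed)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Dual-filter feature selection (", x$fusion_mode, ")\n", sep = "")
  if (is.list(x$selected_names) && x$fusion_mode == "per_target") {
    for (nm in names(x$selected_names))
      cat(" ", nm, ": ", paste(head(x$selected_names[[nm]], 5), collapse = ", "),
          if (x$k > 5) ", ..." else "", "\n", sep = "")
  } else {
    cat("  k =", x$k, "selected:",
        paste(head(x$selected_names, 8), collapse = ", "),
        if (x$k > 8) "..." else "", "\n")
  }
  invisible(x)
}

#' Write a selection report CSV
#'
#' One row per descriptor with the three method ranks, the fused average
#' rank and a selected flag; accompanied by a JSON summary.
#'
#' @param sel a `selection_result` from [select_features()] (single or
#'   mean-across-targets fusion).
#' @param path CSV output path; the JSON summary is written beside it.
#' @export
write_selection_report <- function(sel, path) {
  if (is.null(sel$ranking)) stop("per-target selections have no fused report")
  rk <- if (sel$fusion_mode == "single") sel$per_target_rankings[[1]] else NULL
  rep <- sel$ranking
  names(rep)[names(rep) == "final_rank"] <- "average_rank"
  if (!is.null(rk)) {
    idx <- match(rep$descriptor, rk$descriptor)
    rep$rank_mi <- rk$rank_mi[idx]
    rep$rank_forest <- rk$rank_forest[idx]
    rep$rank_gain <- rk$rank_gain[idx]
    rep <- rep[, c("descriptor", "rank_mi", "rank_forest", "rank_gain",
                   "average_rank")]
  }
  rep$selected <- rep$descriptor %in% unlist(sel$selected_names)
  write.csv(rep, path, row.names = FALSE)
  jsonlite::write_json(list(k = sel$k, fusion_mode = sel$fusion_mode,
                            seed = sel$seed),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
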
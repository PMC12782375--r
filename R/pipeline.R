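#' Configuration of the two-stage screening pipeline
#'
#' Inputs may be in-memory objects (a [descriptor_matrix()] and label
#' data.frames) or CSV paths understood by [read_descriptor_table()] /
#' [read_label_table()].
#'
#' @param descriptors descriptor table (object or path).
#' @param activity activity label table (object or path).
#' @param admet ADMET label table (object or path).
#' @param unlabeled optional unlabeled descriptor table (object or path)
#'   for candidate screening.
#' @param k_activity descriptors selected for the activity stage.
#' @param k_admet descriptors selected for the ADMET stage.
#' @param gate_threshold,gate_inclusive activity gate (pIC50 units).
#' @param gate_prediction_source `"out_of_fold"` (default; gate training
#'   compounds on stage-1 predictions from models that never saw them),
#'   `"refit"` (in-sample predictions) or `"true_labels"`.
#' @param stage1_family regressor family for the activity stage.
#' @param tune_budget trials for the stage-1 hyperparameter search
#'   (1 = published defaults).
#' @param cv_folds folds for tuning, stage-1 out-of-fold gating
#'   predictions and stacking meta-features.
#' @param stacking_menus named list (per property) of base-learner
#'   vectors; defaults to the per-property menus.
#' @param normalize_on `"train"` (fit min-max on the training partition
#'   only; default) or `"all"`.
#' @param drop_mode uninformative-descriptor rule, see
#'   [drop_uninformative_descriptors()].
#' @param split_ratio training fraction.
#' @param seed master seed; all stage seeds fan out from it.
#' @param out_dir optional directory for run artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(descriptors, activity, admet, unlabeled = NULL,
                            k_activity = 20L, k_admet = 40L,
                            gate_threshold = 6.0, gate_inclusive = TRUE,
                            gate_prediction_source = c("out_of_fold", "refit",
                                                       "true_labels"),
                            stage1_family = "hist_boosted_trees",
                            tune_budget = 10L, cv_folds = 5L,
                            stacking_menus = NULL,
                            normalize_on = c("train", "all"),
                            drop_mode = c("zero_constant", "zero_variance"),
                            split_ratio = 0.8, seed = 1L, out_dir = NULL) {
  structure(list(descriptors = descriptors, activity = activity,
                 admet = admet, unlabeled = unlabeled,
                 k_activity = as.integer(k_activity),
                 k_admet = as.integer(k_admet),
                 gate_threshold = gate_threshold,
                 gate_inclusive = isTRUE(gate_inclusive),
                 gate_prediction_source = match.arg(gate_prediction_source),
                 stage1_family = match.arg(stage1_family, REGRESSOR_FAMILIES),
                 tune_budget = as.integer(tune_budget),
                 cv_folds = as.integer(cv_folds),
                 stacking_menus = stacking_menus,
                 normalize_on = match.arg(normalize_on),
                 drop_mode = match.arg(drop_mode),
                 split_ratio = split_ratio, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; file paths
#' are resolved relative to the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (key in c("descriptors", "activity", "admet", "unlabeled", "out_dir")) {
    if (!is.null(raw[[key]]) && is.character(raw[[key]]) &&
        !startsWith(raw[[key]], "/"))
      raw[[key]] <- file.path(base, raw[[key]])
  }
  do.call(pipeline_config, raw)
}

resolve_inputs <- function(cfg) {
  desc <- if (is.character(cfg$descriptors))
    read_descriptor_table(cfg$descriptors) else
      descriptor_matrix(cfg$descriptors)
  act <- if (is.character(cfg$activity))
    read_label_table(cfg$activity, "activity") else cfg$activity
  adm <- if (is.character(cfg$admet))
    read_label_table(cfg$admet, "admet") else cfg$admet
  if (!setequal(act$compound_id, rownames(desc)) ||
      !setequal(adm$compound_id, rownames(desc)))
    stop("label tables do not align with the descriptor table's compound ids")
  act <- act[match(rownames(desc), act$compound_id), ]
  adm <- adm[match(rownames(desc), adm$compound_id), ]
  unl <- if (is.null(cfg$unlabeled)) NULL else if (is.character(cfg$unlabeled))
    read_descriptor_table(cfg$unlabeled) else descriptor_matrix(cfg$unlabeled)
  list(descriptors = desc, activity = act, admet = adm, unlabeled = unl)
}

# Out-of-fold stage-1 predictions on the training partition.
stage1_oof <- function(family, hp, X, y, folds, seed) {
  fold_idx <- make_folds(nrow(X), folds, fanout_seed(seed, 77L))
  oof <- numeric(nrow(X))
  for (i in seq_along(fold_idx)) {
    hold <- fold_idx[[i]]
    fit <- fit_regressor(regressor_spec(family, hp,
                                        seed = fanout_seed(seed, 80L + i)),
                         X[-hold, , drop = FALSE], y[-hold])
    oof[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  oof
}

#' Run the full two-stage screening pipeline
#'
#' Executes, in order: ingestion and validation, uninformative-descriptor
#' removal, 8:2 train/test split, min-max normalization (fitted on the
#' training partition), dual-filter feature selection for the activity
#' and ADMET descriptor sets, stage-1 activity regression (budgeted
#' hyperparameter search, test-set metrics, relative-error histogram),
#' the activity gate (out-of-fold predictions for training compounds),
#' per-property stacked ADMET classification on the gated compounds,
#' phi-coefficient association analysis of the gated compounds' labels,
#' Shapley attribution of the stage-1 model on the test partition, and —
#' when unlabeled descriptors are supplied — candidate screening.
#' All randomness fans out from `cfg$seed`; a rerun with the same
#' configuration reproduces the report exactly. If `cfg$out_dir` is set,
#' every intermediate artifact is written there; a failing stage leaves a
#' `FAILED` marker naming the stage.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `qsar_run`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop("cfg must be a pipeline_config")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  stage <- "ingest"
  run <- tryCatch(
    run_pipeline_stages(cfg, out_dir, advance = function(s) stage <<- s),
    error = function(e) {
      if (!is.null(out_dir))
        writeLines(c(stage, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

run_pipeline_stages <- function(cfg, out_dir, advance) {
  advance("ingest")
  inp <- resolve_inputs(cfg)
  y_all <- setNames(inp$activity$pic50, inp$activity$compound_id)
  labels_all <- as.matrix(inp$admet[, ADMET_PROPERTIES])
  rownames(labels_all) <- inp$admet$compound_id

  advance("preprocess")
  dropped <- drop_uninformative_descriptors(inp$descriptors, cfg$drop_mode)
  X0 <- dropped$matrix
  if (cfg$k_activity > ncol(X0) || cfg$k_admet > ncol(X0))
    stop("k exceeds the descriptor count after filtering")
  split <- split_train_test(rownames(X0), cfg$split_ratio,
                            fanout_seed(cfg$seed, 1L))
  tr <- split$train_ids; te <- split$test_ids
  norm_stats <- if (cfg$normalize_on == "train")
    fit_minmax(X0[tr, , drop = FALSE], fitted_on = "train")
  else fit_minmax(X0, fitted_on = "all")
  Xn <- apply_minmax(X0, norm_stats)

  advance("feature_selection")
  sel_act <- select_features(Xn[tr, , drop = FALSE], y_all[tr],
                             k = cfg$k_activity, fusion_mode = "single",
                             seed = fanout_seed(cfg$seed, 2L))
  sel_adm <- select_features(Xn[tr, , drop = FALSE],
                             labels_all[tr, , drop = FALSE],
                             k = cfg$k_admet,
                             fusion_mode = "mean_across_targets",
                             seed = fanout_seed(cfg$seed, 3L))
  Xa <- Xn[, sel_act$selected_names, drop = FALSE]
  Xm <- Xn[, sel_adm$selected_names, drop = FALSE]

  advance("stage1_regression")
  tune <- tune_hyperparameters(cfg$stage1_family, Xa[tr, , drop = FALSE],
                               y_all[tr], budget = cfg$tune_budget,
                               folds = cfg$cv_folds,
                               seed = fanout_seed(cfg$seed, 4L))
  stage1 <- fit_regressor(regressor_spec(cfg$stage1_family,
                                         tune$best_hyperparams,
                                         seed = fanout_seed(cfg$seed, 5L)),
                          Xa[tr, , drop = FALSE], y_all[tr])
  pred_te <- predict(stage1, Xa[te, , drop = FALSE])
  stage1_metrics <- evaluate_regression(y_all[te], pred_te)
  err_hist <- relative_error_histogram(y_all[te], pred_te)

  advance("gate")
  gate_preds <- switch(cfg$gate_prediction_source,
    out_of_fold = c(setNames(stage1_oof(cfg$stage1_family,
                                        tune$best_hyperparams,
                                        Xa[tr, , drop = FALSE], y_all[tr],
                                        cfg$cv_folds,
                                        fanout_seed(cfg$seed, 6L)), tr),
                    setNames(pred_te, te)),
    refit = setNames(predict(stage1, Xa), rownames(Xa)),
    true_labels = y_all)
  gate <- gate_by_activity(gate_preds, cfg$gate_threshold, cfg$gate_inclusive,
                           prediction_source = cfg$gate_prediction_source)
  gated_tr <- intersect(tr, gate$retained_ids)
  gated_te <- intersect(te, gate$retained_ids)

  advance("stage2_stacking")
  stage2 <- list()
  if (length(gated_tr) == 0L) {
    stage2_skipped <- "activity gate retained zero training compounds"
  } else {
    stage2_skipped <- NULL
    for (prop in ADMET_PROPERTIES) {
      menu <- cfg$stacking_menus[[prop]]
      scfg <- stacking_config(prop, base_learners = menu,
                              folds = cfg$cv_folds,
                              seed = fanout_seed(cfg$seed, 10L + match(prop, ADMET_PROPERTIES)))
      ytr <- labels_all[gated_tr, prop]
      if (length(unique(ytr)) < 2L) {
        stage2[[prop]] <- list(skipped = "single-class training labels")
        next
      }
      model <- fit_stacking(scfg, Xm[gated_tr, , drop = FALSE], ytr)
      entry <- list(model = model)
      if (length(gated_te)) {
        pr <- predict(model, Xm[gated_te, , drop = FALSE])
        entry$metrics <- evaluate_classification(labels_all[gated_te, prop],
                                                 pr$label, pr$probability)
      }
      stage2[[prop]] <- entry
    }
  }

  advance("interpretation")
  gated_all <- gate$retained_ids
  phi <- if (length(gated_all) >= 2L)
    phi_association_matrix(labels_all[gated_all, , drop = FALSE]) else NULL
  attribution <- NULL; importance <- NULL
  if (stage1$family %in% c("boosted_trees", "hist_boosted_trees")) {
    attribution <- compute_attributions(stage1, Xa[te, , drop = FALSE])
    importance <- global_importance(attribution)
  }

  advance("screening")
  screening <- NULL
  run <- structure(list(config = cfg, split = split,
                        removed_descriptors = dropped$removed,
                        norm_stats = norm_stats,
                        selection_activity = sel_act,
                        selection_admet = sel_adm,
                        tuning = tune[c("best_hyperparams", "best_score",
                                        "default_score")],
                        stage1_model = stage1,
                        stage1_metrics = stage1_metrics,
                        error_histogram = err_hist,
                        gate = gate, stage2 = stage2,
                        stage2_skipped = stage2_skipped,
                        phi = phi, attribution = attribution,
                        importance = importance,
                        screening = NULL),
                   class = "qsar_run")
  if (!is.null(inp$unlabeled))
    run$screening <- screen_candidates(run, inp$unlabeled)
  run
}

#' Screen unlabeled candidate compounds
#'
#' Normalizes the candidates with the run's training-set statistics
#' (never refitted), predicts pIC50 with the stage-1 model, applies the
#' activity gate, and attaches the five ADMET positive-class
#' probabilities from the stage-2 models. ADMET columns are populated for
#' every compound; candidates failing the gate are flagged
#' `screened = FALSE`. Rows are sorted by predicted pIC50, descending.
#'
#' @param run a `qsar_run` from [run_pipeline()].
#' @param unlabeled a [descriptor_matrix()] covering the run's selected
#'   descriptor sets.
#' @return object of class `screening_result`: `candidates` (data.frame)
#'   and `band_counts` (compounds with predicted pIC50 > 7, in \[6, 7\],
#'   and < 6).
#' @export
screen_candidates <- function(run, unlabeled) {
  if (!inherits(run, "qsar_run")) stop("run must be a qsar_run")
  Xn <- apply_minmax(
    unlabeled[, run$norm_stats$descriptor_names, drop = FALSE],
    run$norm_stats)
  pred <- predict(run$stage1_model,
                  Xn[, run$selection_activity$selected_names, drop = FALSE])
  names(pred) <- rownames(Xn)
  gate <- gate_by_activity(pred, run$gate$threshold, run$gate$inclusive,
                           prediction_source = "refit")
  out <- data.frame(compound_id = rownames(Xn), predicted_pic50 = pred,
                    screened = rownames(Xn) %in% gate$retained_ids,
                    stringsAsFactors = FALSE, row.names = NULL)
  Xm <- Xn[, run$selection_admet$selected_names, drop = FALSE]
  for (prop in ADMET_PROPERTIES) {
    entry <- run$stage2[[prop]]
    out[[paste0("prob_", prop)]] <- if (is.null(entry$model)) NA_real_
      else predict(entry$model, Xm)$probability
  }
  out <- out[order(-out$predicted_pic50), ]
  rownames(out) <- NULL
  structure(list(candidates = out,
                 band_counts = c(above_7 = sum(out$predicted_pic50 > 7),
                                 from_6_to_7 = sum(out$predicted_pic50 >= 6 &
                                                     out$predicted_pic50 <= 7),
                                 below_6 = sum(out$predicted_pic50 < 6))),
            class = "screening_result")
}

#' @export
print.qsar_run <- function(x, ...) {
  cat("Two-stage QSAR screening run (seed", x$config$seed, ")\n")
  cat(sprintf("  descriptors: %d removed as uninformative; k_activity=%d, k_admet=%d\n",
              length(x$removed_descriptors), x$config$k_activity,
              x$config$k_admet))
  cat("  stage 1 (", x$stage1_model$family, ") test: ", sep = "")
  print(x$stage1_metrics)
  print(x$gate)
  for (prop in names(x$stage2)) {
    entry <- x$stage2[[prop]]
    if (!is.null(entry$metrics)) {
      cat(sprintf("  %-7s ", prop)); print(entry$metrics)
    } else if (!is.null(entry$skipped)) {
      cat(sprintf("  %-7s skipped: %s\n", prop, entry$skipped))
    }
  }
  if (!is.null(x$screening))
    cat("  screening bands:",
        paste(names(x$screening$band_counts), x$screening$band_counts,
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Serialize the run's numeric results (no timestamps, so identical seeds
# give byte-identical reports).
run_report <- function(run) {
  stage2 <- lapply(run$stage2, function(entry) {
    if (!is.null(entry$skipped)) return(list(skipped = entry$skipped))
    m <- entry$metrics
    if (is.null(m)) return(list(fitted = TRUE))
    list(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
         f1 = m$f1, fpr = m$fpr, auc = m$auc,
         confusion = c(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn))
  })
  list(seed = run$config$seed,
       n_removed_descriptors = length(run$removed_descriptors),
       n_train = length(run$split$train_ids),
       n_test = length(run$split$test_ids),
       selected_activity = run$selection_activity$selected_names,
       selected_admet = run$selection_admet$selected_names,
       stage1 = run$stage1_metrics[c("mre", "mse", "mae", "r2")],
       gate = list(threshold = run$gate$threshold,
                   inclusive = run$gate$inclusive,
                   source = run$gate$prediction_source,
                   retained = run$gate$n_retained,
                   rejected = run$gate$n_rejected),
       stage2 = stage2,
       stage2_skipped = run$stage2_skipped,
       phi = if (!is.null(run$phi)) as.data.frame(run$phi$phi) else NULL,
       top_descriptors = if (!is.null(run$importance))
         head(run$importance$importance, 10) else NULL,
       screening_bands = if (!is.null(run$screening))
         as.list(run$screening$band_counts) else NULL)
}

write_run_artifacts <- function(run, out_dir) {
  jsonlite::write_json(run_report(run), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(seed = run$config$seed,
         n_compounds = length(run$split$train_ids) +
           length(run$split$test_ids),
         n_train = length(run$split$train_ids),
         n_test = length(run$split$test_ids),
         removed_descriptors = run$removed_descriptors),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  write_selection_report(run$selection_activity,
                         file.path(out_dir, "selected_activity.csv"))
  write_selection_report(run$selection_admet,
                         file.path(out_dir, "selected_admet.csv"))
  jsonlite::write_json(run$stage1_metrics[c("mre", "mse", "mae", "r2")],
                       file.path(out_dir, "stage1_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(run$error_histogram, file.path(out_dir, "error_histogram.csv"),
            row.names = FALSE)
  if (!is.null(run$phi)) {
    write.csv(run$phi$phi, file.path(out_dir, "phi_matrix.csv"))
    write.csv(run$phi$p_value, file.path(out_dir, "phi_pvalues.csv"))
  }
  if (!is.null(run$importance))
    write.csv(run$importance$importance,
              file.path(out_dir, "global_importance.csv"), row.names = FALSE)
  if (!is.null(run$attribution))
    write.csv(run$attribution$attributions,
              file.path(out_dir, "attributions.csv"))
  if (!is.null(run$screening))
    write.csv(run$screening$candidates, file.path(out_dir, "screening.csv"),
              row.names = FALSE)
  invisible(out_dir)
}
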
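# Small planted binary-classification benchmark via the generator.
admet_bench <- function(n = 600, seed = 1) {
  cfg <- synthetic_config(n_compounds = n, n_descriptors = 50,
                          n_informative_activity = 5,
                          n_informative_admet = 40, n_constant_zero = 0,
                          seed = seed)
  ds <- generate_dataset(cfg)
  X <- apply_minmax(ds$descriptors, fit_minmax(ds$descriptors))
  labels <- as.matrix(ds$admet[, -1])
  rownames(labels) <- ds$admet$compound_id
  list(X = X[, ds$ground_truth$admet_pool], labels = labels)
}

test_that("the activity gate applies its threshold rule", {
  preds <- c(a = 5.9, b = 6.0, c = 7.2)
  g_in <- gate_by_activity(preds, 6, inclusive = TRUE)
  expect_setequal(g_in$retained_ids, c("b", "c"))
  g_ex <- gate_by_activity(preds, 6, inclusive = FALSE)
  expect_setequal(g_ex$retained_ids, "c")
  expect_equal(g_ex$rejected_ids, c("a", "b"))
  empty <- gate_by_activity(setNames(numeric(0), character(0)))
  expect_equal(empty$n_retained, 0L)
})

test_that("stacking configurations default to the per-property menus", {
  expect_identical(stacking_config("Caco-2")$base_learners,
                   c("svm", "boosted_trees", "hist_boosted_trees"))
  expect_identical(stacking_config("CYP3A4")$base_learners,
                   c("knn", "bagged_forest", "boosted_trees",
                     "hist_boosted_trees"))
  expect_identical(stacking_config("hERG")$base_learners,
                   c("knn", "bagged_forest", "boosted_trees"))
  expect_identical(stacking_config("HOB")$base_learners,
                   c("knn", "boosted_trees"))
  expect_identical(stacking_config("MN")$base_learners,
                   c("boosted_trees", "hist_boosted_trees"))
  expect_equal(stacking_config("HOB")$folds, 5L)
  expect_identical(stacking_config("HOB")$meta_learner, "gaussian_nb")
  expect_error(stacking_config("HOB", "svm"), "at least 2")
  expect_error(stacking_config("XYZ"), "unknown ADMET property")
})

test_that("meta-features are out-of-fold: one column per base learner, no self-training", {
  d <- admet_bench(n = 300, seed = 4)
  y <- d$labels[, "Caco-2"]
  cfg <- stacking_config("Caco-2",
                         c("bagged_forest", "boosted_trees", "hist_boosted_trees"),
                         folds = 3, seed = 9)
  model <- fit_stacking(cfg, d$X, y)
  expect_equal(dim(model$oof_meta), c(300L, 3L))
  expect_true(all(model$oof_meta >= 0 & model$oof_meta <= 1))

  # reproduce one fold's base fit by hand: rows of that fold must have
  # received predictions from a model trained without them
  canon <- order(rownames(d$X))
  Xc <- qsarscreen:::as_plain_matrix(d$X)[canon, ]
  yc <- y[canon]
  fold_of <- qsarscreen:::stratified_folds(yc, 3,
                                           qsarscreen:::fanout_seed(9, 1L))
  hold <- which(fold_of == 2L)
  refit <- qsarscreen:::fit_base_learner("boosted_trees", Xc[-hold, ],
                                         yc[-hold],
                                         seed = qsarscreen:::fanout_seed(9, 10L * 2L + 2L))
  manual <- qsarscreen:::predict_base_prob("boosted_trees", refit, Xc[hold, ])
  expect_equal(unname(model$oof_meta[rownames(Xc)[hold], "boosted_trees"]),
               unname(manual))
})

test_that("shuffling the training rows permutes the meta-features and nothing else", {
  d <- admet_bench(n = 250, seed = 6)
  y <- d$labels[, "HOB"]
  cfg <- stacking_config("HOB", folds = 3, seed = 2)
  m1 <- fit_stacking(cfg, d$X, y)
  perm <- sample(nrow(d$X))
  m2 <- fit_stacking(cfg, d$X[perm, ], y[perm])
  expect_equal(m2$oof_meta[rownames(d$X), ], m1$oof_meta[rownames(d$X), ])
  newd <- d$X[1:40, ]
  expect_equal(predict(m2, newd), predict(m1, newd))
})

test_that("stacked prediction is bounded, thresholded at 0.5 and deterministic", {
  d <- admet_bench(n = 300, seed = 8)
  y <- d$labels[, "MN"]
  cfg <- stacking_config("MN", folds = 3, seed = 5)
  model <- fit_stacking(cfg, d$X, y)
  pr <- predict(model, d$X)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_identical(pr$label, as.integer(pr$probability >= 0.5))
  model2 <- fit_stacking(cfg, d$X, y)
  expect_identical(predict(model2, d$X), pr)
  expect_error(fit_stacking(cfg, d$X, rep(1, nrow(d$X))), "single-class")
  expect_error(predict(model, d$X[, 1:5]), "missing descriptor")
})

test_that("stacking separates a planted ADMET endpoint on held-out data", {
  # separable configuration: independent endpoints, each driven by its
  # own descriptor block
  eye <- diag(5)
  dimnames(eye) <- list(names(synthetic_config()$admet_prevalences),
                        names(synthetic_config()$admet_prevalences))
  ds <- generate_dataset(synthetic_config(
    n_compounds = 1000, n_descriptors = 50, n_informative_admet = 40,
    n_constant_zero = 0, latent_correlation = eye, seed = 10))
  X <- apply_minmax(ds$descriptors, fit_minmax(ds$descriptors))
  X <- X[, ds$ground_truth$admet_pool]
  y <- ds$admet[["CYP3A4"]]
  names(y) <- ds$admet$compound_id
  split <- split_train_test(rownames(X), 0.8, seed = 10)
  model <- fit_stacking(stacking_config("CYP3A4", folds = 5, seed = 10),
                        X[split$train_ids, ], y[split$train_ids])
  pr <- predict(model, X[split$test_ids, ])
  auc <- compute_auc(y[split$test_ids], pr$probability)
  expect_gte(auc, 0.95)
})
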
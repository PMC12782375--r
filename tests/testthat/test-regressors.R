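linear_data <- function(n = 500, p = 5, seed = 5) {
  m <- random_descriptors(n, p, seed = seed)
  y <- 6 + 1.5 * m[, 1] + rnorm(n, 0, 0.15)
  list(m = m, y = y)
}

test_that("every regressor family fits, predicts finitely and is seed-deterministic", {
  d <- linear_data(n = 200)
  for (fam in c("bagged_forest", "boosted_trees", "hist_boosted_trees")) {
    spec <- regressor_spec(fam, seed = 42)
    f1 <- fit_regressor(spec, d$m, d$y)
    p1 <- predict(f1, d$m)
    expect_true(all(is.finite(p1)), info = fam)
    f2 <- fit_regressor(spec, d$m, d$y)
    expect_identical(p1, predict(f2, d$m), info = fam)
  }
  expect_error(fit_regressor(regressor_spec("boosted_trees",
                                            list(nonsense = 1))),
               "unknown hyperparameter")
  expect_warning(fit_regressor(regressor_spec("boosted_trees", seed = 1),
                               d$m[1:50, ], rep(2, 50)), "constant")
})

test_that("boosted trees recover a linear signal with high test R2", {
  d <- linear_data(n = 500)
  s <- split_train_test(rownames(d$m), 0.8, seed = 2)
  fit <- fit_regressor(regressor_spec("boosted_trees", seed = 2),
                       d$m[s$train_ids, ], d$y[s$train_ids])
  m <- evaluate_regression(d$y[s$test_ids], predict(fit, d$m[s$test_ids, ]))
  expect_gte(m$r2, 0.9)
})

test_that("prediction demands the model's descriptor columns", {
  d <- linear_data(n = 100, p = 4)
  fit <- fit_regressor(regressor_spec("hist_boosted_trees", seed = 1), d$m, d$y)
  expect_error(predict(fit, d$m[, 1:3]), "missing descriptor")
  # column order at prediction time does not matter
  expect_equal(predict(fit, d$m[, 4:1]), predict(fit, d$m))
})

test_that("a single-layer cascade predicts the mean of its four forests", {
  d <- linear_data(n = 120, p = 4)
  cf <- fit_cascade_forest(unclass(d$m), d$y, max_layers = 1, seed = 3)
  expect_equal(cf$n_layers, 1L)
  manual <- rowMeans(sapply(cf$layers[[1]], function(f)
    predict(f, data = as.data.frame(unclass(d$m)),
            num.threads = 1)$predictions))
  expect_equal(unname(predict(cf, d$m)), unname(manual))
})

test_that("cascade depth respects max_layers and deepening helps on a nonlinear target", {
  set.seed(9)
  n <- 1000
  m <- random_descriptors(n, 6, seed = 9)
  y <- sin(2 * unclass(m)[, 1]) + unclass(m)[, 2] * unclass(m)[, 3] +
    rnorm(n, 0, 0.2)
  tr <- 1:800; te <- 801:1000
  layer_spec <- list(num_trees = 150L)
  shallow <- fit_cascade_forest(unclass(m)[tr, ], y[tr], layer_spec,
                                max_layers = 1, seed = 4)
  deep <- fit_cascade_forest(unclass(m)[tr, ], y[tr], layer_spec,
                             max_layers = 4, early_stop_rounds = 1, seed = 4)
  expect_lte(deep$n_layers, 4L)
  mse <- function(fit) mean((y[te] - predict(fit, unclass(m)[te, ]))^2)
  expect_lte(mse(deep), mse(shallow) * 1.001)
  expect_error(fit_cascade_forest(unclass(m)[tr, ], y[tr], max_layers = 0),
               "max_layers")
  expect_error(fit_cascade_forest(unclass(m)[1:30, ], y[1:30]), "n >= 50")
})

test_that("cascade family works through the common regressor interface", {
  d <- linear_data(n = 150, p = 4)
  fit <- fit_regressor(regressor_spec("cascade_forest",
                                      list(num_trees = 100L, max_layers = 2L),
                                      seed = 6), d$m, d$y)
  expect_s3_class(fit, "qsar_regressor")
  expect_true(all(is.finite(predict(fit, d$m))))
})

test_that("tuning always contains the defaults and never harms the CV score", {
  d <- linear_data(n = 150, p = 4)
  t1 <- tune_hyperparameters("boosted_trees", d$m, d$y, budget = 1, folds = 3,
                             seed = 8)
  expect_identical(t1$best_hyperparams, default_hyperparams("boosted_trees"))
  t4 <- tune_hyperparameters("boosted_trees", d$m, d$y, budget = 4, folds = 3,
                             seed = 8)
  expect_lte(t4$best_score, t4$default_score)
  expect_equal(t4$trials$score[1], t1$best_score)
  # reproducible under the same seed
  t4b <- tune_hyperparameters("boosted_trees", d$m, d$y, budget = 4, folds = 3,
                              seed = 8)
  expect_identical(t4$trials, t4b$trials)
  expect_error(tune_hyperparameters("boosted_trees", d$m, d$y, budget = 0),
               "budget")
})

test_that("feature-set comparison keeps names and rewards informative sets", {
  set.seed(12)
  m <- random_descriptors(400, 12, seed = 12)
  y <- 6 + unclass(m)[, 1] - unclass(m)[, 2] + rnorm(400, 0, 0.3)
  sets <- list(informative = colnames(m)[1:4],
               informative_too = colnames(m)[1:4],
               noise_only = colnames(m)[9:12])
  spec <- regressor_spec("hist_boosted_trees", seed = 12)
  tab <- compare_feature_sets(sets, m, y, spec, seed = 12)
  expect_equal(nrow(tab), 3L)
  expect_identical(tab$feature_set, names(sets))
  expect_equal(tab$r2[1], tab$r2[2])  # identical sets, identical metrics
  expect_gt(tab$r2[1], tab$r2[3])
  expect_error(compare_feature_sets(list(bad = "nope"), m, y, spec),
               "unknown descriptor")
})
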
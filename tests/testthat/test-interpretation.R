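test_that("phi coefficient reproduces worked tables and limit cases", {
  r <- phi_coefficient(contingency_2x2(40, 10, 10, 40))
  expect_equal(r$phi, 0.6)
  expect_equal(r$chi2, 36)
  expect_equal(r$stars, "***")

  expect_equal(phi_coefficient(contingency_2x2(25, 25, 25, 25))$phi, 0)
  expect_equal(phi_coefficient(contingency_2x2(30, 0, 0, 30))$phi, 1)
  expect_error(phi_coefficient(contingency_2x2(5, 5, 0, 0)), "marginal")
})

test_that("chi-square equals n * phi^2 and matches the classical test", {
  set.seed(31)
  for (i in 1:1000) {
    cells <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.05, 1))[, 1]
    if (any(cells[1] + cells[2] == 0, cells[3] + cells[4] == 0,
            cells[1] + cells[3] == 0, cells[2] + cells[4] == 0)) next
    t <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    r <- phi_coefficient(t)
    expect_equal(r$chi2, t$n * r$phi^2, tolerance = 1e-12)
    expect_equal(r$phi, oracle_phi(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
  # spot-check statistic and p against stats::chisq.test without correction
  tab <- matrix(c(40, 10, 10, 40), 2)
  ct <- chisq.test(tab, correct = FALSE)
  r <- phi_coefficient(contingency_2x2(40, 10, 10, 40))
  expect_equal(r$chi2, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("relabeling one margin negates phi", {
  r <- phi_coefficient(contingency_2x2(35, 15, 20, 30))
  flipped <- phi_coefficient(contingency_2x2(15, 35, 30, 20))  # 0<->1 in var 2
  expect_equal(flipped$phi, -r$phi)
})

test_that("the association matrix is symmetric with unit diagonal and correct limits", {
  set.seed(32)
  n <- 10000
  ind <- cbind(A = rbinom(n, 1, 0.4), B = rbinom(n, 1, 0.6),
               C = rbinom(n, 1, 0.3))
  pm <- phi_association_matrix(ind)
  expect_equal(diag(pm$phi), c(A = 1, B = 1, C = 1))
  expect_equal(pm$phi, t(pm$phi))
  expect_lt(max(abs(pm$phi[upper.tri(pm$phi)])), 0.05)

  dup <- cbind(A = ind[, 1], B = ind[, 1])
  expect_equal(phi_association_matrix(dup)$phi["A", "B"], 1)

  const <- cbind(A = ind[1:50, 1], B = rep(1, 50))
  expect_warning(pc <- phi_association_matrix(const), "constant")
  expect_true(is.na(pc$phi["A", "B"]))
})

test_that("tree attributions satisfy local accuracy for both boosted families", {
  set.seed(33)
  X <- random_descriptors(300, 10, seed = 33)
  y <- 6 + unclass(X)[, 1] - 0.8 * unclass(X)[, 2] +
    0.5 * unclass(X)[, 3] * unclass(X)[, 4] + rnorm(300, 0, 0.3)
  for (fam in c("boosted_trees", "hist_boosted_trees")) {
    fit <- fit_regressor(regressor_spec(fam, seed = 7), X, y)
    a <- compute_attributions(fit, X)
    gap <- max(abs(rowSums(a$attributions) + a$base_value - a$prediction))
    expect_lt(gap, 1e-6)
    # double-precision traversal agrees with the booster's float32 predict
    expect_equal(a$prediction, unname(predict(fit, X)), tolerance = 1e-4)
  }
  forest <- fit_regressor(regressor_spec("bagged_forest", seed = 7), X, y)
  expect_error(compute_attributions(forest, X), "boosted_trees")
})

test_that("a descriptor never used in a split receives zero attribution", {
  set.seed(34)
  X <- random_descriptors(200, 3, seed = 34)
  Xc <- unclass(X)
  Xc[, 3] <- 0.5  # constant dummy: no split can use it
  y <- Xc[, 1] + rnorm(200, 0, 0.1)
  fit <- fit_regressor(regressor_spec("boosted_trees",
                                      list(nrounds = 20L), seed = 3),
                       descriptor_matrix(Xc), y)
  a <- compute_attributions(fit, descriptor_matrix(Xc))
  expect_true(all(a$attributions[, 3] == 0))
})

test_that("attributions equal brute-force Shapley on small trees", {
  set.seed(35)
  # depth-1 stump on one effectively binary feature
  X1 <- matrix(c(rep(0, 40), rep(1, 40), rnorm(80)), 80, 2,
               dimnames = list(sprintf("c%02d", 1:80), c("bin", "noise")))
  y1 <- 2 + 3 * X1[, "bin"]
  stump <- fit_regressor(regressor_spec("boosted_trees",
                                        list(nrounds = 1L, max_depth = 1L,
                                             eta = 1), seed = 1),
                         X1, y1)
  a1 <- compute_attributions(stump, X1)
  # with one active feature the attribution is prediction minus baseline
  expect_equal(unname(a1$attributions[, "bin"]),
               a1$prediction - a1$base_value, tolerance = 1e-9)
  or1 <- oracle_shapley(stump, X1[1, ])
  expect_equal(as.numeric(a1$attributions[1, ]), or1$phi, tolerance = 1e-9)

  # three features, a few boosted rounds, depth 2 (<= 7 leaves per tree)
  X3 <- random_descriptors(150, 3, seed = 36)
  y3 <- unclass(X3)[, 1] + 0.5 * unclass(X3)[, 2] * unclass(X3)[, 3] +
    rnorm(150, 0, 0.1)
  small <- fit_regressor(regressor_spec("boosted_trees",
                                        list(nrounds = 3L, max_depth = 2L),
                                        seed = 2), X3, y3)
  a3 <- compute_attributions(small, X3)
  for (i in c(1, 7, 50)) {
    or <- oracle_shapley(small, unclass(X3)[i, ])
    expect_equal(as.numeric(a3$attributions[i, ]), or$phi, tolerance = 1e-9)
    expect_equal(a3$base_value - small$base_score, or$base, tolerance = 1e-9)
  }
})

test_that("global importance ranks by mean absolute attribution", {
  attr0 <- structure(list(
    attributions = matrix(0, 4, 3, dimnames = list(letters[1:4], c("x", "y", "z"))),
    base_value = 0, prediction = rep(0, 4),
    feature_values = matrix(0, 4, 3, dimnames = list(letters[1:4], c("x", "y", "z"))),
    compound_ids = letters[1:4]), class = "attribution_matrix")
  gi0 <- global_importance(attr0)
  expect_equal(gi0$importance$mean_abs_attribution, rep(0, 3))
  expect_identical(gi0$importance$descriptor, c("x", "y", "z"))

  attr1 <- attr0
  attr1$attributions[, "y"] <- c(1, -1, 1, -1)
  gi1 <- global_importance(attr1)
  expect_identical(gi1$importance$descriptor[1], "y")
  expect_equal(gi1$importance$mean_abs_attribution[1], 1)
})

test_that("a stronger planted effect earns a larger global importance", {
  wins <- 0L
  for (seed in 1:10) {
    X <- random_descriptors(300, 5, seed = 100 + seed)
    y <- 2 * unclass(X)[, 1] + 1 * unclass(X)[, 2] + rnorm(300, 0, 0.2)
    fit <- fit_regressor(regressor_spec("hist_boosted_trees", seed = seed),
                         X, y)
    gi <- global_importance(compute_attributions(fit, X))
    imp <- setNames(gi$importance$mean_abs_attribution, gi$importance$descriptor)
    if (imp[colnames(X)[1]] > imp[colnames(X)[2]]) wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})
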
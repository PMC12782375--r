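planted_univariate <- function(n = 1000, p = 50, seed = 7) {
  m <- random_descriptors(n, p, seed = seed)
  target <- m[, 5] + rnorm(n, 0, 0.1)
  list(m = m, target = target, informative = colnames(m)[5])
}

test_that("a planted informative descriptor is ranked first by all three methods", {
  d <- planted_univariate()
  for (method in c("mi", "forest_impurity", "boosting_gain")) {
    rk <- rank_features(d$m, d$target, method, seed = 11)
    expect_equal(unname(rk[d$informative]), 1, info = method)
  }
})

test_that("rank columns are valid fractional rankings and equivariant to column order", {
  d <- planted_univariate(n = 200, p = 12)
  rk <- rank_features(d$m, d$target, "mi")
  expect_equal(sum(rk), 12 * 13 / 2)
  perm <- sample(ncol(d$m))
  rk_perm <- rank_features(d$m[, perm], d$target, "mi")
  expect_equal(rk_perm, rk[colnames(d$m)[perm]])
  # exact duplicate columns share a fractional rank
  m2 <- d$m
  m2[, 2] <- m2[, 1]
  rk2 <- rank_features(descriptor_matrix(unclass(m2)), m2[, 1] + rnorm(200, 0, .01), "mi")
  expect_equal(rk2[[1]], rk2[[2]])
  expect_equal(rk2[[1]], 1.5)
})

test_that("rank aggregation follows the average-rank rule exactly", {
  r1 <- c(a = 1, b = 2, c = 3)
  r2 <- c(a = 2, b = 3, c = 1)
  r3 <- c(a = 3, b = 1, c = 2)
  fr <- aggregate_ranks(r1, r2, r3)
  expect_s3_class(fr, "feature_ranking")
  expect_equal(fr$average_rank, c(2, 2, 2))
  expect_equal(aggregate_ranks(c(a = 1, b = 2), c(a = 1, b = 2),
                               c(a = 1, b = 2))$average_rank[1], 1)
  # A=(1,2,3) and B=(3,2,1) average to the same 2.0 and stay tied
  frab <- aggregate_ranks(c(A = 1, B = 3), c(A = 2, B = 2), c(A = 3, B = 1))
  expect_equal(frab$average_rank, c(2, 2))
  expect_error(aggregate_ranks(r1, r2[1:2], r3), "different descriptor sets")
})

test_that("selection returns exactly k descriptors ordered by fused rank", {
  d <- planted_univariate(n = 300, p = 30)
  sel <- select_features(d$m, d$target, k = 20, seed = 3)
  expect_length(sel$selected_names, 20L)
  expect_length(unique(sel$selected_names), 20L)
  expect_true(all(sel$selected_names %in% colnames(d$m)))
  expect_true(d$informative %in% sel$selected_names)
  expect_false(is.unsorted(sel$ranking$final_rank))
  expect_error(select_features(d$m, d$target, k = 0), "positive")
  expect_error(select_features(d$m, d$target, k = 31), "exceeds")
})

test_that("ties at the selection boundary break lexicographically by name", {
  fake_ranks <- function(m, target, method, seed, cfg) {
    setNames(rep(1.5, ncol(m)), colnames(m))  # everything tied
  }
  testthat::local_mocked_bindings(rank_features = fake_ranks,
                                  .package = "qsarscreen")
  m <- random_descriptors(30, 6, seed = 2)
  colnames(m) <- c("zeta", "beta", "alpha", "gamma", "delta", "eps")
  sel <- select_features(descriptor_matrix(unclass(m),
                                           descriptor_names = colnames(m)),
                         rnorm(30), k = 2, seed = 1)
  expect_identical(sel$selected_names, c("alpha", "beta"))
})

test_that("selection recovers planted informative descriptors", {
  cfg <- synthetic_config(n_compounds = 1000, n_descriptors = 200,
                          n_informative_activity = 10,
                          n_informative_admet = 20, n_constant_zero = 0,
                          seed = 31)
  ds <- generate_dataset(cfg)
  X <- apply_minmax(ds$descriptors, fit_minmax(ds$descriptors))
  sel <- select_features(X, ds$activity$pic50, k = 20, seed = 31)
  recall <- mean(ds$ground_truth$informative_activity %in% sel$selected_names)
  expect_gte(recall, 0.8)
})

test_that("multi-target fusion produces one set from five binary targets", {
  cfg <- synthetic_config(n_compounds = 400, n_descriptors = 50,
                          n_informative_activity = 5,
                          n_informative_admet = 20, n_constant_zero = 0,
                          seed = 17)
  ds <- generate_dataset(cfg)
  X <- apply_minmax(ds$descriptors, fit_minmax(ds$descriptors))
  labels <- as.matrix(ds$admet[, -1])
  rownames(labels) <- ds$admet$compound_id
  sel <- select_features(X, labels, k = 15, seed = 17)
  expect_length(sel$selected_names, 15L)
  expect_length(sel$per_target_rankings, 5L)
  # fused score is the mean of the five per-target average ranks
  per <- sapply(sel$per_target_rankings, function(rk)
    setNames(rk$average_rank, rk$descriptor)[sel$ranking$descriptor])
  expect_equal(unname(rowMeans(per)), sel$ranking$final_rank)
  # a fair share of the informative pool is found
  recall <- mean(ds$ground_truth$admet_pool %in%
                   select_features(X, labels, k = 20, seed = 17)$selected_names)
  expect_gte(recall, 0.5)
  # per-target mode returns one selection per property
  selp <- select_features(X, labels, k = 10, fusion_mode = "per_target",
                          seed = 17)
  expect_named(selp$selected_names, colnames(labels))
  expect_true(all(lengths(selp$selected_names) == 10L))
})
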
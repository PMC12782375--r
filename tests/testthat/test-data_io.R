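test_that("descriptor CSV ingestion preserves values and order, and rejects bad tables", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(Name = c("a", "b", "c"),
                   D1 = c(1.5, 2.25, -3), D2 = c(0, 1, 2),
                   D3 = c(10, 20, 30), D4 = c(-1, 0, 1))
  write.csv(df, tmp, row.names = FALSE)
  m <- read_descriptor_table(tmp)
  expect_equal(dim(m), c(3L, 4L))
  expect_identical(colnames(m), c("D1", "D2", "D3", "D4"))
  expect_identical(rownames(m), c("a", "b", "c"))
  expect_identical(as.numeric(m[, "D1"]), df$D1)

  df_dup <- df; df_dup$Name[2] <- "a"
  write.csv(df_dup, tmp, row.names = FALSE)
  expect_error(read_descriptor_table(tmp), "duplicate compound id.*a")

  df_na <- df; df_na$D2[3] <- "NA"
  write.csv(df_na, tmp, row.names = FALSE)
  expect_error(read_descriptor_table(tmp), "column 'D2', row 3")

  expect_error(read_descriptor_table("/nonexistent/x.csv"), "not found")
})

test_that("descriptor tables round-trip through CSV bit-identically", {
  m <- random_descriptors(20, 6, seed = 42)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(m, tmp)
  m2 <- read_descriptor_table(tmp)
  expect_identical(unclass(m2), unclass(m))
})

test_that("label tables validate their schema", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(Name = c("a", "b"), pIC50 = c(6.5, 5)), tmp,
            row.names = FALSE)
  act <- read_label_table(tmp, "activity")
  expect_equal(act$pic50, c(6.5, 5))

  adm_df <- data.frame(Name = c("a", "b"), `Caco-2` = c(1, 0),
                       CYP3A4 = c(0, 1), hERG = c(1, 1), HOB = c(0, 0),
                       MN = c(1, 0), check.names = FALSE)
  write.csv(adm_df, tmp, row.names = FALSE)
  adm <- read_label_table(tmp, "admet")
  expect_equal(ncol(adm), 6L)
  expect_true(all(unlist(adm[, -1]) %in% 0:1))

  adm_df$hERG[1] <- 2
  write.csv(adm_df, tmp, row.names = FALSE)
  expect_error(read_label_table(tmp, "admet"), "hERG.*outside")

  write.csv(adm_df[, -3], tmp, row.names = FALSE)
  expect_error(read_label_table(tmp, "admet"), "missing ADMET column")
})

test_that("IC50 to pIC50 conversion is exact, invertible and monotone", {
  expect_equal(ic50_to_pic50(1000, "nM"), 6)
  expect_equal(ic50_to_pic50(1, "nM"), 9)
  expect_equal(ic50_to_pic50(50, "nM"), -log10(5e-8), tolerance = 1e-12)
  expect_equal(ic50_to_pic50(1, "uM"), 6)
  expect_error(ic50_to_pic50(-1), "positive")
  expect_error(ic50_to_pic50(10, "mM"), "arg")
  # round trip within 1e-12 relative
  vals <- 10^runif(50, -2, 5)
  back <- 10^(-ic50_to_pic50(vals, "nM")) / 1e-9
  expect_equal(back, vals, tolerance = 1e-12)
  # strictly decreasing
  x <- sort(10^runif(100, -2, 5))
  expect_true(all(diff(ic50_to_pic50(x, "nM")) < 0))
})

test_that("uninformative descriptors are removed by the stated rule", {
  m <- random_descriptors(10, 5)
  m[, 3] <- 0
  res <- drop_uninformative_descriptors(m, "zero_constant")
  expect_equal(ncol(res$matrix), 4L)
  expect_identical(res$removed, colnames(m)[3])
  expect_identical(colnames(res$matrix), colnames(m)[-3])

  m[, 2] <- 3.7  # constant but nonzero: survives zero_constant mode
  expect_equal(ncol(drop_uninformative_descriptors(m, "zero_constant")$matrix), 4L)
  res2 <- drop_uninformative_descriptors(m, "zero_variance")
  expect_setequal(res2$removed, colnames(m)[2:3])

  z <- descriptor_matrix(matrix(0, 4, 2, dimnames = list(letters[1:4], c("x", "y"))))
  expect_error(drop_uninformative_descriptors(z), "degenerate")
})

test_that("min-max normalization maps train columns to [0,1] and does not clamp", {
  m <- descriptor_matrix(matrix(c(2, 4, 6), 3, 1,
                                dimnames = list(letters[1:3], "d")))
  st <- fit_minmax(m)
  expect_equal(as.numeric(apply_minmax(m, st)), c(0, 0.5, 1))
  test <- descriptor_matrix(matrix(8, 1, 1, dimnames = list("z", "d")))
  expect_equal(as.numeric(apply_minmax(test, st)), 1.5)

  big <- random_descriptors(40, 8, seed = 9)
  stb <- fit_minmax(big)
  norm <- apply_minmax(big, stb)
  expect_equal(unname(apply(norm, 2, min)), rep(0, 8))
  expect_equal(unname(apply(norm, 2, max)), rep(1, 8))

  cm <- big; cm[, 1] <- 5
  stc <- fit_minmax(cm)
  expect_warning(res <- apply_minmax(cm, stc), "constant")
  expect_true(all(res[, 1] == 0))

  expect_error(apply_minmax(
    descriptor_matrix(matrix(1, 2, 1, dimnames = list(c("a", "b"), "other"))),
    stb), "missing")
})

test_that("train/test splits follow the floor rule and are seed-deterministic", {
  s <- split_train_test(letters[1:10], 0.8, seed = 3)
  expect_length(s$train_ids, 8L)
  expect_length(s$test_ids, 2L)

  ids <- sprintf("c%04d", 1:1974)
  s2 <- split_train_test(ids, 0.8, seed = 11)
  expect_length(s2$train_ids, 1579L)
  expect_length(s2$test_ids, 395L)

  expect_identical(split_train_test(ids, 0.8, seed = 5),
                   split_train_test(ids, 0.8, seed = 5))
  expect_error(split_train_test("one", 0.8, 1), "too few")
})

test_that("splits are disjoint and exhaustive across many seeds", {
  ids <- sprintf("c%03d", 1:37)
  for (seed in 1:1000) {
    s <- split_train_test(ids, 0.8, seed)
    expect_length(intersect(s$train_ids, s$test_ids), 0L)
    expect_setequal(c(s$train_ids, s$test_ids), ids)
  }
})
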
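test_that("RF importance ranks a planted informative feature first", {
  fm <- planted_feature_matrix(n = 200, d = 10, seed = 1)
  r1 <- rank_features(fm, seed = 3)
  r2 <- rank_features(fm, seed = 3)
  expect_identical(as.data.frame(r1), as.data.frame(r2))  # determinism
  expect_identical(r1$feature[1], "signal")
  expect_true(all(diff(r1$importance) <= 0))              # non-increasing
})

test_that("constant features get zero importance and sort last", {
  fm <- planted_feature_matrix(n = 150, d = 6, seed = 2)
  vals <- fm$values
  vals[, "noise5"] <- 1.0
  fm2 <- feature_matrix(vals, ids = fm$ids, labels = fm$labels)
  r <- rank_features(fm2, seed = 4)
  expect_equal(r$importance[r$feature == "noise5"], 0)
  expect_identical(r$feature[nrow(r)], "noise5")
})

test_that("zero-importance features are dropped, with degenerate warnings", {
  r <- structure(
    data.frame(feature = paste0("f", 1:5),
               importance = c(3, 2, 1, 0, 0)),
    class = c("ranked_features", "data.frame"), n_nonzero = 3L
  )
  expect_equal(nrow(drop_zero_importance(r)), 3)
  r$importance <- c(5, 4, 3, 2, 1)
  expect_equal(nrow(drop_zero_importance(r)), 5)
  r$importance <- rep(0, 5)
  expect_warning(out <- drop_zero_importance(r), "zero importance")
  expect_equal(nrow(out), 0)
})

test_that("IFS evaluates nested prefixes and picks the informative one", {
  fm <- planted_feature_matrix(n = 200, d = 10, seed = 4)
  ranked <- drop_zero_importance(rank_features(fm, seed = 5))
  ifs <- incremental_feature_selection(fm, ranked, folds = 5, seed = 6)
  expect_identical(ifs$trace$size, seq_len(nrow(ranked)))
  expect_true("signal" %in% ifs$best_subset)
  expect_lte(ifs$best_size, 3)
  # nested-prefix invariant and MCC at k=1 not beaten by larger prefixes
  expect_identical(ifs$best_subset, ranked$feature[seq_len(ifs$best_size)])
  expect_gte(ifs$trace$mcc[1], max(ifs$trace$mcc) - 1e-9)
})

test_that("IFS respects max_size, step, and reports evaluator failures", {
  fm <- planted_feature_matrix(n = 100, d = 10, seed = 7)
  ranked <- rank_features(fm, seed = 8)
  fake_eval <- function(sub_fm) {
    structure(list(sen = 1, spe = 1, pre = 1, acc = 1, f1 = 1,
                   mcc = ncol(sub_fm$values) / 100), class = "metric_set")
  }
  ifs <- incremental_feature_selection(fm, ranked, evaluator = fake_eval,
                                       max_size = 3)
  expect_equal(nrow(ifs$trace), 3)
  stepped <- incremental_feature_selection(fm, ranked, evaluator = fake_eval,
                                           max_size = 9, step = 2)
  expect_identical(stepped$trace$size, c(1L, 3L, 5L, 7L, 9L))

  boom <- function(sub_fm) {
    if (ncol(sub_fm$values) == 2) stop("synthetic failure") else fake_eval(sub_fm)
  }
  expect_error(
    incremental_feature_selection(fm, ranked, evaluator = boom, max_size = 4),
    "subset size 2"
  )
})

test_that("IFS with a deterministic evaluator is bit-for-bit reproducible", {
  fm <- planted_feature_matrix(n = 120, d = 8, seed = 9)
  ranked <- rank_features(fm, seed = 10)
  a <- incremental_feature_selection(fm, ranked, max_size = 4, folds = 3,
                                     seed = 11)
  b <- incremental_feature_selection(fm, ranked, max_size = 4, folds = 3,
                                     seed = 11)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_subset, b$best_subset)
})

test_that("MCC ties across prefix sizes resolve to the smallest prefix", {
  fm <- planted_feature_matrix(n = 100, d = 6, seed = 12)
  ranked <- rank_features(fm, seed = 13)
  const_eval <- function(sub_fm) {
    structure(list(sen = 1, spe = 1, pre = 1, acc = 1, f1 = 1, mcc = 0.5),
              class = "metric_set")
  }
  ifs <- incremental_feature_selection(fm, ranked, evaluator = const_eval,
                                       max_size = 5)
  expect_equal(ifs$best_size, 1)
})
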
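test_that("metric suite matches hand-computed confusion tables", {
  perfect <- compute_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unlist(unclass(perfect)),
               c(sen = 1, spe = 1, pre = 1, acc = 1, f1 = 1, mcc = 1))

  inverted <- compute_metrics(list(tp = 0, fp = 5, tn = 0, fn = 5))
  expect_equal(inverted$acc, 0)
  expect_equal(inverted$mcc, -1)

  m <- compute_metrics(list(tp = 3, fp = 1, tn = 2, fn = 2))
  expect_equal(m$sen, 0.6)
  expect_equal(m$spe, 2 / 3)
  expect_equal(m$pre, 0.75)
  expect_equal(m$acc, 0.625)
  expect_equal(m$f1, 2 * 0.6 * 0.75 / (0.6 + 0.75))
  expect_equal(m$mcc, (3 * 2 - 1 * 2) / sqrt(4 * 5 * 3 * 4))
})

test_that("metrics agree with brute-force recomputation from raw pairs", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    truth <- sample(0:1, n, replace = TRUE)
    calls <- sample(0:1, n, replace = TRUE)
    a <- compute_metrics(confusion_counts(truth, calls))
    b <- brute_metrics(truth, calls)
    expect_equal(unclass(a)[names(b)], b)
  }
})

test_that("MCC and ACC have the expected confusion-table symmetries", {
  set.seed(32)
  for (i in 1:50) {
    c0 <- as.list(stats::setNames(sample(0:20, 4, replace = TRUE),
                                  c("tp", "fp", "tn", "fn")))
    if (sum(unlist(c0)) == 0) next
    m <- compute_metrics(c0)
    swapped <- compute_metrics(list(tp = c0$tn, fp = c0$fn,
                                    tn = c0$tp, fn = c0$fp))
    expect_equal(m$mcc, swapped$mcc)      # simultaneous TP<->TN, FP<->FN
    expect_equal(m$acc, swapped$acc)      # ACC invariant to relabeling
    expect_equal(m$sen, swapped$spe)      # Sen and Spe swap
    expect_equal(m$spe, swapped$sen)
  }
})

test_that("degenerate denominators follow the zero convention", {
  allneg <- compute_metrics(list(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_equal(allneg$sen, 0)
  expect_equal(allneg$pre, 0)
  expect_equal(allneg$mcc, 0)
})

test_that("stratified folds are balanced and reproducible", {
  labels <- rep(c(0L, 1L), each = 50)
  f1 <- ubppred:::stratified_folds(labels, k = 5, seed = 4)
  f2 <- ubppred:::stratified_folds(labels, k = 5, seed = 4)
  expect_identical(f1, f2)
  for (k in 1:5) {
    expect_equal(sum(f1 == k), 20)
    expect_equal(sum(f1 == k & labels == 1), 10)  # balanced within fold
  }
  expect_error(ubppred:::stratified_folds(rep(1L, 10), k = 5), "both classes")
  expect_error(ubppred:::stratified_folds(c(rep(0L, 3), rep(1L, 50)), k = 5),
               "cannot be split")
})

test_that("cross-validation recovers a separable planted signal", {
  fm <- separable_feature_matrix(n = 100, d = 5, seed = 6)
  cv1 <- kfold_cv(fm, k = 5, seed = 11)
  cv2 <- kfold_cv(fm, k = 5, seed = 11)
  expect_equal(cv1$mean, cv2$mean)          # fixed seed reproducibility
  expect_length(cv1$folds, 5)
  expect_gte(cv1$mean$mcc, 0.9)
  cvr <- kfold_cv(fm, k = 5, repeats = 2, seed = 11)
  expect_length(cvr$folds, 10)
})

test_that("independent test scores held-out data and detects leakage", {
  fm <- separable_feature_matrix(n = 120, d = 5, seed = 7)
  train <- ubppred:::subset_rows(fm, 1:80)
  test <- ubppred:::subset_rows(fm, 81:120)
  model <- train_classifier(train, seed = 2)
  m <- independent_test(model, test)
  expect_gte(m$mcc, 0.9)
  expect_equal(independent_test(model, train, check_leakage = FALSE)$mcc, 1,
               tolerance = 1e-9)  # resubstitution on the separable fixture
  expect_error(independent_test(model, ubppred:::subset_rows(fm, 60:120)),
               "train_test_leakage")
  expect_error(independent_test(model, ubppred:::subset_rows(test, integer(0))),
               "empty test set")
})
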
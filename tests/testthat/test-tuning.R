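# Analytic two-objective surrogate with a known optimum: both objectives are
# 1 minus the normalized distance to a fixed interior point of the box.
surrogate_target <- function() {
  c(learning_rate = 0.3, n_estimators = 700, max_depth = 6, subsample = 0.6,
    colsample_bytree = 0.4, gamma = 0.7, reg_alpha = 0.3, reg_lambda = 1.2)
}

normalize_position <- function(p) {
  box <- param_box()
  (unlist(p[rownames(box)]) - box[, "lower"]) / (box[, "upper"] - box[, "lower"])
}

make_surrogate <- function() {
  tn <- normalize_position(as.list(surrogate_target()))
  function(params) {
    d <- sqrt(sum((normalize_position(unclass(params)) - tn)^2)) / sqrt(8)
    list(sen = 1 - d, spe = 1 - d)
  }
}

test_that("Pareto dominance follows the componentwise definition", {
  expect_true(dominates(c(0.9, 0.9), c(0.8, 0.8)))
  expect_false(dominates(c(0.9, 0.7), c(0.7, 0.9)))  # incomparable
  expect_false(dominates(c(0.7, 0.9), c(0.9, 0.7)))
  expect_false(dominates(c(0.5, 0.5), c(0.5, 0.5)))  # equal
  expect_true(dominates(c(0.5, 0.6), c(0.5, 0.5)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "arity")
})

entry <- function(obj) list(position = stats::runif(8), objectives = obj)

test_that("archive insertion maintains strict non-domination", {
  a <- archive_insert(list(), entry(c(0.5, 0.5)))
  expect_length(a, 1)
  a <- archive_insert(a, entry(c(0.6, 0.6)))   # dominates -> replaces
  expect_length(a, 1)
  expect_equal(a[[1]]$objectives, c(0.6, 0.6))
  a <- archive_insert(a, entry(c(0.4, 0.4)))   # dominated -> unchanged
  expect_length(a, 1)
  a <- archive_insert(a, entry(c(0.7, 0.5)))   # incomparable -> grows
  expect_length(a, 2)
})

test_that("random insertion streams never leave dominated pairs behind", {
  set.seed(21)
  a <- list()
  for (i in 1:300) {
    a <- archive_insert(a, entry(stats::runif(2)), capacity = 40)
  }
  obj <- do.call(rbind, lapply(a, `[[`, "objectives"))
  for (i in seq_len(nrow(obj))) {          # brute-force pairwise scan
    for (j in seq_len(nrow(obj))) {
      if (i != j) expect_false(dominates(obj[i, ], obj[j, ]))
    }
  }
  expect_lte(length(a), 40)
})

test_that("capacity pruning keeps boundary points of the front", {
  set.seed(22)
  a <- list()
  for (i in 1:200) {
    t <- stats::runif(1)
    a <- archive_insert(a, entry(c(t, 1 - t)), capacity = 10)
  }
  expect_lte(length(a), 10)
  obj <- do.call(rbind, lapply(a, `[[`, "objectives"))
  expect_gt(max(obj[, 1]), 0.95)  # extremes survive crowding pruning
  expect_gt(max(obj[, 2]), 0.95)
})

test_that("the swarm evaluates swarm_size particles at initialization", {
  calls <- 0L
  counting <- function(params) {
    calls <<- calls + 1L
    list(sen = stats::runif(1), spe = stats::runif(1))
  }
  mopso_tune(counting, swarm_size = 80, max_iter = 1, seed = 1)
  expect_equal(calls, 80L + 80L)  # init + one update sweep
})

test_that("MOPSO approaches a known optimum on the analytic surrogate", {
  res <- mopso_tune(make_surrogate(), swarm_size = 20, max_iter = 50,
                    seed = 4)
  d <- sqrt(sum((normalize_position(unclass(res$best)) -
                   normalize_position(as.list(surrogate_target())))^2)) /
    sqrt(8)
  expect_lt(d, 0.05)  # within 5% of the box diagonal
  # reproducibility under the same seed
  res2 <- mopso_tune(make_surrogate(), swarm_size = 20, max_iter = 50,
                     seed = 4)
  expect_equal(res$best, res2$best)
})

test_that("archive positions always satisfy the box constraints", {
  res <- mopso_tune(make_surrogate(), swarm_size = 10, max_iter = 20,
                    seed = 5)
  box <- param_box()
  for (e in res$archive) {
    expect_true(all(e$position >= box[, "lower"] - 1e-12))
    expect_true(all(e$position <= box[, "upper"] + 1e-12))
    expect_silent(validate_params(e$params))
  }
})

test_that("the best archive objective never degrades across iterations", {
  res <- mopso_tune(make_surrogate(), swarm_size = 15, max_iter = 30,
                    seed = 6)
  expect_true(all(diff(res$history$best_sen) >= -1e-12))
  expect_true(all(diff(res$history$best_spe) >= -1e-12))
})

test_that("a single evaluated candidate is archive and best at once", {
  ev <- make_surrogate()
  res <- mopso_tune(ev, swarm_size = 1, max_iter = 1, seed = 7)
  expect_gte(length(res$archive), 1)
  expect_s3_class(res$best, "hyperparams")
})
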
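#' Rank features by random-forest Gini importance
#'
#' Grows a classification forest and scores each feature by the mean
#' decrease in the Gini index over all splits using it; larger scores rank
#' higher. Ties are broken by original column index so the ranking is
#' deterministic for a fixed seed.
#'
#' @param fm A labeled [feature_matrix()] with at least two samples per
#'   class.
#' @param seed Integer seed.
#' @param n_trees Forest size (default 500).
#' @return An object of class `"ranked_features"`: data.frame with columns
#'   `feature`, `importance` (non-increasing), plus attribute `n_nonzero`.
#' @export
rank_features <- function(fm, seed = 1, n_trees = 500) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("ranking requires labels")
  if (length(unique(fm$labels)) < 2) stop("both classes must be present")
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = fm$values, y = factor(fm$labels, levels = c(0, 1)),
    ntree = n_trees
  )
  imp <- rf$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, seq_along(imp))
  out <- data.frame(feature = colnames(fm$values)[ord],
                    importance = as.numeric(imp[ord]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_features", "data.frame"),
            n_nonzero = sum(imp > 0))
}

#' Drop zero-importance features from a ranking
#'
#' Features never chosen for a split carry importance 0 and contribute
#' nothing; only strictly positive importances are retained.
#'
#' @param ranked A `"ranked_features"` object.
#' @return The filtered `"ranked_features"`; warns if nothing survives.
#' @export
drop_zero_importance <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_features"))
  keep <- ranked$importance > 0
  if (!any(keep)) warning("all features have zero importance")
  out <- ranked[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ranked_features", "data.frame"),
            n_nonzero = sum(keep))
}

#' Incremental feature selection (IFS)
#'
#' Evaluates the nested prefixes of an importance-ranked feature list:
#' for k = 1, 1 + step, ... the top-k features are scored by the evaluator
#' (cross-validated model metrics by default) and the prefix maximizing MCC
#' is selected. On MCC ties the smallest prefix wins.
#'
#' @param fm A labeled [feature_matrix()].
#' @param ranked A non-empty `"ranked_features"` ordering of (a subset of)
#'   the matrix's columns.
#' @param evaluator Function `(sub_fm) -> "metric_set"`; defaults to
#'   [kfold_cv()] with `folds` folds and default hyperparameters.
#' @param max_size Largest prefix evaluated (default: all ranked features).
#' @param step Prefix increment (default 1).
#' @param folds,seed,params,nthread Passed to the default evaluator.
#' @return An object of class `"ifs_trace"`: list with `trace` (data.frame
#'   `size`, `mcc`), `best_size`, `best_mcc` and `best_subset` (character
#'   vector of feature names).
#' @export
incremental_feature_selection <- function(fm, ranked, evaluator = NULL,
                                          max_size = Inf, step = 1,
                                          folds = 5, seed = 1,
                                          params = default_params(),
                                          nthread = 1) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(ranked, "ranked_features"))
  if (nrow(ranked) == 0) stop("empty feature ranking")
  if (is.null(evaluator)) {
    evaluator <- function(sub_fm) {
      kfold_cv(sub_fm, k = folds, seed = seed, params = params,
               nthread = nthread)$mean
    }
  }
  sizes <- as.integer(seq(1, min(max_size, nrow(ranked)), by = step))
  mccs <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    k <- sizes[i]
    sub_fm <- subset_features(fm, ranked$feature[seq_len(k)])
    m <- tryCatch(evaluator(sub_fm), error = function(e) {
      stop("IFS evaluator failed at subset size ", k, ": ",
           conditionMessage(e), call. = FALSE)
    })
    mccs[i] <- m$mcc
  }
  best_i <- which.max(mccs)  # first occurrence wins ties (parsimony)
  best_size <- sizes[best_i]
  structure(
    list(trace = data.frame(size = sizes, mcc = mccs),
         best_size = best_size,
         best_mcc = mccs[best_i],
         best_subset = ranked$feature[seq_len(best_size)]),
    class = "ifs_trace"
  )
}

#' @export
print.ifs_trace <- function(x, ...) {
  cat("IFS over ", nrow(x$trace), " prefix sizes; best size ", x$best_size,
      " (CV MCC ", sprintf("%.3f", x$best_mcc), ")\n", sep = "")
  invisible(x)
}
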
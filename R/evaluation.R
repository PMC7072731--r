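#' Confusion counts from labels and calls
#'
#' @param truth Observed 0/1 labels.
#' @param calls Predicted 0/1 calls.
#' @return List with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, calls) {
  stopifnot(length(truth) == length(calls), length(truth) >= 1)
  truth <- as.integer(truth); calls <- as.integer(calls)
  stopifnot(all(truth %in% 0:1), all(calls %in% 0:1))
  list(tp = sum(truth == 1L & calls == 1L),
       fp = sum(truth == 0L & calls == 1L),
       tn = sum(truth == 0L & calls == 0L),
       fn = sum(truth == 1L & calls == 0L))
}

#' Six binary-classification metrics from confusion counts
#'
#' Computes sensitivity, specificity, precision, accuracy, F1 and the
#' Matthews correlation coefficient:
#' \deqn{Sen = TP/(TP+FN),\quad Spe = TN/(TN+FP),\quad Pre = TP/(TP+FP),}
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN),\quad F1 = 2\,Sen\,Pre/(Sen+Pre),}
#' \deqn{MCC = (TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' Degenerate ratios (zero denominator) are reported as 0, including an MCC
#' whose radicand has a zero factor — the usual convention for empty classes.
#'
#' @param counts A list with `tp`, `fp`, `tn`, `fn` (from
#'   [confusion_counts()]), or `tp` alone with the remaining counts given
#'   separately.
#' @param fp,tn,fn Individual counts when `counts` is the scalar `tp`.
#' @return An object of class `"metric_set"`: named list with `sen`, `spe`,
#'   `pre`, `acc`, `f1` in \[0, 1\] and `mcc` in \[-1, 1\].
#' @export
compute_metrics <- function(counts, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.list(counts)) counts <- list(tp = counts, fp = fp, tn = tn, fn = fn)
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  stopifnot(all(c(tp, fp, tn, fn) >= 0), tp + fp + tn + fn >= 1)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  pre <- safe_div(tp, tp + fp)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  f1 <- safe_div(2 * sen * pre, sen + pre)
  rad <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (rad == 0) 0 else (tp * tn - fp * fn) / sqrt(rad)
  structure(list(sen = sen, spe = spe, pre = pre, acc = acc, f1 = f1,
                 mcc = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sen %.3f  Spe %.3f  Pre %.3f  ACC %.3f  F1 %.3f  MCC %.3f\n",
              x$sen, x$spe, x$pre, x$acc, x$f1, x$mcc))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(sen = x$sen, spe = x$spe, pre = x$pre, acc = x$acc,
             f1 = x$f1, mcc = x$mcc)
}

# Stratified fold assignment: every class is spread evenly across folds.
stratified_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  tab <- table(labels)
  if (length(tab) < 2) stop("both classes must be present")
  if (any(tab < k)) {
    stop("class with ", min(tab), " samples cannot be split into ", k,
         " folds")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == as.integer(cl)))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Randomly divides the dataset into `k` near-equal class-stratified
#' subsets; each subset in turn is held out while a model is trained on the
#' rest, and the held-out metrics are averaged over all folds (and over
#' `repeats` independent fold assignments — `repeats = 2` with `k = 5`
#' yields ten submodels).
#'
#' @param fm A labeled [feature_matrix()].
#' @param k Number of folds (default 5).
#' @param repeats Number of independent fold assignments (default 1).
#' @param seed Integer seed controlling fold assignment and training.
#' @param trainer Function `(train_fm, seed) -> model` whose result is
#'   accepted by [predict_classifier()]; defaults to gradient-boosted
#'   training with `params`.
#' @param params [hyperparams()] used by the default trainer.
#' @param nthread Threads for the default trainer (default 1, reproducible).
#' @return List with `mean` (a `"metric_set"` of fold-averaged metrics) and
#'   `folds` (list of per-fold `"metric_set"`s).
#' @export
kfold_cv <- function(fm, k = 5, repeats = 1, seed = 1, trainer = NULL,
                     params = default_params(), nthread = 1) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  if (is.null(trainer)) {
    trainer <- function(train_fm, seed) {
      train_classifier(train_fm, params = params, seed = seed,
                       nthread = nthread)
    }
  }
  fold_metrics <- list()
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(fm$labels, k, seed = seed + 7919L * (r - 1L))
    for (f in seq_len(k)) {
      train_fm <- subset_rows(fm, fold != f)
      test_fm <- subset_rows(fm, fold == f)
      model <- trainer(train_fm, seed + f + 101L * (r - 1L))
      pred <- predict_classifier(model, test_fm)
      m <- compute_metrics(confusion_counts(test_fm$labels, pred$call))
      fold_metrics[[length(fold_metrics) + 1L]] <- m
    }
  }
  avg <- lapply(c("sen", "spe", "pre", "acc", "f1", "mcc"), function(nm) {
    mean(vapply(fold_metrics, `[[`, numeric(1), nm))
  })
  names(avg) <- c("sen", "spe", "pre", "acc", "f1", "mcc")
  list(mean = structure(avg, class = "metric_set"), folds = fold_metrics)
}

#' Evaluate a trained model on an independent test set
#'
#' When the model records its training ids, test ids are checked for
#' train/test leakage before any prediction is made.
#'
#' @param model A `"ubp_model"` from [train_classifier()].
#' @param test_fm A labeled [feature_matrix()] disjoint from training.
#' @param check_leakage Error on train/test id overlap (default TRUE); set
#'   FALSE only for deliberate resubstitution estimates.
#' @return A `"metric_set"` for the test set.
#' @export
independent_test <- function(model, test_fm, check_leakage = TRUE) {
  stopifnot(inherits(test_fm, "feature_matrix"))
  if (nrow(test_fm$values) == 0) stop("empty test set")
  if (is.null(test_fm$labels)) stop("test set has no labels")
  if (check_leakage && !is.null(model$train_ids)) {
    overlap <- intersect(model$train_ids, test_fm$ids)
    if (length(overlap) > 0) {
      stop("train_test_leakage: ", length(overlap),
           " id(s) appear in both sets, e.g. ", overlap[1])
    }
  }
  pred <- predict_classifier(model, test_fm)
  compute_metrics(confusion_counts(test_fm$labels, pred$call))
}
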
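#' Gradient-boosting hyperparameter configuration
#'
#' The eight tuned parameters of the tree-booster model, each restricted to
#' its search threshold: `learning_rate` in \[0, 0.5\], `n_estimators` in
#' \[100, 2000\] (integer), `max_depth` in \[1, 10\] (integer), `subsample`
#' and `colsample_bytree` in (0, 1\], `gamma` in \[0, 1\], `reg_alpha` in
#' \[0, 1\], `reg_lambda` in \[0, 2\]. The booster is always the tree
#' booster.
#'
#' @param learning_rate Step-size shrinkage.
#' @param n_estimators Number of trees.
#' @param max_depth Maximum tree depth.
#' @param subsample Fraction of samples used per tree.
#' @param colsample_bytree Fraction of features used per tree.
#' @param gamma Minimum loss reduction to split a node.
#' @param reg_alpha L1 regularization on leaf weights.
#' @param reg_lambda L2 regularization on leaf weights.
#' @return An object of class `"hyperparams"`.
#' @export
hyperparams <- function(learning_rate = 0.10, n_estimators = 100L,
                        max_depth = 3L, subsample = 1.0,
                        colsample_bytree = 1.0, gamma = 0,
                        reg_alpha = 0, reg_lambda = 1.0) {
  p <- structure(
    list(learning_rate = as.numeric(learning_rate),
         n_estimators = as.integer(round(n_estimators)),
         max_depth = as.integer(round(max_depth)),
         subsample = as.numeric(subsample),
         colsample_bytree = as.numeric(colsample_bytree),
         gamma = as.numeric(gamma),
         reg_alpha = as.numeric(reg_alpha),
         reg_lambda = as.numeric(reg_lambda)),
    class = "hyperparams"
  )
  validate_params(p)
  p
}

#' @export
print.hyperparams <- function(x, ...) {
  cat(sprintf(paste0("Booster config: eta %.3g, %d trees, depth %d, ",
                     "subsample %.2f, colsample %.2f,\n",
                     "  gamma %.2f, alpha %.2f, lambda %.2f\n"),
              x$learning_rate, x$n_estimators, x$max_depth, x$subsample,
              x$colsample_bytree, x$gamma, x$reg_alpha, x$reg_lambda))
  invisible(x)
}

#' Default hyperparameters
#'
#' The untuned configuration: learning_rate 0.10, n_estimators 100,
#' max_depth 3, subsample 1.0, colsample_bytree 1.0, gamma 0, reg_alpha 0,
#' reg_lambda 1.0.
#'
#' @return A `"hyperparams"` object.
#' @export
default_params <- function() hyperparams()

#' Validate a hyperparameter configuration against its search box
#'
#' @param p A `"hyperparams"` object.
#' @return `TRUE` invisibly; errors on any out-of-box value.
#' @export
validate_params <- function(p) {
  box <- param_box()
  for (nm in rownames(box)) {
    v <- p[[nm]]
    if (is.null(v) || !is.finite(v)) stop("missing hyperparameter: ", nm)
    if (v < box[nm, "lower"] || v > box[nm, "upper"]) {
      stop("hyperparameter out of range: ", nm, " = ", v, " not in [",
           box[nm, "lower"], ", ", box[nm, "upper"], "]")
    }
  }
  if (p$subsample <= 0 || p$colsample_bytree <= 0) {
    stop("subsample and colsample_bytree must be > 0")
  }
  invisible(TRUE)
}

#' The 8-dimensional hyperparameter search box
#'
#' Search thresholds for tuning: learning_rate \[0, 0.5\], n_estimators
#' \[100, 2000\], max_depth \[1, 10\], subsample and colsample_bytree
#' (0, 1\] (lower bound 0.05 here since a zero sampling fraction is
#' meaningless), gamma \[0, 1\], reg_alpha \[0, 1\], reg_lambda \[0, 2\].
#'
#' @return 8 x 2 numeric matrix with rownames = parameter names and columns
#'   `lower`, `upper`.
#' @export
param_box <- function() {
  m <- rbind(
    learning_rate = c(0, 0.5),
    n_estimators = c(100, 2000),
    max_depth = c(1, 10),
    subsample = c(0.05, 1),
    colsample_bytree = c(0.05, 1),
    gamma = c(0, 1),
    reg_alpha = c(0, 1),
    reg_lambda = c(0, 2)
  )
  colnames(m) <- c("lower", "upper")
  m
}

#' Train the gradient-boosted UBP classifier
#'
#' Fits a binary logistic tree-booster ensemble on a labeled feature matrix.
#' Training is deterministic for a fixed seed and thread count; feature
#' names and training ids are recorded so that prediction can realign
#' columns and [independent_test()] can detect leakage.
#'
#' @param fm A labeled [feature_matrix()] with both classes present.
#' @param params A [hyperparams()] configuration (default [default_params()]).
#' @param seed Integer seed.
#' @param nthread Number of training threads (default 1 for bit-for-bit
#'   reproducibility across machines).
#' @return An object of class `"ubp_model"`.
#' @export
train_classifier <- function(fm, params = default_params(), seed = 1,
                             nthread = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("training requires labels")
  if (length(unique(fm$labels)) < 2) stop("both classes must be present")
  if (any(!is.finite(fm$values))) stop("feature matrix contains NaN")
  validate_params(params)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(fm$values, label = fm$labels,
                                 nthread = nthread)
  booster <- xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      eta = params$learning_rate,
      max_depth = params$max_depth,
      subsample = params$subsample,
      colsample_bytree = params$colsample_bytree,
      gamma = params$gamma,
      alpha = params$reg_alpha,
      lambda = params$reg_lambda,
      nthread = nthread,
      seed = as.integer(seed)
    ),
    data = dtrain,
    nrounds = params$n_estimators,
    verbose = 0
  )
  structure(
    list(booster = booster, params = params,
         feature_names = colnames(fm$values), train_ids = fm$ids,
         seed = as.integer(seed), n = nrow(fm$values), d = ncol(fm$values)),
    class = "ubp_model"
  )
}

#' @export
print.ubp_model <- function(x, ...) {
  cat("UBP classifier: ", x$params$n_estimators, " trees, depth ",
      x$params$max_depth, ", trained on ", x$n, " x ", x$d, "\n", sep = "")
  invisible(x)
}

#' Predict with a trained UBP classifier
#'
#' Input columns are realigned to the training feature names; missing or
#' extra columns are an error. Calls are made at probability threshold 0.5.
#'
#' @param model A `"ubp_model"`.
#' @param newdata A [feature_matrix()] or numeric matrix with feature
#'   colnames.
#' @param threshold Probability cutoff for calling class 1 (default 0.5).
#' @return data.frame with columns `id`, `probability`, `call`.
#' @export
predict_classifier <- function(model, newdata, threshold = 0.5) {
  stopifnot(inherits(model, "ubp_model"))
  if (inherits(newdata, "feature_matrix")) {
    ids <- newdata$ids
    values <- newdata$values
  } else {
    stopifnot(is.matrix(newdata))
    values <- newdata
    ids <- rownames(values)
    if (is.null(ids)) ids <- paste0("row", seq_len(nrow(values)))
  }
  missing <- setdiff(model$feature_names, colnames(values))
  extra <- setdiff(colnames(values), model$feature_names)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("feature mismatch; missing: [",
         paste(utils::head(missing, 3), collapse = ", "),
         "], extra: [", paste(utils::head(extra, 3), collapse = ", "), "]")
  }
  values <- values[, model$feature_names, drop = FALSE]
  prob <- stats::predict(model$booster, values)
  data.frame(id = ids, probability = as.numeric(prob),
             call = as.integer(prob >= threshold),
             stringsAsFactors = FALSE)
}

#' @export
predict.ubp_model <- function(object, newdata, ...) {
  predict_classifier(object, newdata, ...)
}

#' Save / load a trained model as JSON
#'
#' The booster is embedded in its JSON dump together with the
#' hyperparameters and training metadata, so the file is portable text and
#' `save_model()` followed by [load_model()] reproduces predictions
#' bit-for-bit.
#'
#' @param model A `"ubp_model"`.
#' @param path Output path (`.json`).
#' @return `path` invisibly (`save_model`); the restored `"ubp_model"`
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ubp_model"))
  payload <- list(
    format = "ubppred-model-v1",
    params = unclass(model$params),
    feature_names = model$feature_names,
    train_ids = model$train_ids,
    seed = model$seed, n = model$n, d = model$d,
    booster_json = rawToChar(xgboost::xgb.save.raw(model$booster,
                                                   raw_format = "json"))
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$format, "ubppred-model-v1")) {
    stop("not a ubppred model file: ", path)
  }
  booster <- xgboost::xgb.load.raw(charToRaw(payload$booster_json))
  structure(
    list(booster = booster,
         params = do.call(hyperparams, as.list(payload$params)),
         feature_names = payload$feature_names,
         train_ids = payload$train_ids,
         seed = payload$seed, n = payload$n, d = payload$d),
    class = "ubp_model"
  )
}
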
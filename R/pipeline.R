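#' Default pipeline configuration
#'
#' Returns the full configuration of [run_pipeline()] with its documented
#' defaults: 5-fold cross-validation, MOPSO with a swarm of 80 for 200
#' iterations selecting by MCC, length filter at 50 residues, log-odds PSSM
#' block, 15% of samples held out for the independent test. Any subset of
#' fields can be overridden through `...` or a JSON config file.
#'
#' @param ... Named overrides of default fields.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  config <- list(
    fasta = NULL, pssm_dir = NULL, labels = NULL, out_dir = NULL,
    seed = 1L,
    min_len = 50,
    pssm_block = "log_odds",
    test_fraction = 0.15,
    folds = 5,            # CV folds for reported metrics
    ifs_folds = 5,        # CV folds inside the IFS evaluator
    ifs_max_size = Inf,   # largest ranked prefix evaluated
    ifs_step = 1,
    n_trees = 500,        # RF forest size for importance ranking
    tune = TRUE,
    swarm = 80, iters = 200,
    tune_folds = 5,       # CV folds inside the tuning evaluator
    objectives = c("sen", "spe"),
    nthread = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  config[names(overrides)] <- overrides
  config
}

# per-stage seeds derived from the root seed, kept under 2^31
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 97 + k * 1009) %% 2147483647)
}

#' Run the full prediction workflow end-to-end
#'
#' featurize -> rank -> incremental feature selection -> (optionally) tune
#' -> train -> evaluate, writing every stage artifact plus a provenance
#' manifest to `out_dir`. Stages:
#'
#' 1. Read sequences, apply the length/alphabet filters, read labels and
#'    per-protein ASCII PSSMs, and build the 820-dim feature matrix.
#' 2. Split off a stratified independent test set (`test_fraction`).
#' 3. Rank features by RF Gini importance on the training split, drop
#'    zero-importance features, and select the CV-MCC-maximizing prefix by
#'    IFS.
#' 4. Tune the eight booster hyperparameters by MOPSO (or keep defaults
#'    when `tune = FALSE`).
#' 5. Train the final model on the training split, report its
#'    cross-validation metrics and its independent-test metrics.
#'
#' All randomness derives from `config$seed` through fixed per-stage
#' offsets, so reruns of the same configuration are identical.
#'
#' @param config A list from [pipeline_config()], or a path to a JSON file
#'   of overrides.
#' @return List with `model`, `params`, `ranking`, `ifs`, `cv_metrics`,
#'   `test_metrics`, `config` and `paths` (artifact locations).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- do.call(pipeline_config,
                      jsonlite::fromJSON(config, simplifyVector = TRUE))
  }
  for (req in c("fasta", "pssm_dir", "labels", "out_dir")) {
    if (is.null(config[[req]])) stop("pipeline config is missing '", req, "'")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- inputs & featurization ------------------------------------------------
  fm <- stage("featurize", {
    seqs <- read_fasta(config$fasta)
    filt <- apply_dataset_filters(seqs, min_len = config$min_len)
    if (nrow(filt$rejected) > 0) {
      message(nrow(filt$rejected), " sequence(s) rejected by dataset filters")
    }
    labels <- read_labels(config$labels)
    keep <- intersect(names(filt$kept), names(labels))
    if (length(keep) == 0) stop("no labeled sequence passed the filters")
    block <- if (config$pssm_block == "log_odds") "log_odds" else "percent_frequency"
    pssms <- lapply(keep, function(id) {
      read_pssm(file.path(config$pssm_dir, paste0(id, ".pssm")),
                protein_id = id, block = block)
    })
    names(pssms) <- keep
    featurize_dataset(filt$kept[keep], pssms = pssms, labels = labels[keep])
  })
  write_feature_matrix(fm, file.path(out, "features.tsv"))

  # -- train/test split ------------------------------------------------------
  split <- stage("split", {
    set.seed(stage_seed(config$seed, 1))
    test_idx <- unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(fm$labels == cl)
      sample(idx, max(1L, round(length(idx) * config$test_fraction)))
    }))
    list(train = subset_rows(fm, setdiff(seq_along(fm$ids), test_idx)),
         test = subset_rows(fm, test_idx))
  })

  # -- feature selection -----------------------------------------------------
  ranking <- stage("rank", {
    r <- rank_features(split$train, seed = stage_seed(config$seed, 2),
                       n_trees = config$n_trees)
    drop_zero_importance(r)
  })
  utils::write.table(as.data.frame(ranking),
                     file.path(out, "ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ifs <- stage("ifs", {
    incremental_feature_selection(
      split$train, ranking,
      max_size = config$ifs_max_size, step = config$ifs_step,
      folds = config$ifs_folds, seed = stage_seed(config$seed, 3),
      nthread = config$nthread
    )
  })
  utils::write.table(ifs$trace, file.path(out, "ifs_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(ifs$best_subset, file.path(out, "best_features.txt"))
  train_sub <- subset_features(split$train, ifs$best_subset)
  test_sub <- subset_features(split$test, ifs$best_subset)

  # -- hyperparameter tuning -------------------------------------------------
  params <- if (isTRUE(config$tune)) {
    stage("tune", {
      ev <- make_cv_evaluator(train_sub, folds = config$tune_folds,
                              seed = stage_seed(config$seed, 4),
                              nthread = config$nthread)
      tuned <- mopso_tune(ev, swarm_size = config$swarm,
                          max_iter = config$iters,
                          seed = stage_seed(config$seed, 5),
                          objectives = config$objectives)
      tuned$best
    })
  } else {
    default_params()
  }
  writeLines(jsonlite::toJSON(unclass(params), auto_unbox = TRUE,
                              digits = NA),
             file.path(out, "params.json"))

  # -- final model & evaluation ----------------------------------------------
  model <- stage("train", {
    train_classifier(train_sub, params = params,
                     seed = stage_seed(config$seed, 6),
                     nthread = config$nthread)
  })
  save_model(model, file.path(out, "model.json"))
  cv <- stage("evaluate", {
    kfold_cv(train_sub, k = config$folds, seed = stage_seed(config$seed, 7),
             params = params, nthread = config$nthread)
  })
  test_metrics <- stage("independent_test", independent_test(model, test_sub))
  metrics_df <- rbind(
    cbind(split = "cross_validation", as.data.frame(cv$mean)),
    cbind(split = "independent_test", as.data.frame(test_metrics))
  )
  utils::write.table(metrics_df, file.path(out, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pred <- predict_classifier(model, test_sub)
  utils::write.table(pred, file.path(out, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- config
  manifest$objectives <- as.list(config$objectives)
  manifest$package_version <- as.character(utils::packageVersion("ubppred"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null",
                              digits = NA),
             file.path(out, "config.json"))

  list(model = model, params = params, ranking = ranking, ifs = ifs,
       cv_metrics = cv$mean, test_metrics = test_metrics, config = config,
       paths = list(
         out_dir = out,
         features = file.path(out, "features.tsv"),
         ranking = file.path(out, "ranking.tsv"),
         ifs_trace = file.path(out, "ifs_trace.tsv"),
         best_features = file.path(out, "best_features.txt"),
         params = file.path(out, "params.json"),
         model = file.path(out, "model.json"),
         metrics = file.path(out, "metrics.tsv"),
         predictions = file.path(out, "predictions.tsv"),
         config = file.path(out, "config.json")
       ))
}
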
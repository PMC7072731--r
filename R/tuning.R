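#' Pareto dominance between objective vectors
#'
#' With all objectives maximized, `a` dominates `b` iff `a >= b` in every
#' component and `a > b` in at least one.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("objective vectors of different arity")
  all(a >= b) && any(a > b)
}

#' Insert a candidate into a non-dominated archive
#'
#' The candidate is inserted iff no member dominates it; members it
#' dominates are evicted. When the archive would exceed `capacity`, the
#' member with the smallest crowding distance (the most crowded) is pruned,
#' keeping the archive spread over the Pareto front.
#'
#' @param archive List of entries, each a list with `position`, `objectives`
#'   (and optionally `metrics`).
#' @param candidate An entry of the same shape.
#' @param capacity Maximum archive size (default 100).
#' @return The updated archive (a list).
#' @export
archive_insert <- function(archive, candidate, capacity = 100) {
  for (m in archive) {
    if (dominates(m$objectives, candidate$objectives)) return(archive)
  }
  keep <- vapply(archive, function(m) {
    !dominates(candidate$objectives, m$objectives)
  }, logical(1))
  archive <- c(archive[keep], list(candidate))
  while (length(archive) > capacity) {
    cd <- crowding_distance(archive_objectives(archive))
    archive <- archive[-which.min(cd)]
  }
  archive
}

archive_objectives <- function(archive) {
  do.call(rbind, lapply(archive, `[[`, "objectives"))
}

# Crowding distance of each row of an objectives matrix; boundary points get
# Inf so pruning removes interior, crowded points first.
crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- rep(0, n)
  for (j in seq_len(ncol(obj))) {
    ord <- order(obj[, j])
    rng <- obj[ord[n], j] - obj[ord[1], j]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] +
        (obj[ord[3:n], j] - obj[ord[1:(n - 2)], j]) / rng
    }
  }
  d
}

# Map a continuous position in the search box to a hyperparams object;
# integer-valued parameters are rounded here only.
position_to_params <- function(x) {
  box <- param_box()
  names(x) <- rownames(box)
  hyperparams(
    learning_rate = x[["learning_rate"]],
    n_estimators = round(x[["n_estimators"]]),
    max_depth = round(x[["max_depth"]]),
    subsample = x[["subsample"]],
    colsample_bytree = x[["colsample_bytree"]],
    gamma = x[["gamma"]],
    reg_alpha = x[["reg_alpha"]],
    reg_lambda = x[["reg_lambda"]]
  )
}

#' Multi-objective particle swarm hyperparameter tuning
#'
#' Standard PSO velocity/position dynamics over the 8-dimensional
#' hyperparameter box (constriction coefficients w = 0.729,
#' c1 = c2 = 1.494), extended to multiple objectives with a Pareto archive:
#' each particle's social leader is drawn from the archive by a binary
#' crowding-distance tournament (preferring sparse regions of the front),
#' personal bests are replaced when dominated (coin-flip on incomparable
#' outcomes), and positions are clipped to the box with the velocity zeroed
#' on clipped components. Particles move in continuous space; integer
#' parameters are rounded at evaluation time only.
#'
#' The final configuration returned as `best` is the archive member with
#' the highest MCC — the most reliable single selection metric for a
#' balanced binary problem — falling back to the summed objectives when the
#' evaluator does not report MCC (e.g. analytic surrogates).
#'
#' @param evaluator Function `(hyperparams) -> "metric_set"` (or any named
#'   list of objective values), typically cross-validation of the
#'   classifier on a feature matrix; see [make_cv_evaluator()].
#' @param swarm_size Number of particles (default 80).
#' @param max_iter Iterations after initialization (default 200); the only
#'   stopping criterion.
#' @param seed Integer seed; the run is fully reproducible.
#' @param objectives Names of the maximized objectives (default sensitivity
#'   and specificity, spanning both error types of the confusion matrix).
#' @param capacity Archive capacity (default 100).
#' @param w,c1,c2 PSO inertia and acceleration coefficients.
#' @return List with `best` (a [hyperparams()]), `best_metrics`, `archive`
#'   (list of non-dominated entries), and `history` (data.frame with
#'   per-iteration archive size and best value of each objective).
#' @export
mopso_tune <- function(evaluator, swarm_size = 80, max_iter = 200, seed = 1,
                       objectives = c("sen", "spe"), capacity = 100,
                       w = 0.729, c1 = 1.494, c2 = 1.494) {
  stopifnot(is.function(evaluator), swarm_size >= 1, max_iter >= 1)
  box <- param_box()
  lower <- box[, "lower"]; upper <- box[, "upper"]
  d <- nrow(box)
  set.seed(seed)

  get_obj <- function(metrics) {
    v <- vapply(objectives, function(nm) {
      x <- metrics[[nm]]
      if (is.null(x) || !is.finite(x)) stop("evaluator did not return objective '", nm, "'")
      as.numeric(x)
    }, numeric(1))
    v
  }
  # evaluators may seed their own RNG (CV fold assignment); shield the
  # swarm's random stream from them
  evaluate <- function(x) {
    p <- position_to_params(x)
    rng <- .GlobalEnv$.Random.seed
    metrics <- evaluator(p)
    assign(".Random.seed", rng, envir = .GlobalEnv)
    list(position = x, params = p, metrics = metrics,
         objectives = get_obj(metrics))
  }

  # initialization: uniform positions, small random velocities
  pos <- sapply(seq_len(d), function(j) stats::runif(swarm_size, lower[j], upper[j]))
  vel <- sapply(seq_len(d), function(j) {
    stats::runif(swarm_size, -0.1, 0.1) * (upper[j] - lower[j])
  })
  if (swarm_size == 1) { pos <- matrix(pos, 1); vel <- matrix(vel, 1) }
  archive <- list()
  pbest <- vector("list", swarm_size)
  for (i in seq_len(swarm_size)) {
    e <- evaluate(pos[i, ])
    pbest[[i]] <- e
    archive <- archive_insert(archive, e, capacity)
  }
  if (length(archive) == 0) stop("no evaluation succeeded during initialization")

  pick_leader <- function() {
    n <- length(archive)
    if (n == 1) return(archive[[1]])
    cd <- crowding_distance(archive_objectives(archive))
    i <- sample.int(n, 1); j <- sample.int(n, 1)
    archive[[if (cd[i] >= cd[j]) i else j]]
  }

  history <- vector("list", max_iter)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(swarm_size)) {
      leader <- pick_leader()
      r1 <- stats::runif(d); r2 <- stats::runif(d)
      vel[i, ] <- w * vel[i, ] +
        c1 * r1 * (pbest[[i]]$position - pos[i, ]) +
        c2 * r2 * (leader$position - pos[i, ])
      newpos <- pos[i, ] + vel[i, ]
      clipped <- newpos < lower | newpos > upper
      newpos <- pmin(pmax(newpos, lower), upper)
      vel[i, clipped] <- 0
      pos[i, ] <- newpos
      e <- evaluate(newpos)
      archive <- archive_insert(archive, e, capacity)
      if (dominates(e$objectives, pbest[[i]]$objectives)) {
        pbest[[i]] <- e
      } else if (!dominates(pbest[[i]]$objectives, e$objectives) &&
                 stats::runif(1) < 0.5) {
        pbest[[i]] <- e
      }
    }
    obj <- archive_objectives(archive)
    hrow <- c(iter = it, archive_size = length(archive),
              stats::setNames(apply(obj, 2, max),
                              paste0("best_", objectives)))
    history[[it]] <- hrow
  }

  select_metric <- function(e) {
    m <- e$metrics$mcc
    if (is.null(m) || !is.finite(m)) sum(e$objectives) else as.numeric(m)
  }
  scores <- vapply(archive, select_metric, numeric(1))
  best_e <- archive[[which.max(scores)]]
  list(best = best_e$params,
       best_metrics = best_e$metrics,
       archive = archive,
       history = as.data.frame(do.call(rbind, history)))
}

#' Cross-validation evaluator for hyperparameter tuning
#'
#' Wraps [kfold_cv()] into the `(hyperparams) -> "metric_set"` shape
#' consumed by [mopso_tune()]. The fold assignment is fixed by `seed`, so
#' every candidate configuration is scored on the same folds.
#'
#' @param fm A labeled [feature_matrix()].
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed.
#' @param nthread Training threads (default 1).
#' @return A function mapping a [hyperparams()] to a `"metric_set"`.
#' @export
make_cv_evaluator <- function(fm, folds = 5, seed = 1, nthread = 1) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  function(params) {
    kfold_cv(fm, k = folds, seed = seed, params = params,
             nthread = nthread)$mean
  }
}
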
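#' Amino acid composition (AAC)
#'
#' The 20-vector of residue frequencies: component i is the count of residue
#' AA_i divided by the sequence length L, so the block sums to 1. Residues
#' are ordered alphabetically (A, C, D, ..., Y) and names are prefixed
#' `"AAC:"`.
#'
#' @param sequence Protein sequence over the 20 standard residues, L >= 1.
#' @return Named numeric vector of length 20.
#' @export
compute_aac <- function(sequence) {
  check_featurizable(sequence, min_len = 1)
  res <- strsplit(sequence, "")[[1]]
  counts <- table(factor(res, levels = aa_alphabet()))
  out <- as.numeric(counts) / length(res)
  names(out) <- paste0("AAC:", aa_alphabet())
  out
}

#' Dipeptide composition (DC)
#'
#' The 400-vector of adjacent residue-pair frequencies: component (i, j) is
#' the count of the pair AA_i AA_j divided by L - 1, so the block sums to 1.
#' Pairs are ordered row-major over the alphabetical residue order (AA, AC,
#' ..., AY, CA, ...) and names are prefixed `"DC:"`.
#'
#' @param sequence Protein sequence over the 20 standard residues, L >= 2.
#' @return Named numeric vector of length 400.
#' @export
compute_dc <- function(sequence) {
  check_featurizable(sequence, min_len = 1)
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  if (L < 2) stop("sequence_too_short_for_dc: need L >= 2, got ", L)
  aa <- aa_alphabet()
  i <- match(res[-L], aa)
  j <- match(res[-1], aa)
  idx <- (i - 1L) * 20L + j
  counts <- tabulate(idx, nbins = 400L)
  out <- counts / (L - 1)
  names(out) <- paste0("DC:", rep(aa, each = 20), rep(aa, times = 20))
  out
}

#' PSSM composition
#'
#' Collapses an L x 20 evolutionary profile to a 400-vector: component
#' (t, c) is the sum of the column-c profile scores over the positions
#' occupied by residue t,
#' \deqn{f_{t,c} = \sum_{p : R_p = t} S_{p,c}.}
#' Raw sums are reported by default (no length normalization); see
#' `normalize`. Rows are addressed by the sequence, columns through the
#' PSSM's recorded `column_order`, and the output is ordered row-major over
#' the alphabetical residue order with names `"PSSM:t|c"`.
#'
#' @param sequence Protein sequence; its length must equal the PSSM row
#'   count and its residues must match the PSSM's row residues.
#' @param pssm A `"pssm"` object from [read_pssm()] or [generate_pssm()].
#' @param normalize `"none"` (default), `"by_length"` (divide by L), or
#'   `"by_residue_count"` (divide each residue-t row by the count of t in
#'   the sequence; rows for absent residues stay 0).
#' @return Named numeric vector of length 400.
#' @export
compute_pssm_composition <- function(sequence, pssm,
                                     normalize = c("none", "by_length",
                                                   "by_residue_count")) {
  normalize <- match.arg(normalize)
  check_featurizable(sequence, min_len = 1)
  stopifnot(inherits(pssm, "pssm"))
  check_pssm_matches_sequence(pssm, sequence)
  aa <- aa_alphabet()
  res <- factor(strsplit(sequence, "")[[1]], levels = aa)
  # sum profile rows grouped by the residue occupying each position
  sums <- rowsum(pssm$scores, group = res)            # present residues only
  comp <- matrix(0, nrow = 20, ncol = 20, dimnames = list(aa, aa))
  comp[rownames(sums), ] <- sums[, aa, drop = FALSE]  # reorder columns
  if (normalize == "by_length") {
    comp <- comp / nchar(sequence)
  } else if (normalize == "by_residue_count") {
    n_t <- table(res)
    nz <- n_t > 0
    comp[nz, ] <- comp[nz, , drop = FALSE] / as.numeric(n_t[nz])
  }
  out <- as.numeric(t(comp))  # row-major: residue t outer, column c inner
  names(out) <- paste0("PSSM:", rep(aa, each = 20), "|", rep(aa, times = 20))
  out
}

#' Encode one protein as a feature vector
#'
#' Concatenates, in order, the 20 AAC, 400 DC and 400 PSSM-composition
#' features into the 820-dimensional encoding; with `include_pssm = FALSE`
#' (or no PSSM supplied) only the 420 composition features are returned.
#'
#' @inheritParams compute_pssm_composition
#' @param include_pssm Include the PSSM block? Defaults to TRUE when `pssm`
#'   is supplied. Requesting it without a PSSM is an error.
#' @return Named numeric vector of length 820 (or 420).
#' @export
featurize <- function(sequence, pssm = NULL, include_pssm = !is.null(pssm),
                      normalize = "none") {
  if (include_pssm && is.null(pssm)) {
    stop("PSSM block requested but no PSSM supplied")
  }
  v <- c(compute_aac(sequence), compute_dc(sequence))
  if (include_pssm) {
    v <- c(v, compute_pssm_composition(sequence, pssm, normalize = normalize))
  }
  v
}

check_featurizable <- function(sequence, min_len = 1) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) < min_len) {
    stop("sequence shorter than ", min_len, " residues")
  }
  if (!is_standard_sequence(sequence)) {
    stop("sequence contains non-standard residues; run apply_dataset_filters() first")
  }
  invisible(TRUE)
}

#' Construct a labeled feature matrix
#'
#' @param values Numeric n x d matrix with feature names as colnames; no NaN
#'   or NA entries.
#' @param ids Row identifiers (default: rownames of `values`).
#' @param labels Optional named or aligned 0/1 vector.
#' @return An object of class `"feature_matrix"`: list with `ids`, `values`
#'   (rownames = ids), and `labels` (or NULL).
#' @export
feature_matrix <- function(values, ids = rownames(values), labels = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(colnames(values))) stop("feature matrix needs column names")
  if (is.null(ids)) stop("feature matrix needs row ids")
  if (anyDuplicated(ids)) stop("duplicate ids in feature matrix")
  if (any(!is.finite(values))) stop("feature matrix contains NaN/NA/Inf")
  rownames(values) <- ids
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      missing <- setdiff(ids, names(labels))
      if (length(missing) > 0) {
        stop("labels missing for ", length(missing), " id(s), e.g. ",
             missing[1])
      }
      labels <- labels[ids]
    } else if (length(labels) != length(ids)) {
      stop("unnamed labels must align with ids")
    }
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
    names(labels) <- ids
  }
  structure(list(ids = as.character(ids), values = values, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: ", nrow(x$values), " proteins x ", ncol(x$values),
      " features", if (!is.null(x$labels)) {
        sprintf(" (%d positive / %d negative)",
                sum(x$labels == 1), sum(x$labels == 0))
      }, "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Row/column subsetting that keeps ids and labels aligned.
subset_features <- function(fm, features) {
  missing <- setdiff(features, colnames(fm$values))
  if (length(missing) > 0) {
    stop("unknown feature(s): ", paste(utils::head(missing, 3), collapse = ", "))
  }
  feature_matrix(fm$values[, features, drop = FALSE],
                 ids = fm$ids, labels = fm$labels)
}

subset_rows <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE],
                 ids = fm$ids[idx],
                 labels = if (is.null(fm$labels)) NULL else fm$labels[idx])
}

#' Encode a dataset of proteins as a feature matrix
#'
#' @param seqs Named character vector of sequences (already filtered).
#' @param pssms Optional named list of `"pssm"` objects covering every id in
#'   `seqs`; when NULL the PSSM block is omitted (420-dim encoding).
#' @param labels Optional named 0/1 vector.
#' @param normalize PSSM-block normalization, see
#'   [compute_pssm_composition()].
#' @return A [feature_matrix()].
#' @export
featurize_dataset <- function(seqs, pssms = NULL, labels = NULL,
                              normalize = "none") {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  include_pssm <- !is.null(pssms)
  if (include_pssm) {
    missing <- setdiff(names(seqs), names(pssms))
    if (length(missing) > 0) {
      stop("no PSSM for ", length(missing), " protein(s), e.g. ", missing[1])
    }
  }
  rows <- lapply(names(seqs), function(id) {
    featurize(seqs[[id]], pssm = if (include_pssm) pssms[[id]] else NULL,
              include_pssm = include_pssm, normalize = normalize)
  })
  values <- do.call(rbind, rows)
  rownames(values) <- names(seqs)
  feature_matrix(values, ids = names(seqs), labels = labels)
}
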
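# Shared fixtures and independent oracles used across test files.

tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_sequence <- function(L) {
  paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
}

# A random pssm object without going through the generator module.
random_pssm <- function(sequence, id = "p") {
  cols <- psiblast_column_order()
  L <- nchar(sequence)
  scores <- matrix(sample(-10:10, L * 20, replace = TRUE), nrow = L,
                   dimnames = list(NULL, cols))
  structure(
    list(protein_id = id, scores = scores,
         residues = strsplit(sequence, "")[[1]],
         column_order = cols, source_kind = "log_odds"),
    class = "pssm"
  )
}

# Brute-force PSSM-composition: explicit double loop over positions and
# profile columns, grouping by the residue at each position.
brute_pssm_composition <- function(sequence, pssm) {
  aa <- aa_alphabet()
  res <- strsplit(sequence, "")[[1]]
  out <- stats::setNames(
    numeric(400),
    paste0("PSSM:", rep(aa, each = 20), "|", rep(aa, times = 20))
  )
  for (p in seq_along(res)) {
    for (cc in aa) {
      key <- paste0("PSSM:", res[p], "|", cc)
      out[key] <- out[key] + pssm$scores[p, which(pssm$column_order == cc)]
    }
  }
  out
}

# Brute-force metrics from raw (label, call) pairs, written independently
# of compute_metrics.
brute_metrics <- function(truth, calls) {
  tp <- sum(truth == 1 & calls == 1); fp <- sum(truth == 0 & calls == 1)
  tn <- sum(truth == 0 & calls == 0); fn <- sum(truth == 1 & calls == 0)
  div <- function(a, b) if (b == 0) 0 else a / b
  sen <- div(tp, tp + fn); spe <- div(tn, tn + fp); pre <- div(tp, tp + fp)
  rad <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  list(sen = sen, spe = spe, pre = pre,
       acc = (tp + tn) / length(truth),
       f1 = div(2 * sen * pre, sen + pre),
       mcc = if (rad == 0) 0 else (tp * tn - fp * fn) / sqrt(rad))
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# universe whose first M elements are annotated.
enumerate_hypergeom_tail <- function(N, M, n, m) {
  if (m == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= M) >= m)
}

# Small numeric dataset with one planted informative feature (feature
# "signal"); the label is a deterministic function of it up to noise.
planted_feature_matrix <- function(n = 200, d = 10, seed = 1,
                                   noise_sd = 0.25) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  values <- matrix(stats::rnorm(n * d), nrow = n)
  colnames(values) <- c("signal", paste0("noise", seq_len(d - 1)))
  values[, "signal"] <- (2 * labels - 1) + stats::rnorm(n, sd = noise_sd)
  feature_matrix(values, ids = sprintf("s%03d", seq_len(n)), labels = labels)
}

# Perfectly separable dataset for training sanity checks.
separable_feature_matrix <- function(n = 200, d = 10, seed = 1) {
  planted_feature_matrix(n = n, d = d, seed = seed, noise_sd = 0)
}
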
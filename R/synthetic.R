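#' Configuration for the synthetic benchmark generator
#'
#' Defines a reproducible two-class protein dataset with a planted,
#' composition-space class signal. Positive-class sequences are drawn from a
#' mixture: at each position, with probability `effect_size` the residue
#' comes from the biased component, otherwise from the uniform background —
#' so `effect_size = 0` is an exact null and `effect_size = 1` is maximal
#' signal. The signal kinds target the three feature blocks directly:
#'
#' * `aac_bias` — biased component is uniform over `bias_residues`
#'   (shifts single-residue composition);
#' * `dc_bias` — first-order Markov chain in which the transition from
#'   `bias_residues[1]` emits the last element of `bias_residues` with
#'   probability `effect_size` (shifts one dipeptide frequency);
#' * `pssm_bias` — sequences are uniform in both classes, but
#'   positive-class profiles have their `bias_residues` columns up-shifted
#'   (signal only visible through the PSSM-composition block);
#' * `none` — exact null, classes identically distributed.
#'
#' @param seed Integer seed; identical configurations generate identical
#'   datasets.
#' @param n_pos,n_neg Class sizes (default 100 each, balanced).
#' @param length_range Min/max sequence length, min >= 50 (default 50-150,
#'   typical of small complete protein chains).
#' @param signal_kind One of `"aac_bias"`, `"dc_bias"`, `"pssm_bias"`,
#'   `"none"`.
#' @param effect_size Mixture weight of the biased component, in \[0, 1\].
#' @param bias_residues Residues carrying the planted signal (default "A").
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1, n_pos = 100, n_neg = 100,
                             length_range = c(50, 150),
                             signal_kind = c("aac_bias", "dc_bias",
                                             "pssm_bias", "none"),
                             effect_size = 0.8, bias_residues = "A") {
  signal_kind <- match.arg(signal_kind)
  stopifnot(length(length_range) == 2, length_range[1] >= 50,
            length_range[1] <= length_range[2],
            effect_size >= 0, effect_size <= 1,
            all(bias_residues %in% aa_alphabet()))
  structure(
    list(seed = as.integer(seed), n_pos = as.integer(n_pos),
         n_neg = as.integer(n_neg),
         length_range = as.integer(length_range),
         signal_kind = signal_kind, effect_size = effect_size,
         bias_residues = bias_residues),
    class = "synthetic_config"
  )
}

draw_sequence <- function(L, config, positive) {
  aa <- aa_alphabet()
  kind <- if (positive) config$signal_kind else "none"
  if (kind == "aac_bias" && config$effect_size > 0) {
    biased <- stats::runif(L) < config$effect_size
    res <- character(L)
    res[biased] <- sample(config$bias_residues, sum(biased), replace = TRUE)
    res[!biased] <- sample(aa, sum(!biased), replace = TRUE)
  } else if (kind == "dc_bias" && config$effect_size > 0) {
    from <- config$bias_residues[1]
    to <- config$bias_residues[length(config$bias_residues)]
    res <- character(L)
    res[1] <- sample(aa, 1)
    for (p in 2:L) {
      res[p] <- if (res[p - 1] == from && stats::runif(1) < config$effect_size) {
        to
      } else {
        sample(aa, 1)
      }
    }
  } else {
    res <- sample(aa, L, replace = TRUE)
  }
  paste(res, collapse = "")
}

#' Generate random protein sequences with an optional planted signal
#'
#' @param config A [synthetic_config()].
#' @return Named character vector of `n_pos + n_neg` sequences; ids are
#'   `pos001..` / `neg001..` (positives first).
#' @export
generate_proteins <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_pos + config$n_neg
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 n, replace = TRUE)
  positive <- c(rep(TRUE, config$n_pos), rep(FALSE, config$n_neg))
  ids <- c(sprintf("pos%03d", seq_len(config$n_pos)),
           sprintf("neg%03d", seq_len(config$n_neg)))
  seqs <- vapply(seq_len(n), function(i) {
    draw_sequence(lens[i], config, positive[i])
  }, character(1))
  stats::setNames(seqs, ids)
}

#' Generate a synthetic evolutionary profile for one protein
#'
#' Produces an L x 20 integer log-odds-like matrix in PSI-BLAST column
#' order: small uniform noise in \[-3, 3\] plus a +4 shift on the column of
#' the residue actually present at each position (conservation of the
#' observed residue). Under `pssm_bias` with `positive = TRUE`, the
#' `bias_residues` columns are additionally up-shifted by
#' `round(6 * effect_size)` at every position. A matching percentage block
#' (100 on the observed residue) is attached for ASCII serialization.
#'
#' Uses the current RNG stream; seed at the dataset level (see
#' [generate_labeled_dataset()]).
#'
#' @param sequence Protein sequence.
#' @param config A [synthetic_config()].
#' @param protein_id Identifier for the profile.
#' @param positive Is this a positive-class protein?
#' @return A `"pssm"` object (log-odds) with a `percents` attribute.
#' @export
generate_pssm <- function(sequence, config, protein_id = "protein",
                          positive = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- nchar(sequence)
  cols <- psiblast_column_order()
  res <- strsplit(sequence, "")[[1]]
  scores <- matrix(sample(-3:3, L * 20, replace = TRUE), nrow = L,
                   dimnames = list(NULL, cols))
  col_idx <- match(res, cols)
  scores[cbind(seq_len(L), col_idx)] <- scores[cbind(seq_len(L), col_idx)] + 4L
  if (positive && config$signal_kind == "pssm_bias") {
    shift <- as.integer(round(6 * config$effect_size))
    scores[, config$bias_residues] <- scores[, config$bias_residues] + shift
  }
  percents <- matrix(0L, nrow = L, ncol = 20, dimnames = list(NULL, cols))
  percents[cbind(seq_len(L), col_idx)] <- 100L
  p <- structure(
    list(protein_id = protein_id, scores = scores, residues = res,
         column_order = cols, source_kind = "log_odds"),
    class = "pssm"
  )
  attr(p, "percents") <- percents
  p
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Serializes a profile in the `-out_ascii_pssm` layout parsed by
#' [read_pssm()]: title line, 40-column residue header, one row per
#' position with index, residue, 20 integer log-odds, 20 integer
#' percentages, and the two trailing per-position statistics.
#'
#' @param pssm A `"pssm"` object (integer log-odds). The percentage block
#'   is taken from the `percents` attribute if present, else zeros.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  scores <- pssm$scores
  percents <- attr(pssm, "percents")
  if (is.null(percents)) {
    percents <- matrix(0L, nrow = nrow(scores), ncol = 20)
  }
  cols <- pssm$column_order
  lines <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("           ", paste(sprintf("%3s", c(cols, cols)), collapse = " "))
  )
  for (i in seq_len(nrow(scores))) {
    lines <- c(lines, paste0(
      sprintf("%5d %s ", i, pssm$residues[i]),
      paste(sprintf("%3d", as.integer(round(scores[i, ]))), collapse = " "),
      "  ",
      paste(sprintf("%3d", as.integer(round(percents[i, ]))), collapse = " "),
      sprintf("  %4.2f %4.2f", 0.5, 0.25)
    ))
  }
  lines <- c(lines, "", "                      K         Lambda",
             "Standard Ungapped    0.1337     0.3176")
  writeLines(lines, path)
  invisible(path)
}

#' Generate a labeled synthetic feature dataset end-to-end
#'
#' Runs the full chain — sequences, per-protein profiles, featurization —
#' and returns the stacked labeled feature matrix (820 columns). Balanced
#' classes by default; positives are labeled 1.
#'
#' @param config A [synthetic_config()].
#' @return A labeled [feature_matrix()] with attributes `proteins` (named
#'   character vector) and `pssms` (named list of `"pssm"` objects).
#' @export
generate_labeled_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  proteins <- generate_proteins(config)  # seeds the stream
  positive <- grepl("^pos", names(proteins))
  pssms <- lapply(seq_along(proteins), function(i) {
    generate_pssm(proteins[[i]], config, protein_id = names(proteins)[i],
                  positive = positive[i])
  })
  names(pssms) <- names(proteins)
  labels <- stats::setNames(as.integer(positive), names(proteins))
  fm <- featurize_dataset(proteins, pssms = pssms, labels = labels)
  attr(fm, "proteins") <- proteins
  attr(fm, "pssms") <- pssms
  fm
}

#' Generate an annotation universe with one planted enriched term
#'
#' Builds `n_terms` random term memberships over `n_genes` genes plus one
#' planted term (`"T_planted"`) constructed to overlap the returned query
#' set in `planted_term_overlap` genes — by construction the most enriched
#' term.
#'
#' @param seed Integer seed.
#' @param n_genes Background universe size (default 200).
#' @param n_terms Number of random (null) terms (default 30).
#' @param planted_term_overlap Query genes placed in the planted term
#'   (default 15).
#' @param query_size Query set size (default 20).
#' @param term_size_range Min/max random term size (default 8-30).
#' @return List with `annotations` (an [annotation_set()] whose background
#'   is all `n_genes` genes), `query` (character vector), and
#'   `planted_term` (`"T_planted"`).
#' @export
generate_annotation_universe <- function(seed = 1, n_genes = 200,
                                         n_terms = 30,
                                         planted_term_overlap = 15,
                                         query_size = 20,
                                         term_size_range = c(8, 30)) {
  stopifnot(planted_term_overlap <= query_size, query_size <= n_genes)
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  query <- sample(genes, query_size)
  size_lo <- min(term_size_range[1], n_genes)
  size_hi <- min(term_size_range[2], n_genes)
  terms <- lapply(seq_len(n_terms), function(i) {
    sample(genes, sample(seq(size_lo, size_hi), 1))
  })
  names(terms) <- sprintf("T%03d", seq_len(n_terms))
  planted <- c(sample(query, planted_term_overlap),
               sample(setdiff(genes, query),
                      min(5, length(setdiff(genes, query)))))
  terms[["T_planted"]] <- planted
  list(annotations = annotation_set(terms, background = genes),
       query = query, planted_term = "T_planted")
}

#' Write an annotation set as a GMT-like file
#'
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  lines <- vapply(names(annotations$term_to_genes), function(term) {
    paste(c(term, "synthetic term",
            annotations$term_to_genes[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic toy project to disk
#'
#' Emits every artifact the pipeline and CLI consume: `proteins.fasta`,
#' `pssm/<id>.pssm` (ASCII profiles), `labels.tsv`, `terms.gmt` +
#' `background.txt` (annotation universe over the protein ids, query =
#' positive proteins), and `sites.tsv` (one random interior binding site
#' per positive protein). All files are plain text and round-trip through
#' the package readers.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of paths, plus the generated `feature_matrix`
#'   (element `matrix`), invisibly.
#' @export
simulate_project <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  fm <- generate_labeled_dataset(config)
  proteins <- attr(fm, "proteins")
  pssms <- attr(fm, "pssms")
  paths <- list(
    fasta = file.path(dir, "proteins.fasta"),
    pssm_dir = file.path(dir, "pssm"),
    labels = file.path(dir, "labels.tsv"),
    gmt = file.path(dir, "terms.gmt"),
    background = file.path(dir, "background.txt"),
    sites = file.path(dir, "sites.tsv")
  )
  write_fasta(proteins, paths$fasta)
  for (id in names(pssms)) {
    write_pssm_ascii(pssms[[id]], file.path(paths$pssm_dir,
                                            paste0(id, ".pssm")))
  }
  write_labels(fm$labels, paths$labels)
  pos_ids <- names(proteins)[grepl("^pos", names(proteins))]
  uni <- generate_annotation_universe(
    seed = config$seed + 1L, n_genes = length(proteins), n_terms = 20,
    planted_term_overlap = min(15L, length(pos_ids)),
    query_size = min(20L, length(pos_ids))
  )
  # relabel the universe's abstract genes with the project's protein ids,
  # mapping the query genes onto positive proteins so the planted term is
  # enriched in the positive class
  abstract <- sprintf("g%04d", seq_along(proteins))
  gene_map <- character(length(abstract))
  names(gene_map) <- c(uni$query, setdiff(abstract, uni$query))
  gene_map[uni$query] <- pos_ids[seq_along(uni$query)]
  gene_map[setdiff(abstract, uni$query)] <-
    setdiff(names(proteins), pos_ids[seq_along(uni$query)])
  terms <- lapply(uni$annotations$term_to_genes,
                  function(g) unname(gene_map[g]))
  write_gmt(annotation_set(terms, background = unname(gene_map)), paths$gmt)
  writeLines(unname(gene_map), paths$background)
  sites <- data.frame(
    protein_id = pos_ids,
    position = vapply(pos_ids, function(id) {
      L <- nchar(proteins[[id]])
      sample(seq(11, L - 10), 1)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  utils::write.table(sites, paths$sites, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$matrix <- fm
  invisible(paths)
}
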
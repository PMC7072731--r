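#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and returned in file order as a named character
#' vector (names are the record identifiers, taken as the first
#' whitespace-delimited token of each header). No composition or length
#' filtering is applied here; see [apply_dataset_filters()].
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @seealso [write_fasta()], [apply_dataset_filters()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("FASTA parse error: empty identifier in header of record ",
         which(!nzchar(ids))[1])
  }
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA parse error: empty sequence for record '",
         ids[which(empty)[1]], "'")
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    stop("duplicate sequence identifier(s): ",
         paste(unique(ids[dup]), collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Filter a protein dataset by length and alphabet
#'
#' Mirrors the benchmark-construction rule for UBP datasets: proteins with
#' fewer than `min_len` residues tend to be peptides rather than complete
#' proteins, and sequences containing non-standard letters (B, J, O, U, X, Z,
#' gaps, ...) would confuse composition features. Exactly `min_len` residues
#' is kept. Nothing is silently altered: every rejected record carries a
#' machine-readable reason.
#'
#' @param seqs Named character vector of sequences (from [read_fasta()]).
#' @param min_len Minimum sequence length retained (default 50).
#' @return List with `kept` (named character vector) and `rejected`
#'   (data.frame with columns `id`, `reason`; reasons are `"too_short"` and
#'   `"nonstandard_residue"`).
#' @export
apply_dataset_filters <- function(seqs, min_len = 50) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  nonstd <- !is_standard_sequence(seqs)
  short <- !nonstd & nchar(seqs) < min_len
  reason <- rep(NA_character_, length(seqs))
  reason[nonstd] <- "nonstandard_residue"
  reason[short] <- "too_short"
  keep <- is.na(reason)
  list(
    kept = seqs[keep],
    rejected = data.frame(
      id = names(seqs)[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect of PSI-BLAST (BLAST+): a title line,
#' a header row naming 20 residue columns twice, then one row per sequence
#' position carrying the position index, the query residue, 20 log-odds
#' scores and 20 weighted observed percentages. Profiles are produced
#' externally, e.g.
#' `psiblast -query seq.fasta -db swissprot -num_iterations 3 -evalue 0.01
#' -out_ascii_pssm out.pssm`.
#'
#' By default the log-odds block (columns 1-20) is returned; with
#' `block = "percent_frequency"` the percentage block (columns 21-40) is
#' returned divided by 100. The column order is taken verbatim from the file
#' header and recorded in the result; it is not re-sorted.
#'
#' @param path Path to an ASCII PSSM file.
#' @param protein_id Identifier to attach; defaults to the file base name.
#' @param block Which score block to read: `"log_odds"` (default) or
#'   `"percent_frequency"`.
#' @return An object of class `"pssm"`: list with `protein_id`, `scores`
#'   (L x 20 numeric matrix, colnames = `column_order`), `residues`
#'   (character vector of the query sequence, length L), `column_order`,
#'   and `source_kind`.
#' @export
read_pssm <- function(path, protein_id = NULL,
                      block = c("log_odds", "percent_frequency")) {
  block <- match.arg(block)
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(protein_id)) {
    protein_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  # header row: 40 single-letter residue tokens (20 log-odds + 20 percents)
  is_header <- vapply(toks, function(t) {
    length(t) == 40 && all(t %in% aa_alphabet())
  }, logical(1))
  if (!any(is_header)) {
    stop("PSSM parse error in '", path,
         "': missing column header line (40 residue labels)")
  }
  h <- which(is_header)[1]
  column_order <- toks[[h]][1:20]
  if (!setequal(column_order, aa_alphabet())) {
    stop("PSSM parse error: header columns are not the 20 standard residues")
  }
  scores <- list()
  residues <- character(0)
  for (i in seq(h + 1, length(toks))) {
    t <- toks[[i]]
    if (length(t) == 0) break                       # blank line ends the table
    if (is.na(suppressWarnings(as.integer(t[1])))) break  # Lambda/K footer
    # position, residue, 20 log-odds, 20 percents, information, rel. weight
    if (length(t) < 42) {
      stop("PSSM parse error at row ", i - h,
           ": expected >= 42 fields, got ", length(t))
    }
    vals <- suppressWarnings(as.numeric(
      if (block == "log_odds") t[3:22] else t[23:42]
    ))
    if (anyNA(vals)) {
      stop("PSSM parse error at row ", i - h, ": non-numeric score cell")
    }
    residues <- c(residues, t[2])
    scores[[length(scores) + 1L]] <- vals
  }
  if (length(scores) == 0) {
    stop("PSSM parse error in '", path, "': no score rows found")
  }
  m <- do.call(rbind, scores)
  if (block == "percent_frequency") m <- m / 100
  colnames(m) <- column_order
  structure(
    list(
      protein_id = protein_id,
      scores = m,
      residues = residues,
      column_order = column_order,
      source_kind = if (block == "log_odds") "log_odds" else "percent_frequency"
    ),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM for '", x$protein_id, "': ", nrow(x$scores), " positions x 20 (",
      x$source_kind, ")\n", sep = "")
  invisible(x)
}

# Error unless the PSSM's row residues equal the FASTA sequence.
check_pssm_matches_sequence <- function(pssm, sequence) {
  L <- nchar(sequence)
  if (nrow(pssm$scores) != L) {
    stop("PSSM/sequence mismatch for '", pssm$protein_id, "': ",
         nrow(pssm$scores), " PSSM rows vs ", L, " residues")
  }
  seq_res <- strsplit(sequence, "")[[1]]
  if (!all(pssm$residues == seq_res)) {
    bad <- which(pssm$residues != seq_res)[1]
    stop("PSSM/sequence mismatch for '", pssm$protein_id,
         "' at position ", bad, ": PSSM has '", pssm$residues[bad],
         "', sequence has '", seq_res[bad], "'")
  }
  invisible(TRUE)
}

#' Read binary labels from a TSV file
#'
#' Expects two tab-separated columns `id<TAB>label` with label in \{0, 1\};
#' an optional header line `id<TAB>label` is skipped.
#'
#' @param path Path to the label file.
#' @return Named integer vector of 0/1 labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) != 2) stop("label file must have exactly two columns")
  if (identical(tolower(df[1, 1]), "id")) df <- df[-1, , drop = FALSE]
  lab <- suppressWarnings(as.integer(df[[2]]))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L))) {
    stop("labels must be 0 or 1")
  }
  if (anyDuplicated(df[[1]])) stop("duplicate ids in label file")
  stats::setNames(lab, df[[1]])
}

#' Write binary labels to a TSV file
#' @param labels Named 0/1 vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(id = names(labels), label = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a term-to-gene annotation file (GMT-like)
#'
#' Each line is `term<TAB>description<TAB>gene1<TAB>gene2...`. The annotation
#' universe `N` used by the hypergeometric test is the background set: by
#' default the union of all gene sets, or an explicit background that must
#' contain that union.
#'
#' @param path Path to the GMT-like file.
#' @param background Optional character vector (or path to a one-id-per-line
#'   file) giving the background universe explicitly.
#' @return An object of class `"annotation_set"`: list with `term_to_genes`
#'   (named list of character vectors) and `background` (character vector).
#' @export
read_annotations <- function(path, background = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("annotation file '", path, "' is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) {
    stop("annotation parse error: line ", which(bad)[1],
         " has no gene entries")
  }
  terms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(terms)) {
    stop("duplicate term id(s): ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  genes <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(genes) <- terms
  if (is.character(background) && length(background) == 1 &&
      file.exists(background)) {
    background <- readLines(background, warn = FALSE)
    background <- trimws(background[nzchar(trimws(background))])
  }
  annotation_set(genes, background)
}

#' Construct an annotation set
#'
#' @param term_to_genes Named list mapping term ids to character vectors of
#'   gene/protein ids; no term may be empty.
#' @param background Optional background universe; defaults to the union of
#'   all gene sets and must contain it otherwise.
#' @return An `"annotation_set"` object.
#' @export
annotation_set <- function(term_to_genes, background = NULL) {
  stopifnot(is.list(term_to_genes), !is.null(names(term_to_genes)))
  if (any(vapply(term_to_genes, length, integer(1)) == 0)) {
    stop("empty term in annotation set")
  }
  universe <- unique(unlist(term_to_genes, use.names = FALSE))
  if (is.null(background)) {
    background <- universe
  } else {
    background <- unique(background)
    missing <- setdiff(universe, background)
    if (length(missing) > 0) {
      stop("background_incomplete: ", length(missing),
           " annotated gene(s) absent from the supplied background")
    }
  }
  structure(list(term_to_genes = term_to_genes, background = background),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set: ", length(x$term_to_genes), " terms over a background of ",
      length(x$background), " genes\n", sep = "")
  invisible(x)
}

#' Read a binding-site table
#'
#' Two tab-separated columns: protein id and 1-based residue position
#' (header `protein_id<TAB>position` optional). Position validity against the
#' sequences is checked by [extract_windows()].
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `protein_id` (character) and `position`
#'   (integer).
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("binding-site file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) != 2) stop("binding-site file must have exactly two columns")
  if (identical(tolower(df[1, 1]), "protein_id")) df <- df[-1, , drop = FALSE]
  pos <- suppressWarnings(as.integer(df[[2]]))
  if (anyNA(pos) || any(pos < 1)) {
    stop("binding-site positions must be positive integers")
  }
  data.frame(protein_id = df[[1]], position = pos, stringsAsFactors = FALSE)
}

#' Write a feature matrix to TSV
#'
#' The first column is `id`, followed (when labels are present) by `label`,
#' then one column per feature with the feature names as header.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(id = fm$ids, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(fm$labels)) df$label <- as.integer(fm$labels)
  vals <- as.data.frame(fm$values, check.names = FALSE)
  utils::write.table(cbind(df, vals), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' @param path Path written by [write_feature_matrix()].
#' @return A [feature_matrix()] (with labels if a `label` column is present).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("feature matrix file lacks an 'id' column")
  ids <- as.character(df$id)
  labels <- NULL
  drop <- "id"
  if ("label" %in% names(df)) {
    labels <- stats::setNames(as.integer(df$label), ids)
    drop <- c(drop, "label")
  }
  vals <- as.matrix(df[, setdiff(names(df), drop), drop = FALSE])
  rownames(vals) <- ids
  feature_matrix(vals, ids = ids, labels = labels)
}
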
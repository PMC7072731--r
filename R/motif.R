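#' Extract binding-site windows for motif discovery
#'
#' Slices, for each annotated binding site, the fragment of `width` residues
#' centered on the site (default 21, i.e. 10 residues each side). Sites
#' within half a window of a terminus yield clipped fragments flagged
#' `full_width = FALSE`; callers decide whether to keep them. All
#' coordinates are 1-based inclusive.
#'
#' @param seqs Named character vector of protein sequences.
#' @param sites data.frame with columns `protein_id`, `position` (from
#'   [read_sites()]).
#' @param width Odd window width (default 21).
#' @return data.frame with columns `protein_id`, `site_position`, `start`,
#'   `end`, `fragment`, `full_width`.
#' @export
extract_windows <- function(seqs, sites, width = 21) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            is.data.frame(sites),
            all(c("protein_id", "position") %in% names(sites)))
  if (width %% 2 != 1 || width < 1) stop("width must be a positive odd integer")
  unknown <- !(sites$protein_id %in% names(seqs))
  lens <- nchar(seqs)[sites$protein_id]
  out_of_range <- !unknown & (sites$position < 1 | sites$position > lens)
  if (any(unknown) || any(out_of_range)) {
    bad <- which(unknown | out_of_range)
    stop("invalid binding-site row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": unknown protein id or position outside the sequence")
  }
  half <- (width - 1) %/% 2
  start <- pmax(1L, sites$position - half)
  end <- pmin(as.integer(lens), sites$position + half)
  data.frame(
    protein_id = sites$protein_id,
    site_position = sites$position,
    start = start,
    end = end,
    fragment = substr(seqs[sites$protein_id], start, end),
    full_width = (end - start + 1L) == width,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write binding-site windows as motif-discovery input
#'
#' Emits the fragments as FASTA with headers `proteinid|site=P`, ready for a
#' motif finder such as MEME (e.g.
#' `meme windows.fasta -protein -nmotifs 10 -evt 0.05`). Fragments shorter
#' than `min_width` are excluded (too short to seed a motif) and counted in
#' a message.
#'
#' @param windows data.frame from [extract_windows()].
#' @param path Output FASTA path.
#' @param min_width Minimum fragment length written (default 8).
#' @return Number of records written, invisibly.
#' @export
write_meme_input <- function(windows, path, min_width = 8) {
  stopifnot(is.data.frame(windows),
            all(c("protein_id", "site_position", "fragment") %in%
                  names(windows)))
  keep <- nchar(windows$fragment) >= min_width
  if (any(!keep)) {
    message(sum(!keep), " fragment(s) shorter than ", min_width,
            " residues were excluded")
  }
  kept <- windows[keep, , drop = FALSE]
  seqs <- stats::setNames(
    kept$fragment,
    paste0(kept$protein_id, "|site=", kept$site_position)
  )
  if (length(seqs) > 0) {
    write_fasta(seqs, path)
  } else {
    writeLines(character(0), path)
  }
  invisible(sum(keep))
}
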
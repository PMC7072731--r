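#' Amino-acid alphabets
#'
#' `aa_alphabet()` returns the 20 standard amino acids in alphabetical
#' single-letter order (A, C, D, ..., Y), the canonical order used for all
#' feature names in this package. `psiblast_column_order()` returns the
#' column order used by PSI-BLAST ASCII PSSM files
#' (A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T, W, Y, V).
#'
#' Downstream code never assumes the two orders agree: PSSM columns are
#' always addressed through the matrix's recorded `column_order`.
#'
#' @return Character vector of 20 single-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
psiblast_column_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# TRUE for sequences over the 20 standard residues only
is_standard_sequence <- function(x) {
  !grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), x)
}
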
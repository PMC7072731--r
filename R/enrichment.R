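#' Hypergeometric upper-tail probability of an annotation overlap
#'
#' The probability of observing an overlap of at least `m` between a query
#' of size `n` and a term annotating `M` of the `N` background genes, under
#' sampling without replacement:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \binom{M}{i}\binom{N-M}{n-i} \big/
#'   \binom{N}{n}.}
#' Computed through the hypergeometric distribution function (log-space
#' internally), so it is stable for genome-scale inputs.
#'
#' @param N Background universe size.
#' @param M Number of background genes annotated with the term.
#' @param n Query size (annotated query genes).
#' @param m Observed overlap.
#' @return P-value in \[0, 1\].
#' @export
hypergeom_tail <- function(N, M, n, m) {
  stopifnot(length(N) == 1, length(M) == 1, length(n) == 1, length(m) == 1)
  N <- as.integer(N); M <- as.integer(M); n <- as.integer(n); m <- as.integer(m)
  if (anyNA(c(N, M, n, m)) || any(c(N, M, n, m) < 0)) {
    stop("arguments must be non-negative integers")
  }
  if (M > N || n > N) stop("M and n must not exceed N")
  if (m > min(M, n)) stop("overlap m cannot exceed min(M, n)")
  if (m == 0) return(1)
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Term over-representation analysis of a gene set
#'
#' Tests each annotation term for enrichment in the query via the
#' hypergeometric upper tail ([hypergeom_tail()]). Query genes outside the
#' background are dropped (with a message). Terms with no query overlap are
#' omitted. Significance is called at the raw P-value cutoff (no
#' multiple-testing correction, matching the usual raw-0.05 convention for
#' this analysis); set `bh = TRUE` to call significance on
#' Benjamini-Hochberg adjusted values instead.
#'
#' @param query Character vector of query gene/protein ids.
#' @param annotations An [annotation_set()].
#' @param cutoff Significance cutoff (default 0.05).
#' @param bh Apply Benjamini-Hochberg correction before flagging?
#' @return data.frame of class `"enrichment_result"`, sorted by ascending
#'   `p_value`, with columns `term`, `N`, `M`, `n`, `m`, `p_value`
#'   (`p_adjusted` when `bh`), `significant`.
#' @export
enrich <- function(query, annotations, cutoff = 0.05, bh = FALSE) {
  stopifnot(inherits(annotations, "annotation_set"))
  query <- unique(query)
  eff <- intersect(query, annotations$background)
  n_dropped <- length(query) - length(eff)
  if (n_dropped > 0) {
    message(n_dropped, " query gene(s) outside the background were dropped")
  }
  if (length(eff) == 0) stop("no query gene is in the annotation background")
  N <- length(annotations$background)
  n <- length(eff)
  rows <- lapply(names(annotations$term_to_genes), function(term) {
    genes <- annotations$term_to_genes[[term]]
    m <- length(intersect(eff, genes))
    if (m == 0) return(NULL)
    data.frame(term = term, N = N, M = length(genes), n = n, m = m,
               p_value = hypergeom_tail(N, length(genes), n, m),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(term = character(0), N = integer(0), M = integer(0),
                      n = integer(0), m = integer(0), p_value = numeric(0),
                      significant = logical(0))
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (bh) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < cutoff
  } else {
    out$significant <- out$p_value < cutoff
  }
  class(out) <- c("enrichment_result", "data.frame")
  out
}
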
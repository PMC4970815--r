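# Karlin-Altschul statistics and final ranking.

#' Karlin-Altschul search space
#'
#' @param m Query segment length in residues.
#' @param n Total database residues.  Chunked searches must pass the
#'   whole database's residue count, not the chunk's, so that E-values
#'   and ranks are invariant under chunking.
#' @param lambda,K Gapped Karlin-Altschul parameters (defaults are the
#'   published values for BLOSUM62 with gap penalties 11/1).
#' @export
search_space <- function(m, n, lambda = 0.267, K = 0.041) {
  stopifnot(m >= 1, n >= 1, lambda > 0, K > 0)
  list(m = m, n = n, lambda = lambda, K = K)
}

#' E-value and bit score of a raw score
#'
#' `E = K * m * n * exp(-lambda * S)`; bit score
#' `S' = (lambda * S - ln K) / ln 2`.  No effective-length correction
#' is applied (a documented divergence from NCBI BLAST).
#'
#' @param S Non-negative raw score (vectorized).
#' @param space A [search_space()].
#' @return list with `evalue` and `bitscore` vectors.
#' @export
evalue <- function(S, space) {
  stopifnot(all(S >= 0))
  list(evalue = space$K * space$m * space$n * exp(-space$lambda * S),
       bitscore = (space$lambda * S - log(space$K)) / log(2))
}

#' Threshold, rank and truncate hits per query read
#'
#' Per query read (across all its segments, frames and database
#' chunks): keeps hits with `E <= e_cut`, sorts by bit score
#' descending, then E-value ascending, then subject id ascending (with
#' coordinate tie-breaks for full determinism), and truncates to
#' `max_targets` rows.
#'
#' @param hits Hit data.frame with at least `qseqid`, `sseqid`,
#'   `bitscore`, `evalue`.
#' @param e_cut E-value threshold (default 10).
#' @param max_targets Maximum reported rows per query (default 100).
#' @export
rank_and_threshold <- function(hits, e_cut = 10, max_targets = 100L) {
  stopifnot(e_cut > 0, max_targets >= 1L)
  hits <- hits[hits$evalue <= e_cut, , drop = FALSE]
  if (!nrow(hits)) {
    return(hits)
  }
  parts <- split(hits, hits$qseqid)
  parts <- lapply(parts, function(h) {
    o <- order(-h$bitscore, h$evalue, h$sseqid, h$qstart, h$sstart,
               h$frame)
    utils::head(h[o, , drop = FALSE], max_targets)
  })
  out <- rbind_all(parts[order(names(parts))])
  rownames(out) <- NULL
  out
}
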
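# Chain filtering: thin redundant ungapped segments before gapped
# extension.  Two drop rules, applied greedily in score order:
#   1. among segments on the same database sequence whose diagonals lie
#      within +/- band of a surviving segment, only the highest-scoring
#      survives (ties: smallest qstart, then smallest dstart);
#   2. a segment whose query interval is fully contained in a surviving
#      higher-scoring segment's query interval on the same database
#      sequence is dropped.

#' Chain filter for ungapped segments
#'
#' @param segments data.frame of [ungapped_extend()] segments from one
#'   (query segment, chunk) pair.
#' @param store The chunk's `clx_store` (to resolve database sequence
#'   ids).
#' @param band Diagonal band half-width (default 16).
#' @return The surviving segments, sorted by score descending (ties:
#'   qstart, then dstart ascending).
#' @export
chain_filter <- function(segments, store, band = 16L) {
  if (nrow(segments) <= 1L) {
    return(segments)
  }
  sseq <- sequence_of(store, segments$dstart)
  o <- order(-segments$score, segments$qstart, segments$dstart)
  segments <- segments[o, , drop = FALSE]
  sseq <- sseq[o]
  n <- nrow(segments)
  keep <- logical(n)
  kept <- integer(0)
  for (i in seq_len(n)) {
    drop <- FALSE
    for (k in kept) {
      if (sseq[k] != sseq[i]) next
      if (abs(segments$diagonal[k] - segments$diagonal[i]) <= band ||
          (segments$qstart[i] >= segments$qstart[k] &&
           segments$qend[i] <= segments$qend[k])) {
        drop <- TRUE
        break
      }
    }
    if (!drop) {
      keep[i] <- TRUE
      kept <- c(kept, i)
    }
  }
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
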
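# X-dropoff ungapped extension of seeds.

#' Walk one direction of an ungapped extension
#'
#' Reference (scalar R) form of the X-dropoff walk: residue pairs are
#' scored in the given direction, the running maximum is tracked, and
#' the walk stops when the running score falls more than
#' `x_drop_ungapped` below the maximum or when either side runs out
#' (query boundary or database delimiter).  Returns the prefix achieving
#' the maximum, shortest prefix on ties.
#'
#' @param qcodes,dcodes Integer code vectors (query segment, database
#'   store slice / full store).
#' @param qpos,dpos 0-based positions of the first pair to score.
#' @param direction `"right"` or `"left"` (step of +1 or -1).
#' @param sp A [scoring_params()] object.
#' @return list with `offset` (number of pairs kept) and `delta`
#'   (score of the kept prefix).
#' @export
extend_one_direction <- function(qcodes, dcodes, qpos, dpos, direction, sp) {
  step <- if (identical(direction, "right")) 1L else -1L
  run <- 0L
  best <- 0L
  off <- 0L
  i <- 0L
  repeat {
    qi <- qpos + step * i
    di <- dpos + step * i
    if (qi < 0L || qi >= length(qcodes)) break
    if (di < 0L || di >= length(dcodes)) break
    if (dcodes[di + 1L] == CODE_DELIM || qcodes[qi + 1L] == CODE_DELIM) break
    run <- run + sp$matrix[qcodes[qi + 1L] + 1L, dcodes[di + 1L] + 1L]
    if (run > best) {
      best <- run
      off <- i + 1L
    }
    if (run < best - sp$x_drop_ungapped) break
    i <- i + 1L
  }
  list(offset = off, delta = best)
}

#' Ungapped X-dropoff extension of seeds
#'
#' Scores the L aligned seed columns, extends left and right with the
#' X-dropoff rule, and keeps segments whose total raw score reaches
#' `min_ungapped_score`.
#'
#' @param codes Integer codes of the query segment.
#' @param seeds Seed data.frame (or matrix with qpos/dpos in the first
#'   two columns) from [search_seeds()].
#' @param chunk A `clx_chunk`.
#' @param sp A [scoring_params()] object.
#' @return data.frame of surviving segments: `qstart`, `qend`,
#'   `dstart`, `dend` (0-based half-open), `score`, `diagonal`.
#' @export
ungapped_extend <- function(codes, seeds, chunk, sp) {
  if (is.data.frame(seeds)) {
    seeds <- cbind(seeds$qpos, seeds$dpos)
  }
  m <- cpp_ungapped_extend(as.integer(codes), chunk$store$codes,
                           matrix(as.integer(seeds), ncol = 2L),
                           chunk$params$L, sp$matrix,
                           sp$x_drop_ungapped, sp$min_ungapped_score)
  out <- data.frame(qstart = m[, 1], qend = m[, 2], dstart = m[, 3],
                    dend = m[, 4], score = m[, 5])
  out$diagonal <- out$dstart - out$qstart
  unique(out)
}
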
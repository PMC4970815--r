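# Seed search and triangle-inequality similarity filtering.

#' Triangle-inequality similarity filter
#'
#' Given the full distance `D_qr` between a query window and a cluster
#' representative, the lower bound on the distance between the query and
#' a member at stored distance `d_rm` is `LB = |D_qr - d_rm|`
#' (two-sided triangle inequality).  A member passes when `LB <= T_f`;
#' the representative itself passes when `D_qr <= T_f`.  No member whose
#' true distance is within `T_f` is ever rejected.
#'
#' @param D_qr Non-negative integer distance query-representative.
#' @param d_rm Integer vector of stored member-representative distances.
#' @param T_f Filter threshold.
#' @return A list with `lb` (integer vector) and `pass` (logical).
#' @export
similarity_filter <- function(D_qr, d_rm, T_f) {
  stopifnot(D_qr >= 0L, all(d_rm >= 0L))
  lb <- abs(D_qr - d_rm)
  list(lb = lb, pass = lb <= T_f)
}

#' Seed search of one query segment against a chunk
#'
#' For every query position with a keyable length-L window, looks up the
#' window's hash keys (radius `r_h`), computes full reduced-Hamming
#' distances to singleton entries (B_e) and cluster representatives
#' (B_r), and applies the triangle-inequality filter to cluster members
#' (B_m).  Hits are deduplicated on (query position, database position)
#' and ordered by query position then database position.
#'
#' @param codes Integer codes of the query segment.
#' @param chunk A `clx_chunk`.
#' @param T_f Filter threshold (default 2).
#' @param r_h Lookup neighborhood radius (default 1).
#' @return A data.frame with columns `qpos`, `dpos` (0-based),
#'   `provenance` (`"singleton"`, `"representative"`, `"member"`) and
#'   `lb`; attribute `n_dist_evals` counts full distance evaluations.
#' @export
search_seeds <- function(codes, chunk, T_f = 2L, r_h = 1L) {
  res <- search_seeds_batch(list(as.integer(codes)), chunk,
                            T_f = T_f, r_h = r_h)
  m <- res$seeds[[1]]
  out <- data.frame(qpos = m[, 1], dpos = m[, 2],
                    provenance = c("singleton", "representative",
                                   "member")[m[, 3] + 1L],
                    lb = m[, 4], stringsAsFactors = FALSE)
  attr(out, "n_dist_evals") <- res$n_dist_evals
  out
}

# batch interface used by the scheduler: list of code vectors in, list
# of seed matrices (qpos, dpos, prov, lb) out
search_seeds_batch <- function(codes_list, chunk, T_f = 2L, r_h = 1L) {
  tb <- chunk$tables
  p <- chunk$params
  qgroups <- lapply(codes_list, reduce_codes)
  res <- cpp_search_seeds(qgroups,
                          tb$be_keys, tb$be_off, tb$be_pos,
                          tb$br_keys, tb$br_off, tb$br_cid,
                          tb$bm_rep, tb$bm_off, tb$bm_member, tb$bm_dist,
                          reduce_codes(chunk$store$codes),
                          p$L, p$k_h, as.integer(T_f), as.integer(r_h))
  list(seeds = res, n_dist_evals = attr(res, "n_dist_evals"))
}
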
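# X-dropoff gapped extension (score-only, one-column storage) and full
# traceback for reported hits.

# db-sequence bounds [start, end) (0-based, global) around position dpos
db_seq_bounds <- function(store, dpos) {
  i <- sequence_of(store, dpos)
  stopifnot(!is.na(i))
  c(store$offsets[i], store$offsets[i] + store$lengths[i])
}

#' Score-only X-dropoff gapped extension in one direction
#'
#' Runs the affine-gap extension DP outward from an anchor, pruning any
#' cell whose score falls more than `x_drop_gapped` below the best seen
#' so far.  The score pass keeps a single row of the DP matrix (plus the
#' column-wise gap state), never the full matrix.
#'
#' @param qcodes,dcodes Integer code vectors (query segment, database
#'   store).
#' @param qa,da 0-based anchor column (scored separately by the
#'   caller).
#' @param direction `"left"` or `"right"` of the anchor.
#' @param sp A [scoring_params()] object.
#' @param dbounds 0-based half-open database-sequence bounds limiting
#'   the extension (delimiters terminate it otherwise).
#' @return list with `delta` (best score gain), `qext`, `dext` (number
#'   of query/database residues consumed).
#' @export
gapped_extend_score <- function(qcodes, dcodes, qa, da, direction, sp,
                                dbounds = c(0L, length(dcodes))) {
  if (identical(direction, "right")) {
    A <- if (qa + 1L < length(qcodes)) qcodes[(qa + 2L):length(qcodes)] else integer(0)
    B <- if (da + 1L < dbounds[2]) dcodes[(da + 2L):dbounds[2]] else integer(0)
  } else {
    A <- if (qa > 0L) qcodes[qa:1L] else integer(0)
    B <- if (da > dbounds[1]) dcodes[da:(dbounds[1] + 1L)] else integer(0)
  }
  r <- cpp_xdrop_score(as.integer(A), as.integer(B), sp$matrix,
                       sp$gap_open, sp$gap_extend,
                       as.double(sp$x_drop_gapped))
  list(delta = r[1], qext = r[2], dext = r[3])
}

# anchor column: centre of the highest-scoring window of (up to) 11
# residues within the ungapped segment, leftmost on ties
anchor_column <- function(qcodes, dcodes, seg, sp) {
  len <- seg$qend - seg$qstart
  cols <- vapply(seq_len(len) - 1L, function(i) {
    sp$matrix[qcodes[seg$qstart + i + 1L] + 1L,
              dcodes[seg$dstart + i + 1L] + 1L]
  }, numeric(1))
  w <- min(11L, len)
  sums <- vapply(seq_len(len - w + 1L) - 1L,
                 function(s) sum(cols[(s + 1L):(s + w)]), numeric(1))
  ws <- which.max(sums) - 1L  # leftmost maximum
  a <- ws + (w - 1L) %/% 2L
  list(qa = seg$qstart + a, da = seg$dstart + a,
       score = as.integer(cols[a + 1L]))
}

#' Gapped X-dropoff extension of an ungapped segment (score only)
#'
#' Anchors at the central column of the segment's highest-scoring
#' 11-residue window (leftmost on ties), extends left and right with
#' [gapped_extend_score()], and splices coordinates.  The total score
#' is the anchor column score plus both direction deltas.
#'
#' @param codes Integer codes of the query segment.
#' @param seg One row of a chain-filtered segment data.frame.
#' @param chunk A `clx_chunk`.
#' @param sp A [scoring_params()] object.
#' @return list with `score`, `qstart`, `qend`, `dstart`, `dend`
#'   (0-based half-open) and the anchor (`qa`, `da`).
#' @export
gapped_extend <- function(codes, seg, chunk, sp) {
  dcodes <- chunk$store$codes
  anc <- anchor_column(codes, dcodes, seg, sp)
  db <- db_seq_bounds(chunk$store, anc$da)
  left <- gapped_extend_score(codes, dcodes, anc$qa, anc$da, "left", sp, db)
  right <- gapped_extend_score(codes, dcodes, anc$qa, anc$da, "right", sp, db)
  list(score = anc$score + left$delta + right$delta,
       qstart = anc$qa - left$qext, qend = anc$qa + 1L + right$qext,
       dstart = anc$da - left$dext, dend = anc$da + 1L + right$dext,
       qa = anc$qa, da = anc$da)
}

ops_to_alignment <- function(ops, qcodes, dcodes, qat, dat, step) {
  # ops: 0 = pair, 1 = gap in query (consumes db), 2 = gap in db
  qa <- character(length(ops))
  da <- character(length(ops))
  letters22 <- c(AA_LETTERS, "X", "|")
  qi <- qat
  di <- dat
  for (t in seq_along(ops)) {
    op <- ops[t]
    if (op == 0L) {
      qa[t] <- letters22[qcodes[qi + 1L] + 1L]
      da[t] <- letters22[dcodes[di + 1L] + 1L]
      qi <- qi + step
      di <- di + step
    } else if (op == 1L) {
      qa[t] <- "-"
      da[t] <- letters22[dcodes[di + 1L] + 1L]
      di <- di + step
    } else {
      qa[t] <- letters22[qcodes[qi + 1L] + 1L]
      da[t] <- "-"
      qi <- qi + step
    }
  }
  list(q = qa, d = da)
}

#' Traceback alignment for a gapped result
#'
#' Re-runs the identical pruned extension DP on each side with full
#' matrices, reconstructs the operation path, and verifies that the
#' score recomputed from the aligned strings (substitution sums plus
#' affine gap costs) equals the score-only result; a mismatch is an
#' internal consistency error, never silently patched.
#'
#' @param codes Integer codes of the query segment.
#' @param res A [gapped_extend()] result.
#' @param chunk A `clx_chunk`.
#' @param sp A [scoring_params()] object.
#' @return `res` extended with `qaln`, `daln`, `midline`, `identities`,
#'   `mismatches`, `gapopens`, `align_len`.
#' @export
traceback_align <- function(codes, res, chunk, sp) {
  dcodes <- chunk$store$codes
  db <- db_seq_bounds(chunk$store, res$da)
  side <- function(direction) {
    if (identical(direction, "right")) {
      A <- if (res$qa + 1L < length(codes)) codes[(res$qa + 2L):length(codes)] else integer(0)
      B <- if (res$da + 1L < db[2]) dcodes[(res$da + 2L):db[2]] else integer(0)
      ei <- res$qend - res$qa - 1L
      ej <- res$dend - res$da - 1L
    } else {
      A <- if (res$qa > 0L) codes[res$qa:1L] else integer(0)
      B <- if (res$da > db[1]) dcodes[res$da:(db[1] + 1L)] else integer(0)
      ei <- res$qa - res$qstart
      ej <- res$da - res$dstart
    }
    tb <- cpp_xdrop_traceback(as.integer(A), as.integer(B), sp$matrix,
                              sp$gap_open, sp$gap_extend,
                              as.double(sp$x_drop_gapped), ei, ej)
    tb
  }
  ltb <- side("left")
  rtb <- side("right")
  # left ops run outward from the anchor over reversed sequences;
  # reversing them gives left-to-right order starting at (qstart, dstart)
  la <- ops_to_alignment(rev(ltb$ops), codes, dcodes,
                         res$qstart, res$dstart, 1L)
  ra <- ops_to_alignment(rtb$ops, codes, dcodes, res$qa + 1L, res$da + 1L, 1L)
  letters22 <- c(AA_LETTERS, "X", "|")
  qaln <- c(la$q, letters22[codes[res$qa + 1L] + 1L], ra$q)
  daln <- c(la$d, letters22[dcodes[res$da + 1L] + 1L], ra$d)
  recomputed <- alignment_score(qaln, daln, sp)
  if (recomputed != res$score) {
    stop(sprintf("traceback_align(): recomputed score %d != reported score %d",
                 recomputed, res$score))
  }
  ident <- qaln == daln & qaln != "-"
  gap <- qaln == "-" | daln == "-"
  pos_score <- vapply(seq_along(qaln), function(t) {
    if (gap[t]) return(FALSE)
    sp$matrix[aa_encode(qaln[t]) + 1L, aa_encode(daln[t]) + 1L] > 0L
  }, logical(1))
  midline <- ifelse(ident, "|", ifelse(!gap & pos_score, "+", " "))
  c(res, list(qaln = paste(qaln, collapse = ""),
              daln = paste(daln, collapse = ""),
              midline = paste(midline, collapse = ""),
              identities = sum(ident),
              mismatches = sum(!ident & !gap),
              gapopens = count_gap_opens(qaln) + count_gap_opens(daln),
              align_len = length(qaln)))
}

count_gap_opens <- function(chars) {
  g <- chars == "-"
  sum(g & !c(FALSE, g[-length(g)]))
}

# recompute an alignment score from aligned columns: substitution sums
# plus affine gap costs (open + k * extend per gap run)
alignment_score <- function(qaln, daln, sp) {
  stopifnot(length(qaln) == length(daln))
  score <- 0L
  in_qgap <- FALSE
  in_dgap <- FALSE
  for (t in seq_along(qaln)) {
    if (qaln[t] == "-") {
      score <- score - sp$gap_extend - (if (in_qgap) 0L else sp$gap_open)
      in_qgap <- TRUE
      in_dgap <- FALSE
    } else if (daln[t] == "-") {
      score <- score - sp$gap_extend - (if (in_dgap) 0L else sp$gap_open)
      in_dgap <- TRUE
      in_qgap <- FALSE
    } else {
      score <- score + sp$matrix[aa_encode(qaln[t]) + 1L,
                                 aa_encode(daln[t]) + 1L]
      in_qgap <- FALSE
      in_dgap <- FALSE
    }
  }
  score
}
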
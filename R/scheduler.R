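# Two-phase batched scheduler over database chunks.
#
# Phase 1: seed search + similarity filtering + ungapped extension.
# Phase 2: chain filtering, then gapped extension of buffered tasks,
# dispatched sorted by query segment length (a load-balancing rule that
# must not — and by construction does not — change results).
# Parallelism is a contract, not a mechanism: tasks are partitioned
# round-robin over `workers` serial partitions and merged in canonical
# order, so results are identical for any worker count, batch budget,
# chunk count, or prefetch setting.

#' Phase 1: seeds and ungapped segments for a chunk
#'
#' @param segments Query segment data.frame from [translate_queries()].
#' @param chunk A `clx_chunk`.
#' @param sp A [scoring_params()] object.
#' @param T_f,r_h Seeding parameters.
#' @param workers Number of serial task partitions (results are
#'   independent of this).
#' @return list with `usegs` (ungapped segments data.frame with a
#'   `seg_id` column, canonical order) and `n_dist_evals`.
#' @export
run_phase1 <- function(segments, chunk, sp, T_f = 2L, r_h = 1L,
                       workers = 1L) {
  if (!nrow(segments)) {
    return(list(usegs = empty_usegs(), n_dist_evals = 0))
  }
  part <- split(seq_len(nrow(segments)),
                (seq_len(nrow(segments)) - 1L) %% workers)
  ndist <- 0
  res <- vector("list", nrow(segments))
  for (p in part) {
    sb <- search_seeds_batch(segments$codes[p], chunk, T_f = T_f, r_h = r_h)
    ndist <- ndist + sb$n_dist_evals
    for (k in seq_along(p)) {
      i <- p[k]
      seeds <- sb$seeds[[k]]
      if (!nrow(seeds)) next
      u <- ungapped_extend(segments$codes[[i]], seeds[, 1:2, drop = FALSE],
                           chunk, sp)
      if (nrow(u)) {
        u$seg_id <- segments$seg_id[i]
        res[[i]] <- u
      }
    }
  }
  usegs <- rbind_all(res)
  if (is.null(usegs)) {
    usegs <- empty_usegs()
  } else {
    usegs <- usegs[order(usegs$seg_id, usegs$qstart, usegs$dstart), ,
                   drop = FALSE]
    rownames(usegs) <- NULL
  }
  list(usegs = usegs, n_dist_evals = ndist)
}

empty_usegs <- function() {
  data.frame(qstart = integer(0), qend = integer(0), dstart = integer(0),
             dend = integer(0), score = integer(0), diagonal = integer(0),
             seg_id = integer(0))
}

#' Phase 2: chain filtering and batched gapped extension for a chunk
#'
#' Chain-filters each query segment's ungapped segments, buffers the
#' survivors up to `budget` tasks, and dispatches each full buffer
#' sorted by query segment length ascending (ties by segment id, then
#' buffer order).  Dispatch order is logged; results are merged in
#' canonical order and are identical for any budget or worker count.
#'
#' @param usegs Phase-1 output data.frame.
#' @param segments Query segment data.frame.
#' @param chunk A `clx_chunk`.
#' @param sp A [scoring_params()] object.
#' @param band Chain-filter diagonal band half-width.
#' @param budget Maximum buffered phase-2 tasks before dispatch.
#' @param workers Number of serial task partitions.
#' @param log_fn Optional function(line) receiving structured log lines.
#' @return data.frame of gapped results (score-only) with `seg_id`.
#' @export
run_phase2 <- function(usegs, segments, chunk, sp, band = 16L,
                       budget = 65536L, workers = 1L, log_fn = NULL) {
  if (!nrow(usegs)) {
    return(empty_gapped())
  }
  seg_lookup <- setNames(seq_len(nrow(segments)), segments$seg_id)
  tasks <- vector("list", 64L)
  nt <- 0L
  for (sid in unique(usegs$seg_id)) {
    surv <- chain_filter(usegs[usegs$seg_id == sid, , drop = FALSE],
                         chunk$store, band = band)
    if (nrow(surv)) {
      nt <- nt + 1L
      if (nt > length(tasks)) tasks <- c(tasks, vector("list", length(tasks)))
      surv$seg_id <- sid
      tasks[[nt]] <- surv
    }
  }
  if (!nt) {
    return(empty_gapped())
  }
  tasks <- rbind_all(tasks[seq_len(nt)])
  out <- vector("list", 0L)
  from <- 1L
  while (from <= nrow(tasks)) {
    to <- min(from + budget - 1L, nrow(tasks))
    buf <- tasks[from:to, , drop = FALSE]
    seg_len <- vapply(buf$seg_id,
                      function(s) length(segments$codes[[seg_lookup[[as.character(s)]]]]),
                      integer(1))
    o <- order(seg_len, buf$seg_id, seq_len(nrow(buf)))
    buf <- buf[o, , drop = FALSE]
    if (!is.null(log_fn)) {
      log_fn(sprintf("phase=2 chunk=%d tasks=%d dispatch_len=%s",
                     chunk$chunk_id, nrow(buf),
                     paste(seg_len[o], collapse = ",")))
    }
    part <- split(seq_len(nrow(buf)), (seq_len(nrow(buf)) - 1L) %% workers)
    for (p in part) {
      for (i in p) {
        seg <- buf[i, , drop = FALSE]
        codes <- segments$codes[[seg_lookup[[as.character(seg$seg_id)]]]]
        g <- gapped_extend(codes, seg, chunk, sp)
        out[[length(out) + 1L]] <- data.frame(
          seg_id = seg$seg_id, score = g$score, qstart = g$qstart,
          qend = g$qend, dstart = g$dstart, dend = g$dend,
          qa = g$qa, da = g$da)
      }
    }
    from <- to + 1L
  }
  res <- rbind_all(out)
  res <- unique(res[order(res$seg_id, res$dstart, res$qstart, -res$score), ,
                    drop = FALSE])
  # identical alignments reached from different surviving segments
  # collapse to one HSP
  dup <- duplicated(res[, c("seg_id", "qstart", "qend", "dstart", "dend")])
  res <- res[!dup, , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_gapped <- function() {
  data.frame(seg_id = integer(0), score = integer(0), qstart = integer(0),
             qend = integer(0), dstart = integer(0), dend = integer(0),
             qa = integer(0), da = integer(0))
}

#' Full search: queries against a chunked database
#'
#' Processes chunks sequentially (optionally prefetching the next
#' chunk's index while the current one is being searched — an
#' optimization that never affects results), merges per-chunk hits with
#' E-values computed against the whole database's residue count, and
#' ranks them.
#'
#' @param reads Named character vector of DNA reads, or a FASTA/FASTQ
#'   path.
#' @param db_prefix Database prefix as given to [build_db()].
#' @param sp A [scoring_params()] object.
#' @param T_f,r_h,band,budget,workers,min_seg_len Pipeline parameters.
#' @param e_cut E-value report threshold.
#' @param max_targets Maximum reported rows per query.
#' @param prefetch Load the next chunk ahead of need.
#' @param log_fn Optional function(line) for the structured run log.
#' @return data.frame of ranked hits (one row per query-subject HSP)
#'   with attribute `n_dist_evals`.
#' @export
run_search <- function(reads, db_prefix, sp = scoring_params(),
                       T_f = 2L, r_h = 1L, band = 16L, budget = 65536L,
                       workers = 1L, min_seg_len = 10L, e_cut = 10,
                       max_targets = 100L, prefetch = TRUE,
                       log_fn = NULL) {
  if (is.character(reads) && is.null(names(reads)) && length(reads) == 1L) {
    reads <- read_queries(reads)
  }
  manifest <- read_manifest(db_prefix)
  n_global <- manifest$total_residues
  segments <- translate_queries(reads, min_len = min_seg_len)
  expect <- list(L = manifest$L, T_c = manifest$T_c, k_h = manifest$k_h)
  chunk_paths <- file.path(manifest$dir, manifest$chunks)
  missing <- !file.exists(chunk_paths)
  if (any(missing)) {
    stop(sprintf("missing index chunk file: %s", chunk_paths[which(missing)[1]]))
  }
  all_hits <- vector("list", length(chunk_paths))
  ndist <- 0
  nxt <- if (prefetch && length(chunk_paths)) {
    load_index(chunk_paths[1], expect)
  } else {
    NULL
  }
  for (ci in seq_along(chunk_paths)) {
    chunk <- if (prefetch) nxt else load_index(chunk_paths[ci], expect)
    if (prefetch) {
      nxt <- if (ci < length(chunk_paths)) {
        load_index(chunk_paths[ci + 1L], expect)
      } else {
        NULL
      }
    }
    p1 <- run_phase1(segments, chunk, sp, T_f = T_f, r_h = r_h,
                     workers = workers)
    ndist <- ndist + p1$n_dist_evals
    if (!is.null(log_fn)) {
      log_fn(sprintf("phase=1 chunk=%d segments=%d ungapped=%d dist_evals=%.0f",
                     chunk$chunk_id, nrow(segments), nrow(p1$usegs),
                     p1$n_dist_evals))
    }
    gp <- run_phase2(p1$usegs, segments, chunk, sp, band = band,
                     budget = budget, workers = workers, log_fn = log_fn)
    if (nrow(gp)) {
      all_hits[[ci]] <- finalize_chunk_hits(gp, segments, chunk, sp,
                                            n_global, e_cut)
    }
  }
  hits <- rbind_all(all_hits)
  if (is.null(hits)) {
    hits <- empty_hits()
  }
  out <- rank_and_threshold(hits, e_cut = e_cut, max_targets = max_targets)
  attr(out, "n_dist_evals") <- ndist
  out
}

empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0),
             mismatch = integer(0), gapopen = integer(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), evalue = numeric(0), bitscore = numeric(0),
             score = integer(0), frame = integer(0),
             qaln = character(0), daln = character(0),
             stringsAsFactors = FALSE)
}

# convert chunk-local gapped results into reportable hits: subject ids
# and subject-local coordinates, nucleotide query coordinates, E-values
# against the global residue count, and traceback alignments (only for
# hits inside the report threshold)
finalize_chunk_hits <- function(gp, segments, chunk, sp, n_global, e_cut) {
  seg_lookup <- setNames(seq_len(nrow(segments)), segments$seg_id)
  rows <- vector("list", nrow(gp))
  for (i in seq_len(nrow(gp))) {
    g <- as.list(gp[i, ])
    si <- seg_lookup[[as.character(g$seg_id)]]
    seg <- segments[si, ]
    space <- search_space(length(segments$codes[[si]]), n_global,
                          sp$lambda, sp$K)
    ev <- evalue(g$score, space)
    if (ev$evalue > e_cut) next
    aln <- traceback_align(segments$codes[[si]], g, chunk, sp)
    sidx <- sequence_of(chunk$store, g$dstart)
    soff <- chunk$store$offsets[sidx]
    qnt <- segment_nt_coords(seg$frame, seg$off, seg$read_len,
                             g$qstart, g$qend)
    rows[[i]] <- data.frame(
      qseqid = seg$read_id, sseqid = chunk$store$names[sidx],
      pident = 100 * aln$identities / aln$align_len,
      length = aln$align_len, mismatch = aln$mismatches,
      gapopen = aln$gapopens, qstart = qnt[1], qend = qnt[2],
      sstart = g$dstart - soff + 1L, send = g$dend - soff,
      evalue = ev$evalue, bitscore = ev$bitscore,
      score = g$score, frame = seg$frame,
      qaln = aln$qaln, daln = aln$daln, stringsAsFactors = FALSE)
  }
  rbind_all(rows)
}
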
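test_that("identical flanks extend without gaps to the full score", {
  sp <- default_sp()
  seqaa <- "MKVLATTRRDEWGHIPQNSY"
  ch <- build_chunk_index(c(a = seqaa))
  codes <- aa_encode(seqaa)
  seg <- data.frame(qstart = 5L, qend = 15L,
                    dstart = ch$store$offsets[1] + 5L,
                    dend = ch$store$offsets[1] + 15L,
                    score = 50L, diagonal = ch$store$offsets[1])
  g <- gapped_extend(codes, seg, ch, sp)
  full <- sum(vapply(seq_along(codes), function(i) {
    sp$matrix[codes[i] + 1L, codes[i] + 1L]
  }, numeric(1)))
  expect_identical(g$score, as.integer(full))
  expect_identical(g$qstart, 0L)
  expect_identical(g$qend, length(codes))
})

test_that("anchor adjacent to delimiters gives zero deltas", {
  sp <- default_sp()
  ch <- build_chunk_index(c(a = "CCCCCCCCCC"))
  codes <- aa_encode("C")
  l <- gapped_extend_score(codes, ch$store$codes, 0L,
                           ch$store$offsets[1], "left", sp,
                           c(ch$store$offsets[1], ch$store$offsets[1] + 10L))
  expect_identical(l$delta, 0L)
  expect_identical(l$qext, 0L)
})

test_that("saturating X_g equals the full-matrix oracle", {
  sp_inf <- scoring_params(x_drop_gapped = 1e6)
  set.seed(40)
  for (rep in 1:60) {
    A <- aa_encode(random_aa(sample(5:40, 1)))
    B <- aa_encode(random_aa(sample(5:40, 1)))
    got <- cpp_xdrop_score_wrap(A, B, sp_inf)
    want <- ref_extension_best(A, B, sp_inf)
    expect_identical(as.numeric(got), as.numeric(want))
  }
})

test_that("X_g monotonicity and convergence to the unpruned optimum", {
  set.seed(41)
  for (rep in 1:20) {
    A <- aa_encode(random_aa(40))
    B <- A
    mut <- sample(40, 8)
    B[mut] <- sample(0:19, 8, replace = TRUE)
    prev <- -Inf
    xg <- 4L
    repeat {
      sc <- cpp_xdrop_score_wrap(A, B, scoring_params(x_drop_gapped = xg))
      expect_true(sc >= prev)
      if (xg > 4096L) break
      prev <- sc
      xg <- xg * 2L
    }
    expect_identical(as.numeric(sc),
                     as.numeric(ref_extension_best(A, B, default_sp())))
  }
})

test_that("gapped score is bounded below by ungapped, above by Smith-Waterman", {
  d <- simulate_dataset(sim_config(seed = 43L, n_proteins = 12L,
                                   len_range = c(60L, 80L), n_reads = 30L,
                                   read_len = 90L, sub_rate = 0.05))
  dir <- withr::local_tempdir()
  writeLines(paste0(">", names(d$proteins), "\n", d$proteins),
             file.path(dir, "p.fasta"))
  build_db(file.path(dir, "p.fasta"), file.path(dir, "db"))
  ch <- load_index(file.path(dir, "db.001.idx"))
  sp <- default_sp()
  segs <- translate_queries(d$reads)
  checked <- 0L
  for (i in seq_len(nrow(segs))) {
    seeds <- search_seeds(segs$codes[[i]], ch)
    if (!nrow(seeds)) next
    u <- ungapped_extend(segs$codes[[i]], seeds, ch, sp)
    if (!nrow(u)) next
    surv <- chain_filter(u, ch$store)
    for (k in seq_len(nrow(surv))) {
      g <- gapped_extend(segs$codes[[i]], surv[k, ], ch, sp)
      expect_true(g$score >= surv$score[k])  # gap-free path included
      sidx <- sequence_of(ch$store, surv$dstart[k])
      sw <- smith_waterman(segs$aa[i], d$proteins[[sidx]], sp)
      expect_true(g$score <= sw$score)
      checked <- checked + 1L
    }
  }
  expect_true(checked >= 30L)
})

test_that("traceback reproduces the score-only result exactly", {
  sp <- default_sp()
  # identical windows: all-identity midline, no gaps
  seqaa <- "WQHKDERNSTVAGILM"
  ch <- build_chunk_index(c(a = seqaa))
  codes <- aa_encode(seqaa)
  seg <- data.frame(qstart = 3L, qend = 13L,
                    dstart = ch$store$offsets[1] + 3L,
                    dend = ch$store$offsets[1] + 13L, score = 0L,
                    diagonal = ch$store$offsets[1])
  g <- gapped_extend(codes, seg, ch, sp)
  aln <- traceback_align(codes, g, ch, sp)
  expect_identical(aln$qaln, seqaa)
  expect_identical(aln$daln, seqaa)
  expect_identical(aln$midline, strrep("|", nchar(seqaa)))
  expect_identical(aln$gapopens, 0L)
  # one inserted residue in the subject: exactly one gap column,
  # affine cost open + 1 * extend
  left <- "MKWLHTRDEC"
  right <- "FYPGNQSAVI"
  qaa <- paste0(left, right)
  saa <- paste0(left, "W", right)
  ch2 <- build_chunk_index(setNames(c(saa), "s"))
  codes2 <- aa_encode(qaa)
  seg2 <- data.frame(qstart = 0L, qend = 10L,
                     dstart = ch2$store$offsets[1],
                     dend = ch2$store$offsets[1] + 10L, score = 0L,
                     diagonal = ch2$store$offsets[1])
  g2 <- gapped_extend(codes2, seg2, ch2, sp)
  aln2 <- traceback_align(codes2, g2, ch2, sp)
  expect_identical(aln2$qaln, paste0(left, "-", right))
  expect_identical(aln2$daln, saa)
  ungapped_part <- sum(vapply(aa_encode(qaa), function(cd) {
    sp$matrix[cd + 1L, cd + 1L]
  }, numeric(1)))
  expect_identical(g2$score,
                   as.integer(ungapped_part - sp$gap_open - sp$gap_extend))
  expect_identical(aln2$gapopens, 1L)
})
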
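test_that("simulator respects its stated world", {
  # substitution 0, indel 0: best-frame translation is an exact
  # substring of the source protein
  d0 <- simulate_dataset(sim_config(seed = 80L, n_proteins = 10L,
                                    len_range = c(60L, 90L), n_reads = 8L,
                                    read_len = 90L, sub_rate = 0))
  for (i in seq_len(nrow(d0$truth))) {
    t <- d0$truth[i, ]
    read <- d0$reads[[t$read_id]]
    oriented <- if (t$strand == "+") read else revcomp(read)
    segs <- six_frame_translate(oriented, min_len = 1L)
    aa <- segs$aa[segs$frame == 1L]
    expect_identical(length(aa), 1L)
    expect_identical(aa, substr(d0$proteins[[t$protein_id]],
                                t$aa_start + 1L, t$aa_start + 30L))
  }
  # decoy fraction 1: empty truth table
  dd <- simulate_dataset(sim_config(seed = 81L, n_proteins = 5L,
                                    len_range = c(60L, 70L), n_reads = 4L,
                                    read_len = 90L, decoy_frac = 1))
  expect_identical(nrow(dd$truth), 0L)
  # identical seed, identical files
  d1 <- simulate_dataset(sim_config(seed = 82L, n_proteins = 6L,
                                    len_range = c(60L, 70L), n_reads = 5L,
                                    read_len = 90L),
                         dir = withr::local_tempdir())
  d2 <- simulate_dataset(sim_config(seed = 82L, n_proteins = 6L,
                                    len_range = c(60L, 70L), n_reads = 5L,
                                    read_len = 90L),
                         dir = withr::local_tempdir())
  for (f in names(d1$files)) {
    expect_identical(readBin(d1$files[[f]], "raw", file.size(d1$files[[f]])),
                     readBin(d2$files[[f]], "raw", file.size(d2$files[[f]])))
  }
})

test_that("smith_waterman matches hand values and Biostrings", {
  sp <- default_sp()
  r <- smith_waterman("AAA", "AAA", sp)
  expect_identical(r$score, 12)  # 3 x S(A,A) = 3 x 4
  expect_identical(r$qaln, "AAA")
  # all-negative pair floors at zero with an empty alignment
  m <- matrix(-1L, 22L, 22L)
  r0 <- smith_waterman("AC", "DE", scoring_params(matrix = m))
  expect_identical(r0$score, 0)
  expect_identical(r0$qaln, "")
  # 50 random pairs against the established implementation
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(83)
  for (i in 1:50) {
    a <- random_aa(sample(20:60, 1))
    b <- random_aa(sample(20:60, 1))
    got <- smith_waterman(a, b, sp)$score
    want <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = e$BLOSUM62, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
    expect_identical(got, as.numeric(want))
  }
})

test_that("score-only SW against a store matches the pairwise kernel", {
  set.seed(84)
  sp <- default_sp()
  prot <- setNames(vapply(rep(50L, 8), random_aa, character(1)),
                   sprintf("p%d", 1:8))
  store <- build_store(prot)
  qs <- lapply(1:6, function(i) aa_encode(random_aa(25)))
  m <- cpp_sw_scores_wrap(qs, store, sp)
  for (qi in seq_along(qs)) {
    for (si in seq_along(prot)) {
      expect_identical(m[qi, si],
                       as.integer(smith_waterman(aa_decode(qs[[qi]]),
                                                 prot[[si]], sp)$score))
    }
  }
})

test_that("top_hit_agreement implements the restricted-denominator rule", {
  oracle <- list(r1 = list(best = "s1", score = 50),
                 r2 = list(best = c("s2", "s3"), score = 40))
  hits <- data.frame(qseqid = c("r1", "r2"), sseqid = c("s1", "s3"),
                     bitscore = c(30, 20), evalue = c(1e-10, 1e-8),
                     stringsAsFactors = FALSE)
  expect_identical(top_hit_agreement(hits, oracle)$fraction, 1)
  # oracle tie satisfied by any co-optimal subject (r2 -> s3 above)
  hits$sseqid <- c("s9", "s9")
  expect_identical(top_hit_agreement(hits, oracle)$fraction, 0)
  # E-value restriction shrinks the denominator
  hits$evalue <- c(1e-10, 1)
  a <- top_hit_agreement(hits, oracle)
  expect_identical(a$n, 1L)
  # empty pipeline output: undefined, not zero
  none <- hits[0, ]
  expect_true(is.na(top_hit_agreement(none, oracle)$fraction))
})

test_that("truth table is recoverable by the SW oracle at 5% substitutions", {
  d <- get_benchmark()
  oracle <- get_benchmark_oracle()
  ok <- vapply(seq_len(nrow(d$truth)), function(i) {
    t <- d$truth[i, ]
    t$protein_id %in% oracle[[t$read_id]]$best
  }, logical(1))
  expect_true(mean(ok) >= 0.99)
})
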
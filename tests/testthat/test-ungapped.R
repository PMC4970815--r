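# published BLOSUM62 diagonal entries used as frozen expectations
BL62_DIAG <- c(A = 4, R = 5, N = 6, D = 6, C = 9, Q = 5, E = 5, G = 6,
               H = 8, I = 4)

test_that("extend_one_direction follows the X-dropoff walk", {
  sp <- default_sp()
  # identical flanks RRRR vs RRRR: 4 steps of S(R,R) = 5
  q <- aa_encode("RRRR")
  d <- c(CODE_DELIM, aa_encode("RRRR"), CODE_DELIM)
  r <- extend_one_direction(q, d, 0L, 1L, "right", sp)
  expect_identical(r$offset, 4L)
  expect_identical(r$delta, 4L * 5L)
  # crafted per-step scores +4, -5, -5, +9 with X_u = 9: stops after
  # step 3 (running -6 < max 4 - 9), best prefix is step 1
  m <- matrix(0L, 22L, 22L)
  m[1L, 1L] <- 4L       # A/A = +4
  m[2L, 2L] <- -5L      # C/C = -5
  m[3L, 3L] <- 9L       # D/D = +9
  sp2 <- scoring_params(matrix = m, x_drop_ungapped = 9L)
  q2 <- aa_encode("ACCD")
  d2 <- c(CODE_DELIM, aa_encode("ACCD"), CODE_DELIM)
  r2 <- extend_one_direction(q2, d2, 0L, 1L, "right", sp2)
  expect_identical(r2$offset, 1L)
  expect_identical(r2$delta, 4L)
  # delimiter immediately adjacent: offset 0, delta 0
  r3 <- extend_one_direction(q, d, 0L, 0L, "left", sp)
  expect_identical(r3, list(offset = 0L, delta = 0L))
})

test_that("ungapped_extend scores the seed window and applies the cutoff", {
  sp <- default_sp()
  ch <- build_chunk_index(c(a = "ARNDCQEGHI"))
  codes <- aa_encode("ARNDCQEGHI")
  seeds <- data.frame(qpos = 0L, dpos = ch$store$offsets[1])
  u <- ungapped_extend(codes, seeds, ch, sp)
  expect_identical(u$score, as.integer(sum(BL62_DIAG)))  # 58
  expect_identical(u$qend - u$qstart, 10L)
  # a cutoff above the attainable score discards the segment
  sp_hi <- scoring_params(min_ungapped_score = 100L)
  expect_identical(nrow(ungapped_extend(codes, seeds, ch, sp_hi)), 0L)
})

test_that("reported scores equal an independent recount", {
  sp <- default_sp()
  set.seed(21)
  ch <- build_chunk_index(setNames(vapply(rep(40L, 10), random_aa,
                                          character(1)),
                                   sprintf("s%d", 1:10)))
  for (rep in 1:200) {
    codes <- aa_encode(random_aa(30))
    qpos <- sample(0:20, 1)
    dp_ok <- extract_subsequences(ch$store, 10L)
    dpos <- sample(dp_ok, 1)
    u <- ungapped_extend(codes, data.frame(qpos = qpos, dpos = dpos), ch,
                         scoring_params(min_ungapped_score = -1000L))
    expect_identical(nrow(u), 1L)
    recount <- sum(vapply(seq_len(u$qend - u$qstart), function(i) {
      sp$matrix[codes[u$qstart + i] + 1L,
                ch$store$codes[u$dstart + i] + 1L]
    }, numeric(1)))
    expect_identical(u$score, as.integer(recount))
    # the segment always contains the original seed window
    expect_true(u$qstart <= qpos && u$qend >= qpos + 10L)
    expect_identical(u$diagonal, u$dstart - u$qstart)
  }
})

test_that("increasing X_u never decreases the score; order independence", {
  set.seed(22)
  ch <- build_chunk_index(setNames(vapply(rep(50L, 5), random_aa,
                                          character(1)),
                                   sprintf("s%d", 1:5)))
  codes <- aa_encode(random_aa(40))
  pos <- extract_subsequences(ch$store, 10L)
  seeds <- data.frame(qpos = sample(0:30, 50, replace = TRUE),
                      dpos = sample(pos, 50, replace = TRUE))
  lo <- ungapped_extend(codes, seeds, ch,
                        scoring_params(x_drop_ungapped = 5L,
                                       min_ungapped_score = -1000L))
  hi <- ungapped_extend(codes, seeds, ch,
                        scoring_params(x_drop_ungapped = 50L,
                                       min_ungapped_score = -1000L))
  expect_true(max(hi$score) >= max(lo$score))
  # batch-order independence: shuffled seeds give the same segment set
  sp <- scoring_params(min_ungapped_score = -1000L)
  a <- ungapped_extend(codes, seeds, ch, sp)
  b <- ungapped_extend(codes, seeds[sample(nrow(seeds)), ], ch, sp)
  key <- function(x) do.call(paste, c(x, sep = "_"))
  expect_setequal(key(a), key(b))
})
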
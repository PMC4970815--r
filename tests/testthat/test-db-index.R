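test_that("extract_subsequences counts delimiter-free windows", {
  expect_length(extract_subsequences(build_store(c(a = random_aa(10))), 10L), 1L)
  expect_length(extract_subsequences(build_store(c(a = random_aa(9))), 10L), 0L)
  set.seed(1)
  st <- build_store(c(a = random_aa(12), b = random_aa(15)))
  pos <- extract_subsequences(st, 10L)
  expect_length(pos, 9L)
  expect_true(!is.unsorted(pos, strictly = TRUE))
  # no window contains a delimiter
  for (p in pos) {
    expect_false(any(st$codes[(p + 1L):(p + 10L)] == CODE_DELIM))
  }
})

test_that("hamming_distance is the mismatch count and a metric", {
  expect_identical(hamming_distance(rep(0L, 10), rep(0L, 10)), 0L)
  expect_identical(hamming_distance(rep(0L, 10), c(rep(0L, 9), 1L)), 1L)
  expect_error(hamming_distance(1:3, 1:4), "mismatch")
  set.seed(2)
  for (i in 1:2000) {
    a <- sample(0:11, 10, replace = TRUE)
    b <- sample(0:11, 10, replace = TRUE)
    cc <- sample(0:11, 10, replace = TRUE)
    dab <- hamming_distance(a, b)
    expect_identical(dab, ref_hamming(a, b))
    expect_identical(dab, hamming_distance(b, a))
    expect_true(hamming_distance(a, cc) <= dab + hamming_distance(b, cc))
  }
  expect_identical(hamming_distance(0:9, 0:9), 0L)
})

test_that("hash_key is a most-significant-first base-10 encoding", {
  expect_identical(hash_key(rep(0L, 10)), 0L)
  expect_identical(hash_key(c(1L, rep(0L, 9))), 10000L)
  expect_true(is.na(hash_key(c(10L, rep(0L, 9)))))
  expect_true(is.na(hash_key(c(0L, 0L, 11L, 0L, 0L, rep(0L, 5)))))
  # injective over all 10^5 prefixes: the encoding is a bijection onto
  # 0..99999, checked by decoding
  set.seed(3)
  pre <- matrix(sample(0:9, 5000 * 5, replace = TRUE), ncol = 5)
  keys <- apply(pre, 1, function(g) hash_key(c(g, 0L, 0L, 0L, 0L, 0L)))
  dec <- t(vapply(keys, function(k) {
    (k %/% 10^(4:0)) %% 10
  }, numeric(5)))
  expect_equal(dec, pre, ignore_attr = TRUE)
})

test_that("greedy clustering matches the brute-force restatement", {
  # 5 identical windows -> 1 cluster with 4 members at distance 0
  st <- build_store(setNames(rep(paste(rep("A", 10), collapse = ""), 5),
                             paste0("s", 1:5)))
  cl <- greedy_cluster(extract_subsequences(st, 10L), st, T_c = 1L)
  expect_length(cl$rep, 1L)
  expect_identical(cl$dists[[1]], rep(0L, 4))
  # two far-apart windows -> two singletons
  st2 <- build_store(c(a = "AAAAAAAAAA", b = "AAAAACHKPG"))
  cl2 <- greedy_cluster(extract_subsequences(st2, 10L), st2, T_c = 1L)
  expect_length(cl2$rep, 2L)
  expect_identical(lengths(cl2$members), c(0L, 0L))
  # 200 random subsequences: identical clusters from the independent
  # oracle, and recomputed member distances agree
  set.seed(4)
  st3 <- random_store(20L, c(12L, 25L))
  pos <- extract_subsequences(st3, 10L)
  got <- greedy_cluster(pos, st3, T_c = 1L)
  want <- ref_greedy_cluster(pos, st3, L = 10L, T_c = 1L, k_h = 5L)
  expect_identical(got$rep, want$rep)
  expect_identical(got$members, want$members)
  expect_identical(got$dists, want$dists)
  # determinism
  expect_identical(greedy_cluster(pos, st3, T_c = 1L), got)
})

test_that("build_tables partitions clusters into B_e / B_r / B_m", {
  st <- build_store(c(a = "AAAAAAAAAA"))
  cl <- greedy_cluster(extract_subsequences(st, 10L), st, T_c = 1L)
  tb <- build_tables(cl, st)
  expect_length(tb$be_keys, 1L)
  expect_identical(tb$be_pos, 1L)
  expect_length(tb$br_keys, 0L)
  st2 <- build_store(setNames(rep("AAAAAAAAAA", 3), paste0("s", 1:3)))
  cl2 <- greedy_cluster(extract_subsequences(st2, 10L), st2, T_c = 1L)
  tb2 <- build_tables(cl2, st2)
  expect_length(tb2$be_keys, 0L)
  expect_length(tb2$br_keys, 1L)
  expect_length(tb2$bm_member, 2L)
  # random index: membership partition equals the keyable windows
  set.seed(5)
  st3 <- random_store(25L, c(12L, 30L))
  pos <- extract_subsequences(st3, 10L)
  groups <- reduce_codes(st3$codes)
  keyable <- pos[vapply(pos, function(p) {
    !any(groups[(p + 1L):(p + 5L)] >= 10L)
  }, logical(1))]
  cl3 <- greedy_cluster(pos, st3, T_c = 1L)
  tb3 <- build_tables(cl3, st3)
  all_pos <- c(tb3$be_pos, tb3$bm_rep, tb3$bm_member)
  expect_identical(sort(all_pos), sort(keyable))
  expect_false(anyDuplicated(all_pos) > 0L)
})

test_that("chunk_database assigns sequences greedily in input order", {
  seqs <- setNames(vapply(c(5L, 5L), random_aa, character(1)), c("a", "b"))
  expect_length(chunk_database(seqs, 1e9), 1L)
  seqs3 <- setNames(vapply(rep(100L, 3), random_aa, character(1)),
                    paste0("s", 1:3))
  expect_length(chunk_database(seqs3, 150), 3L)
  expect_error(chunk_database(seqs3, 50), "s1")
  set.seed(6)
  lens <- sample(10:80, 30, replace = TRUE)
  seqs4 <- setNames(vapply(lens, random_aa, character(1)),
                    sprintf("q%02d", 1:30))
  chunks <- chunk_database(seqs4, 200)
  expect_identical(unlist(unname(lapply(chunks, names))), names(seqs4))
  expect_identical(unlist(chunks, use.names = FALSE), unname(seqs4))
  expect_true(all(vapply(chunks, function(ch) sum(nchar(ch)), numeric(1)) <= 200))
})

test_that("index serialization round-trips and rejects mismatches", {
  set.seed(7)
  seqs <- setNames(vapply(rep(30L, 2), random_aa, character(1)), c("a", "b"))
  ch <- build_chunk_index(seqs)
  p <- withr::local_tempfile(fileext = ".idx")
  save_index(ch, p)
  back <- load_index(p)
  expect_identical(unclass(back), unclass(ch))
  expect_error(load_index(p, expect = list(L = 11L)), "incompatible")
  # byte-identical second save (500-window scale)
  set.seed(8)
  big <- build_chunk_index(setNames(vapply(rep(40L, 20), random_aa,
                                           character(1)),
                                    sprintf("s%02d", 1:20)))
  p1 <- withr::local_tempfile(fileext = ".idx")
  p2 <- withr::local_tempfile(fileext = ".idx")
  save_index(big, p1)
  save_index(big, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # non-index file is refused
  junk <- withr::local_tempfile(fileext = ".idx")
  writeLines("not an index", junk)
  expect_error(load_index(junk), "not a clustx index")
})
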
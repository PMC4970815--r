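# Test kit: seeded metagenomic read simulator, Smith-Waterman oracle
# wrappers, and the top-hit agreement statistic.

#' Simulation configuration
#'
#' Defaults emulate the benchmark setting: 200 proteins of 100-400
#' residues, 200 reads of 150 bp reverse-translated from protein
#' windows, 5% DNA substitution rate, no indels, no decoys.
#'
#' @param seed RNG seed (identical seed, identical dataset).
#' @param n_proteins,len_range Database size.
#' @param n_reads,read_len Read set size and read length (bp).
#' @param sub_rate,indel_rate Per-base DNA mutation rates.
#' @param decoy_frac Fraction of reads that are random DNA with no
#'   source protein.
#' @export
sim_config <- function(seed = 42L, n_proteins = 200L,
                       len_range = c(100L, 400L), n_reads = 200L,
                       read_len = 150L, sub_rate = 0.05,
                       indel_rate = 0, decoy_frac = 0) {
  stopifnot(read_len %% 3L == 0L, len_range[1] >= ceiling(read_len / 3),
            sub_rate >= 0, sub_rate <= 1, indel_rate >= 0,
            decoy_frac >= 0, decoy_frac <= 1)
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 len_range = as.integer(len_range),
                 n_reads = as.integer(n_reads),
                 read_len = as.integer(read_len), sub_rate = sub_rate,
                 indel_rate = indel_rate, decoy_frac = decoy_frac),
            class = "clx_sim_config")
}

# codon table inverted: amino acid -> synonymous codons (stops excluded)
codons_by_aa <- function() {
  if (is.null(the$codons_by_aa)) {
    gc <- genetic_code_table()
    gc <- gc[gc != "*"]
    the$codons_by_aa <- split(names(gc), unname(gc))
  }
  the$codons_by_aa
}

#' Simulate a protein database and metagenomic-style reads
#'
#' Proteins are sampled i.i.d. from uniform amino-acid frequencies.
#' Each non-decoy read is reverse-translated (uniform synonymous codon
#' choice) from a random window of a random protein, placed on a random
#' strand, then mutated at the DNA level at the configured substitution
#' and indel rates.  The truth table records each read's source.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: writes `proteins.fasta`,
#'   `reads.fastq` and `truth.tsv` there.
#' @return list with `proteins` (named character), `reads` (named
#'   character), `truth` (data.frame: read_id, protein_id, aa_start,
#'   strand, n_sub, n_indel) and, when `dir` is given, the file paths.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  plens <- sample(config$len_range[1]:config$len_range[2],
                  config$n_proteins, replace = TRUE)
  proteins <- vapply(plens, function(n) {
    paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
  }, character(1))
  names(proteins) <- sprintf("prot%04d", seq_len(config$n_proteins))
  cba <- codons_by_aa()
  w_aa <- config$read_len %/% 3L
  n_decoy <- round(config$decoy_frac * config$n_reads)
  is_decoy <- seq_len(config$n_reads) <= n_decoy
  reads <- character(config$n_reads)
  truth <- vector("list", config$n_reads)
  for (i in seq_len(config$n_reads)) {
    rid <- sprintf("read%04d", i)
    if (is_decoy[i]) {
      reads[i] <- paste(sample(bases, config$read_len, replace = TRUE),
                        collapse = "")
      next
    }
    j <- sample.int(config$n_proteins, 1L)
    s <- sample.int(plens[j] - w_aa + 1L, 1L) - 1L  # 0-based aa window start
    window <- substr(proteins[j], s + 1L, s + w_aa)
    aas <- strsplit(window, "", fixed = TRUE)[[1]]
    codons <- vapply(aas, function(a) {
      cc <- cba[[a]]
      cc[sample.int(length(cc), 1L)]
    }, character(1))
    dna <- paste(codons, collapse = "")
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") dna <- revcomp(dna)
    chars <- strsplit(dna, "", fixed = TRUE)[[1]]
    sub_at <- which(stats::runif(length(chars)) < config$sub_rate)
    for (p in sub_at) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    n_indel <- 0L
    if (config$indel_rate > 0) {
      indel_at <- which(stats::runif(length(chars)) < config$indel_rate)
      n_indel <- length(indel_at)
      for (p in rev(indel_at)) {  # right-to-left keeps positions valid
        if (stats::runif(1) < 0.5) {
          chars <- append(chars, sample(bases, 1L), after = p)
        } else {
          chars <- chars[-p]
        }
      }
    }
    reads[i] <- paste(chars, collapse = "")
    truth[[i]] <- data.frame(read_id = rid, protein_id = names(proteins)[j],
                             aa_start = s, strand = strand,
                             n_sub = length(sub_at), n_indel = n_indel,
                             stringsAsFactors = FALSE)
  }
  names(reads) <- sprintf("read%04d", seq_len(config$n_reads))
  truth <- rbind_all(truth)
  if (is.null(truth)) {
    truth <- data.frame(read_id = character(0), protein_id = character(0),
                        aa_start = integer(0), strand = character(0),
                        n_sub = integer(0), n_indel = integer(0),
                        stringsAsFactors = FALSE)
  }
  out <- list(proteins = proteins, reads = reads, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pfa <- file.path(dir, "proteins.fasta")
    writeLines(paste0(">", names(proteins), "\n", proteins), pfa)
    rfq <- file.path(dir, "reads.fastq")
    writeLines(sprintf("@%s\n%s\n+\n%s", names(reads), reads,
                       strrep("I", nchar(reads))), rfq)
    tts <- file.path(dir, "truth.tsv")
    utils::write.table(truth, tts, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- c(proteins = pfa, reads = rfq, truth = tts)
  }
  out
}

#' Exact Smith-Waterman local alignment (oracle)
#'
#' Full-matrix affine-gap local alignment with traceback, independent
#' of every pipeline code path (separate kernel).  Used as the
#' reference for sensitivity and score-bound tests.
#'
#' @param query,subject Amino-acid strings.
#' @param sp A [scoring_params()] object.
#' @return list with `score`, 0-based half-open `qstart`/`qend`/
#'   `sstart`/`send`, and aligned strings `qaln`/`saln`.
#' @export
smith_waterman <- function(query, subject, sp = scoring_params()) {
  A <- aa_encode(query)
  B <- aa_encode(subject)
  r <- cpp_smith_waterman(A, B, sp$matrix, sp$gap_open, sp$gap_extend)
  if (r$score == 0) {
    return(list(score = 0, qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
                qaln = "", saln = ""))
  }
  aln <- ops_to_alignment(r$ops, A, B, r$qstart, r$sstart, 1L)
  list(score = r$score, qstart = r$qstart, qend = r$qend,
       sstart = r$sstart, send = r$send,
       qaln = paste(aln$q, collapse = ""),
       saln = paste(aln$d, collapse = ""))
}

#' Best-scoring subject per read under the Smith-Waterman oracle
#'
#' Translates each read in six frames (same stop-splitting rule as the
#' pipeline) and scores every segment against every database sequence
#' with the score-only Smith-Waterman kernel.  The per-read best is the
#' maximum over its segments.
#'
#' @param reads Named character vector of DNA reads.
#' @param proteins Named character vector of database sequences.
#' @param sp A [scoring_params()] object.
#' @param min_seg_len Minimum translated segment length.
#' @return list mapping read id to list(best = character vector of
#'   co-optimal subject ids, score = best score); reads with no
#'   positive-scoring subject map to an empty `best`.
#' @export
oracle_top_hits <- function(reads, proteins, sp = scoring_params(),
                            min_seg_len = 10L) {
  store <- build_store(proteins)
  segments <- translate_queries(reads, min_len = min_seg_len)
  out <- setNames(vector("list", length(reads)), names(reads))
  if (!nrow(segments)) {
    return(lapply(out, function(x) list(best = character(0), score = 0)))
  }
  scores <- cpp_sw_scores(segments$codes, store$codes, length(proteins),
                          sp$matrix, sp$gap_open, sp$gap_extend)
  for (rid in names(reads)) {
    rows <- which(segments$read_id == rid)
    if (!length(rows)) {
      out[[rid]] <- list(best = character(0), score = 0)
      next
    }
    per_subject <- apply(scores[rows, , drop = FALSE], 2, max)
    top <- max(per_subject)
    out[[rid]] <- if (top <= 0) {
      list(best = character(0), score = 0)
    } else {
      list(best = store$names[per_subject == top], score = top)
    }
  }
  out
}

#' Top-hit agreement between pipeline output and the oracle
#'
#' Fraction of queries whose pipeline best subject matches the oracle
#' best subject, restricted to queries whose best pipeline E-value is
#' at or below `e_cut`.  Oracle ties count as correct when the pipeline
#' reports any co-optimal subject.  An empty denominator yields `NA`
#' (undefined), distinct from 0.
#'
#' @param hits Ranked pipeline hit data.frame ([run_search()] output).
#' @param oracle [oracle_top_hits()] output.
#' @param e_cut E-value restriction.
#' @return list with `fraction`, `n_correct` and `n` (denominator).
#' @export
top_hit_agreement <- function(hits, oracle, e_cut = 1e-5) {
  eligible <- character(0)
  correct <- 0L
  for (rid in unique(hits$qseqid)) {
    h <- hits[hits$qseqid == rid, , drop = FALSE]
    if (min(h$evalue) > e_cut) next
    eligible <- c(eligible, rid)
    best <- h$sseqid[which.max(h$bitscore)]
    if (!is.null(oracle[[rid]]) && best %in% oracle[[rid]]$best) {
      correct <- correct + 1L
    }
  }
  n <- length(eligible)
  list(fraction = if (n) correct / n else NA_real_,
       n_correct = correct, n = n)
}
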
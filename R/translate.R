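# Six-frame translation of DNA reads into protein query segments.
#
# Standard genetic code (NCBI table 1), codons containing N translate to
# X, and segments are maximal stop-free runs: translating through stops
# would require a stop penalty the search has no basis to set, so reads
# are split at stop codons instead.

genetic_code_table <- function() {
  if (is.null(the$gencode)) {
    the$gencode <- Biostrings::GENETIC_CODE
  }
  the$gencode
}

#' Reverse complement of a DNA string
#'
#' @param dna DNA string over A/C/G/T/N (case-insensitive).
#' @return The reverse complement, upper-cased.
#' @export
revcomp <- function(dna) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(dna), "", fixed = TRUE)[[1]]),
               collapse = ""))
}

translate_codons <- function(oriented, frame_off) {
  n_codon <- (nchar(oriented) - frame_off) %/% 3L
  if (n_codon < 1L) {
    return(character(0))
  }
  starts <- frame_off + 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(oriented, starts, starts + 2L)
  aa <- unname(genetic_code_table()[codons])
  aa[is.na(aa)] <- "X"  # codons containing N (or other ambiguity)
  aa
}

#' Six-frame translation of a read
#'
#' Translates a DNA read in all six frames and emits every maximal
#' stop-free run of at least `min_len` residues as a query segment.
#' Frames +1/+2/+3 read the forward strand at offsets 0/1/2; frames
#' -1/-2/-3 read the reverse complement the same way.
#'
#' @param read DNA string over A/C/G/T/N, case-insensitive.
#' @param min_len Minimum segment length in residues (default 10, the
#'   seed subsequence length: shorter segments cannot seed).
#' @param read_id Identifier recorded with each segment.
#' @return A data.frame with one row per segment: `read_id`, `frame`
#'   (+1..+3, -1..-3), `off` (0-based nucleotide offset of the segment's
#'   first codon on the frame's strand), `aa` (amino-acid string),
#'   `read_len`.
#' @export
six_frame_translate <- function(read, min_len = 10L, read_id = "read") {
  stopifnot(min_len >= 1L)
  read <- toupper(read)
  if (grepl("[^ACGTN]", read)) {
    stop("six_frame_translate(): read contains non-ACGTN characters")
  }
  read_len <- nchar(read)
  out <- vector("list", 6L)
  k <- 0L
  for (strand in c(1L, -1L)) {
    oriented <- if (strand == 1L) read else revcomp(read)
    for (fo in 0:2) {
      aa <- translate_codons(oriented, fo)
      if (!length(aa)) next
      stop_at <- aa == "*"
      run <- rle(stop_at)
      run_end <- cumsum(run$lengths)
      run_start <- run_end - run$lengths + 1L
      keep <- !run$values & run$lengths >= min_len
      if (!any(keep)) next
      for (j in which(keep)) {
        k <- k + 1L
        out[[k]] <- data.frame(
          read_id = read_id,
          frame = strand * (fo + 1L),
          off = fo + 3L * (run_start[j] - 1L),
          aa = paste(aa[run_start[j]:run_end[j]], collapse = ""),
          read_len = read_len,
          stringsAsFactors = FALSE)
        if (k == length(out)) out <- c(out, vector("list", length(out)))
      }
    }
  }
  if (k == 0L) {
    return(data.frame(read_id = character(0), frame = integer(0),
                      off = integer(0), aa = character(0),
                      read_len = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(k)])
}

#' Six-frame translation of a set of reads
#'
#' @param reads Named character vector of DNA reads.
#' @param min_len Minimum segment length in residues.
#' @return Segment data.frame as in [six_frame_translate()], with an
#'   additional `seg_id` column (1..n) and a `codes` list-column of
#'   encoded residues.
#' @export
translate_queries <- function(reads, min_len = 10L) {
  parts <- lapply(seq_along(reads), function(i) {
    six_frame_translate(reads[[i]], min_len = min_len,
                        read_id = names(reads)[i])
  })
  seg <- rbind_all(parts)
  if (is.null(seg) || !nrow(seg)) {
    seg <- data.frame(read_id = character(0), frame = integer(0),
                      off = integer(0), aa = character(0),
                      read_len = integer(0), stringsAsFactors = FALSE)
  }
  seg$seg_id <- seq_len(nrow(seg))
  seg$codes <- lapply(seg$aa, function(a) if (nzchar(a)) aa_encode(a) else integer(0))
  seg
}

# Map an amino-acid interval [qs, qe) (0-based, segment-local) to
# 1-based nucleotide coordinates on the read, BLASTX convention
# (reverse frames have qstart > qend).
segment_nt_coords <- function(frame, off, read_len, qs_aa, qe_aa) {
  if (frame > 0L) {
    c(off + 3L * qs_aa + 1L, off + 3L * qe_aa)
  } else {
    c(read_len - (off + 3L * qs_aa), read_len - (off + 3L * qe_aa) + 1L)
  }
}
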
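# Readers and the tabular writer.

#' Read query reads from FASTA or FASTQ
#'
#' Format is auto-detected from the first non-empty byte (`>` FASTA,
#' `@` FASTQ); gzip is transparent.  Ids are taken up to the first
#' whitespace, sequences upper-cased; N is allowed, FASTQ qualities are
#' ignored.
#'
#' @param path Input file path.
#' @return Named character vector of DNA reads.
#' @export
read_queries <- function(path) {
  con <- gzfile(path, "rt")
  first <- ""
  repeat {
    line <- readLines(con, 1L)
    if (!length(line)) break
    if (nzchar(trimws(line))) {
      first <- substr(trimws(line), 1L, 1L)
      break
    }
  }
  close(con)
  fmt <- switch(first, ">" = "fasta", "@" = "fastq",
                stop(sprintf("read_queries(): malformed record at line 1 of '%s': expected '>' or '@'",
                             path)))
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) {
      stop(sprintf("read_queries(): malformed %s in '%s': %s",
                   fmt, path, conditionMessage(e)))
    })
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read a protein database FASTA
#'
#' Multi-record, wrapped lines ok; `*` characters are stripped, ids
#' taken up to the first whitespace.
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_proteins <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- gsub("*", "", toupper(as.character(x)), fixed = TRUE)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

format_evalue <- function(e) {
  ifelse(e < 1e-2, sprintf("%.1e", e), as.character(signif(e, 2)))
}

#' Write hits in BLAST tabular (outfmt-6) layout
#'
#' Twelve tab-separated columns: qseqid, sseqid, pident (2 decimals),
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue (2
#' significant digits, scientific below 1e-2), bitscore (1 decimal).
#' Query coordinates are 1-based nucleotide positions on the read
#' (reverse frames have qstart > qend); subject coordinates are 1-based
#' amino-acid positions.  One `#`-prefixed header line is always
#' written so empty outputs are self-describing.
#'
#' @param hits Ranked hit data.frame from [run_search()].
#' @param path Output path.
#' @export
write_tabular <- function(hits, path) {
  header <- paste0("#", paste(c("qseqid", "sseqid", "pident", "length",
                                "mismatch", "gapopen", "qstart", "qend",
                                "sstart", "send", "evalue", "bitscore"),
                              collapse = "\t"))
  lines <- character(nrow(hits))
  if (nrow(hits)) {
    lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                     hits$qseqid, hits$sseqid, hits$pident, hits$length,
                     hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
                     hits$sstart, hits$send, format_evalue(hits$evalue),
                     hits$bitscore)
  }
  con <- file(path, "wb")  # binary mode: LF line endings on any platform
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Parse a file written by [write_tabular()]
#'
#' @param path Tabular file path.
#' @return data.frame with the twelve outfmt-6 columns.
#' @export
read_tabular <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12L), cols))
    return(out)
  }
  out <- utils::read.table(text = lines, sep = "\t", col.names = cols,
                           stringsAsFactors = FALSE)
  out
}
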
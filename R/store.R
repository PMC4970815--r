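# Delimiter-concatenated encoded sequence store.
#
# All residues of a database (or of a set of query segments) live in one
# flat integer code array; sequences are separated by the delimiter code
# 21, with one leading and one trailing delimiter.  Offsets are 0-based
# positions of each sequence's first residue in the code array.

#' Build a delimiter-concatenated sequence store
#'
#' Encodes a set of amino-acid sequences into one flat code array with a
#' delimiter (code 21) before the first, between consecutive, and after
#' the last sequence.  Duplicate names are disambiguated with a
#' deterministic numeric suffix (with a warning).
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @return An object of class `clx_store`: a list with `codes`
#'   (integer), `offsets` (0-based start of each sequence), `lengths`,
#'   `names`, and `total_residues`.
#' @examples
#' s <- build_store(c(s1 = "AC"))
#' s$codes   # 21 0 1 21
#' @export
build_store <- function(sequences) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)),
            all(nzchar(names(sequences))))
  nm <- names(sequences)
  if (anyDuplicated(nm)) {
    warning("build_store(): duplicate sequence names disambiguated by suffix")
    nm <- make.unique(nm, sep = ".")
  }
  enc <- lapply(unname(sequences), aa_encode)
  lens <- lengths(enc)
  n <- length(enc)
  codes <- integer(sum(lens) + n + 1L)
  codes[] <- CODE_DELIM
  offsets <- integer(n)
  at <- 1L  # 0-based position after the leading delimiter
  for (i in seq_len(n)) {
    offsets[i] <- at
    codes[(at + 1L):(at + lens[i])] <- enc[[i]]
    at <- at + lens[i] + 1L
  }
  structure(list(codes = codes, offsets = offsets, lengths = lens,
                 names = nm, total_residues = sum(lens)),
            class = "clx_store")
}

#' @export
print.clx_store <- function(x, ...) {
  cat(sprintf("<clx_store: %d sequences, %d residues>\n",
              length(x$names), x$total_residues))
  invisible(x)
}

#' Store coordinate lookups
#'
#' `sequence_of()` maps a 0-based position in the store's code array to
#' the index of the sequence containing it (`NA` for delimiter
#' positions); `position_of()` returns the 0-based start position of a
#' sequence.  `store_decode()` recovers sequence `i` as a string.
#'
#' @param store A `clx_store`.
#' @param pos Integer vector of 0-based positions into `store$codes`.
#' @param i Sequence index (1-based).
#' @export
sequence_of <- function(store, pos) {
  idx <- findInterval(pos, store$offsets)
  idx[idx == 0L] <- NA_integer_
  inside <- !is.na(idx) & pos < store$offsets[pmax(idx, 1L)] +
    store$lengths[pmax(idx, 1L)]
  idx[!inside] <- NA_integer_
  idx
}

#' @rdname sequence_of
#' @export
position_of <- function(store, i) {
  store$offsets[i]
}

#' @rdname sequence_of
#' @export
store_decode <- function(store, i) {
  off <- store$offsets[i]
  aa_decode(store$codes[(off + 1L):(off + store$lengths[i])])
}
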
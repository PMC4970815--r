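# Amino-acid code table, reduced alphabet, and scoring parameters.
#
# Codes are 5-bit-range integers: the 20 canonical residues get 0..19 in
# alphabetical order of their one-letter code, X (any non-canonical
# character, including B/Z/J/U/O) is 20, and the sequence delimiter is 21.

#' @rdname aa_encode
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname aa_encode
#' @export
CODE_X <- 20L

#' @rdname aa_encode
#' @export
CODE_DELIM <- 21L

# code -> reduced group, a fixed Murphy-style 10-group partition:
# {A,S,T} {C} {D,N} {E,Q} {F,W,Y} {G} {H} {I,L,M,V} {K,R} {P},
# plus X -> 10 and delimiter -> 11.
REDUCED_GROUPS <- local({
  g <- integer(22)
  grp <- list(`0` = c("A", "S", "T"), `1` = "C", `2` = c("D", "N"),
              `3` = c("E", "Q"), `4` = c("F", "W", "Y"), `5` = "G",
              `6` = "H", `7` = c("I", "L", "M", "V"), `8` = c("K", "R"),
              `9` = "P")
  for (k in names(grp)) {
    g[match(grp[[k]], AA_LETTERS)] <- as.integer(k)
  }
  g[CODE_X + 1L] <- 10L
  g[CODE_DELIM + 1L] <- 11L
  g
})

#' Encode and decode amino-acid sequences
#'
#' `aa_encode()` maps an amino-acid string to integer codes 0..20
#' (canonical residues 0..19 alphabetically, anything else to X = 20);
#' `aa_decode()` inverts it.  `reduce_codes()` projects codes onto the
#' 12-group reduced alphabet (10 residue groups + X group 10 + delimiter
#' group 11) used by the clustering metric.
#'
#' @param sequence Non-empty amino-acid string; case-insensitive.
#' @param codes Integer vector of codes in 0..21.
#' @return `aa_encode()`: integer vector of codes in 0..20.
#'   `aa_decode()`: a character scalar.  `reduce_codes()`: integer vector
#'   of group ids in 0..11.
#' @examples
#' aa_encode("ACDE")
#' reduce_codes(aa_encode("AST"))
#' @export
aa_encode <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("aa_encode(): empty input sequence")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  codes <- match(chars, AA_LETTERS) - 1L
  codes[is.na(codes)] <- CODE_X
  codes
}

#' @rdname aa_encode
#' @export
aa_decode <- function(codes) {
  stopifnot(all(codes >= 0L & codes <= CODE_DELIM))
  letters22 <- c(AA_LETTERS, "X", "|")
  paste(letters22[codes + 1L], collapse = "")
}

#' @rdname aa_encode
#' @export
reduce_codes <- function(codes) {
  codes <- as.integer(codes)
  if (length(codes) && (anyNA(codes) || any(codes < 0L | codes > CODE_DELIM))) {
    stop("reduce_codes(): codes must lie in 0..21")
  }
  REDUCED_GROUPS[codes + 1L]
}

# 22x22 integer substitution matrix in code order (rows/cols 0..21).
# Built from the published BLOSUM62 shipped with Biostrings; the
# delimiter row/column carries a large negative sentinel so that any
# accidental delimiter comparison terminates an extension immediately
# (extensions also check for the delimiter code explicitly).
DELIM_SCORE <- -32000L

blosum62_codes <- function() {
  if (!is.null(the$blosum62)) {
    return(the$blosum62)
  }
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  letters21 <- c(AA_LETTERS, "X")
  m <- matrix(DELIM_SCORE, 22L, 22L)
  m[1:21, 1:21] <- e$BLOSUM62[letters21, letters21]
  storage.mode(m) <- "integer"
  stopifnot(isSymmetric(unname(m)), all(m[CODE_X + 1L, 1:21] <= 0L))
  the$blosum62 <- m
  m
}

#' Scoring parameters for extension and statistics
#'
#' Bundles the substitution matrix (BLOSUM62 by default), affine gap
#' penalties, X-dropoff bounds for ungapped (`x_drop_ungapped`) and
#' gapped (`x_drop_gapped`) extension, the minimum raw score an ungapped
#' segment must reach to survive (`min_ungapped_score`), and the gapped
#' Karlin-Altschul constants used for E-values.  A gap of length k costs
#' `gap_open + k * gap_extend`.
#'
#' Defaults follow BLAST conventions for BLOSUM62 with gap penalties
#' 11/1: X-dropoffs 20/38 and gapped lambda = 0.267, K = 0.041.
#'
#' @param matrix 22x22 integer substitution matrix in code order, or
#'   `NULL` for BLOSUM62.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param x_drop_ungapped,x_drop_gapped Positive X-dropoff bounds.
#' @param min_ungapped_score Raw-score cutoff for ungapped segments.
#' @param lambda,K Gapped Karlin-Altschul parameters.
#' @return An object of class `clx_scoring`.
#' @export
scoring_params <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           x_drop_ungapped = 20L, x_drop_gapped = 38L,
                           min_ungapped_score = 20L,
                           lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) {
    matrix <- blosum62_codes()
  }
  stopifnot(is.matrix(matrix), dim(matrix) == c(22L, 22L),
            isSymmetric(unname(matrix)),
            gap_open > 0, gap_extend > 0,
            x_drop_ungapped > 0, x_drop_gapped > 0,
            lambda > 0, K > 0)
  storage.mode(matrix) <- "integer"
  structure(list(matrix = matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 x_drop_ungapped = as.integer(x_drop_ungapped),
                 x_drop_gapped = as.integer(x_drop_gapped),
                 min_ungapped_score = as.integer(min_ungapped_score),
                 lambda = lambda, K = K),
            class = "clx_scoring")
}
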
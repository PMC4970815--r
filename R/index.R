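# Database preprocessing: length-L subsequence extraction, greedy
# clustering in the reduced alphabet, the three seed-lookup tables
# B_e (singleton representatives), B_r (non-singleton representatives)
# and B_m (cluster members), database chunking, and index serialization.

INDEX_MAGIC <- "CLXIDX1"
INDEX_VERSION <- 1L
ALPHABET_ID <- 1L  # murphy-style 10-group reduced alphabet

#' Extract all delimiter-free length-L windows of a store
#'
#' @param store A `clx_store`.
#' @param L Window length (default 10).
#' @return Integer vector of 0-based window start positions, ascending.
#' @export
extract_subsequences <- function(store, L = 10L) {
  stopifnot(L >= 1L)
  pos <- lapply(seq_along(store$offsets), function(i) {
    n <- store$lengths[i] - L + 1L
    if (n < 1L) integer(0) else store$offsets[i] + seq_len(n) - 1L
  })
  unlist(pos, use.names = FALSE)
}

#' Reduced-Hamming distance between two group arrays
#'
#' Counts positions with unequal group ids.  This is a metric on group
#' arrays (the triangle inequality is what makes the similarity filter
#' sound).
#'
#' @param a,b Equal-length integer vectors of group ids.
#' @return Integer distance in `0..length(a)`.
#' @export
hamming_distance <- function(a, b) {
  cpp_hamming(as.integer(a), as.integer(b))
}

#' Base-10 positional hash key of a window's group prefix
#'
#' The key encodes the first `k_h` reduced group ids most-significant
#' first (injective over prefixes in groups 0..9).  Windows whose prefix
#' contains the X group (10) or delimiter group (11) are unkeyable and
#' return `NA`: they are excluded from the index and from lookup.
#'
#' @param groups Integer vector of group ids, length >= `k_h`.
#' @param k_h Prefix length (default 5).
#' @return Integer key in `0 .. 10^k_h - 1`, or `NA` if unkeyable.
#' @export
hash_key <- function(groups, k_h = 5L) {
  stopifnot(length(groups) >= k_h)
  pre <- groups[seq_len(k_h)]
  if (any(pre >= 10L)) {
    return(NA_integer_)
  }
  as.integer(sum(pre * 10^(k_h - seq_len(k_h))))
}

#' Hash keys to look up for a query window
#'
#' Returns the exact key of the window's prefix and, at neighborhood
#' radius `r_h = 1`, every key differing in exactly one of the `k_h`
#' prefix positions (9 alternatives per position), deduplicated with the
#' exact key first and neighbors ascending.  An unkeyable prefix yields
#' an empty vector.
#'
#' @inheritParams hash_key
#' @param r_h Neighborhood radius, 0 or 1.
#' @export
lookup_keys <- function(groups, k_h = 5L, r_h = 1L) {
  exact <- hash_key(groups, k_h)
  if (is.na(exact)) {
    return(integer(0))
  }
  if (r_h == 0L) {
    return(exact)
  }
  pre <- groups[seq_len(k_h)]
  nb <- integer(0)
  for (i in seq_len(k_h)) {
    alts <- setdiff(0:9, pre[i])
    nb <- c(nb, as.integer(exact + (alts - pre[i]) * 10^(k_h - i)))
  }
  c(exact, sort(unique(nb)))
}

#' Greedy first-fit clustering of database subsequences
#'
#' Processes keyable windows in position order; each joins the first
#' existing cluster (creation order) sharing its hash key whose
#' representative is within `T_c` in reduced-Hamming distance over all
#' `L` positions, else founds a new cluster.  Member-representative
#' distances are stored for the triangle-inequality filter.
#'
#' @param positions 0-based window start positions (from
#'   [extract_subsequences()]).
#' @param store A `clx_store`.
#' @param L Window length.
#' @param T_c Clustering distance threshold (default 1).
#' @param k_h Hash-key prefix length.
#' @return A list with parallel elements `rep` (representative
#'   positions), `members` (list of member position vectors) and `dists`
#'   (list of member-representative distances).
#' @export
greedy_cluster <- function(positions, store, L = 10L, T_c = 1L, k_h = 5L) {
  stopifnot(T_c >= 0L)
  groups <- reduce_codes(store$codes)
  cpp_greedy_cluster(groups, as.integer(positions), as.integer(L),
                     as.integer(T_c), as.integer(k_h))
}

singleton_clusters <- function(positions, store, L, k_h) {
  groups <- reduce_codes(store$codes)
  keyable <- vapply(positions, function(p) {
    !any(groups[(p + 1L):(p + k_h)] >= 10L)
  }, logical(1))
  pos <- positions[keyable]
  list(rep = as.integer(pos),
       members = rep(list(integer(0)), length(pos)),
       dists = rep(list(integer(0)), length(pos)))
}

#' Build the B_e / B_r / B_m lookup tables from clusters
#'
#' Singleton clusters are keyed into `B_e` (key -> representative
#' positions); clusters with members go into `B_r` (key -> cluster ids)
#' with their members and distances in `B_m`.  Tables are stored
#' flattened (sorted key vectors plus offset arrays) so they serialize
#' compactly and feed the C++ search directly.
#'
#' @param clusters Output of [greedy_cluster()].
#' @param store A `clx_store`.
#' @param L Window length.
#' @param k_h Hash-key prefix length.
#' @export
build_tables <- function(clusters, store, L = 10L, k_h = 5L) {
  groups <- reduce_codes(store$codes)
  nrep <- length(clusters$rep)
  keys <- vapply(clusters$rep, function(p) {
    hash_key(groups[(p + 1L):(p + L)], k_h)
  }, integer(1))
  stopifnot(!anyNA(keys))
  single <- lengths(clusters$members) == 0L
  flatten <- function(keys, payload) {
    if (!length(keys)) {
      return(list(keys = integer(0), off = 0L, val = integer(0)))
    }
    o <- order(keys, seq_along(keys))  # stable: creation order within key
    keys <- keys[o]
    payload <- payload[o]
    uk <- unique(keys)
    cnt <- as.integer(table(factor(keys, levels = uk)))
    list(keys = uk, off = c(0L, cumsum(cnt)), val = payload)
  }
  be <- flatten(keys[single], clusters$rep[single])
  multi_idx <- which(!single)
  br <- flatten(keys[multi_idx], seq_along(multi_idx) - 1L)  # 0-based cids
  bm_member <- unlist(clusters$members[multi_idx], use.names = FALSE)
  bm_dist <- unlist(clusters$dists[multi_idx], use.names = FALSE)
  if (is.null(bm_member)) bm_member <- integer(0)
  if (is.null(bm_dist)) bm_dist <- integer(0)
  list(be_keys = be$keys, be_off = be$off, be_pos = be$val,
       br_keys = br$keys, br_off = br$off, br_cid = br$val,
       bm_rep = as.integer(clusters$rep[multi_idx]),
       bm_off = c(0L, cumsum(lengths(clusters$members[multi_idx]))),
       bm_member = as.integer(bm_member), bm_dist = as.integer(bm_dist))
}

#' Assign database sequences to chunks
#'
#' Greedy assignment in input order with 1 byte/residue accounting: a
#' chunk closes when adding the next sequence would exceed
#' `chunk_bytes`.  The paper-scale default is 1 GB; desk-scale tests use
#' small values.
#'
#' @param sequences Named character vector of protein sequences.
#' @param chunk_bytes Chunk capacity in residues.
#' @return List of named character vectors, one per chunk.
#' @export
chunk_database <- function(sequences, chunk_bytes = 1e9) {
  lens <- nchar(sequences)
  too_big <- lens > chunk_bytes
  if (any(too_big)) {
    stop(sprintf("chunk_database(): sequence '%s' (%d residues) exceeds chunk_bytes = %g",
                 names(sequences)[which(too_big)[1]],
                 lens[which(too_big)[1]], chunk_bytes))
  }
  chunks <- list()
  start <- 1L
  acc <- 0
  for (i in seq_along(sequences)) {
    if (acc > 0 && acc + lens[i] > chunk_bytes) {
      chunks[[length(chunks) + 1L]] <- sequences[start:(i - 1L)]
      start <- i
      acc <- 0
    }
    acc <- acc + lens[i]
  }
  chunks[[length(chunks) + 1L]] <- sequences[start:length(sequences)]
  chunks
}

#' Build one chunk's index (store + tables)
#'
#' @param sequences Named character vector for this chunk.
#' @param chunk_id Integer chunk id (1-based).
#' @param seq_offset Global index of the sequence preceding this chunk's
#'   first sequence (0 for the first chunk).
#' @param L,T_c,k_h Index parameters.
#' @param cluster If `FALSE`, every subsequence becomes its own
#'   singleton cluster (used to measure the clustering benefit).
#' @return A `clx_chunk` object.
#' @export
build_chunk_index <- function(sequences, chunk_id = 1L, seq_offset = 0L,
                              L = 10L, T_c = 1L, k_h = 5L, cluster = TRUE) {
  store <- build_store(sequences)
  subs <- extract_subsequences(store, L)
  clusters <- if (cluster) {
    greedy_cluster(subs, store, L = L, T_c = T_c, k_h = k_h)
  } else {
    singleton_clusters(subs, store, L, k_h)
  }
  tables <- build_tables(clusters, store, L = L, k_h = k_h)
  structure(list(chunk_id = as.integer(chunk_id),
                 seq_offset = as.integer(seq_offset),
                 store = store, tables = tables,
                 params = list(L = as.integer(L), T_c = as.integer(T_c),
                               k_h = as.integer(k_h),
                               alphabet = ALPHABET_ID,
                               cluster = isTRUE(cluster))),
            class = "clx_chunk")
}

#' Serialize / deserialize one chunk index
#'
#' The file starts with magic bytes and an integer parameter header
#' (version, L, T_c, k_h, reduced-alphabet id); loading with mismatched
#' parameters raises an incompatibility error.
#'
#' @param chunk A `clx_chunk`.
#' @param path File path.
#' @param expect Optional named list of parameters (`L`, `T_c`, `k_h`)
#'   the caller requires; mismatch is an error.
#' @export
save_index <- function(chunk, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(INDEX_MAGIC), con)
  writeBin(c(INDEX_VERSION, chunk$params$L, chunk$params$T_c,
             chunk$params$k_h, chunk$params$alphabet), con, size = 4L,
           endian = "little")
  serialize(unclass(chunk), con, xdr = TRUE)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path, expect = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(INDEX_MAGIC)))
  if (!identical(magic, INDEX_MAGIC)) {
    stop(sprintf("load_index(): '%s' is not a clustx index file", path))
  }
  hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  names(hdr) <- c("version", "L", "T_c", "k_h", "alphabet")
  if (hdr[["version"]] != INDEX_VERSION || hdr[["alphabet"]] != ALPHABET_ID) {
    stop("load_index(): incompatible index version or alphabet")
  }
  for (p in intersect(names(expect), c("L", "T_c", "k_h"))) {
    if (hdr[[p]] != expect[[p]]) {
      stop(sprintf("load_index(): incompatible index: %s = %d in file, %d requested",
                   p, hdr[[p]], expect[[p]]))
    }
  }
  chunk <- unserialize(con)
  class(chunk) <- "clx_chunk"
  chunk
}

#' Build a chunked database index from a protein FASTA
#'
#' Reads the FASTA (wrapped lines ok, `*` stripped), assigns sequences
#' to chunks, builds and saves one index file per chunk, and writes a
#' JSON manifest (`<prefix>.manifest.json`) recording chunk files,
#' parameters, and the global residue count used for E-values.
#'
#' @param input Path to a protein FASTA, or a named character vector of
#'   sequences.
#' @param out_prefix Output path prefix.
#' @inheritParams build_chunk_index
#' @param chunk_bytes Chunk capacity in residues (default 1e9, the
#'   1 GB working-memory heuristic).
#' @return Path of the manifest file, invisibly.
#' @export
build_db <- function(input, out_prefix, chunk_bytes = 1e9,
                     L = 10L, T_c = 1L, k_h = 5L, cluster = TRUE) {
  sequences <- if (is.character(input) && length(input) == 1L &&
                   is.null(names(input))) {
    read_proteins(input)
  } else {
    input
  }
  chunks <- chunk_database(sequences, chunk_bytes)
  files <- character(length(chunks))
  off <- 0L
  for (i in seq_along(chunks)) {
    ch <- build_chunk_index(chunks[[i]], chunk_id = i, seq_offset = off,
                            L = L, T_c = T_c, k_h = k_h, cluster = cluster)
    files[i] <- sprintf("%s.%03d.idx", basename(out_prefix), i)
    save_index(ch, file.path(dirname(out_prefix), files[i]))
    off <- off + length(chunks[[i]])
  }
  manifest <- list(format = "clustx-index", version = INDEX_VERSION,
                   L = L, T_c = T_c, k_h = k_h, alphabet = ALPHABET_ID,
                   cluster = isTRUE(cluster),
                   chunks = files,
                   n_sequences = length(sequences),
                   total_residues = sum(nchar(sequences)))
  mpath <- paste0(out_prefix, ".manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

read_manifest <- function(db_prefix) {
  mpath <- paste0(db_prefix, ".manifest.json")
  if (!file.exists(mpath)) {
    stop(sprintf("database manifest not found: %s", mpath))
  }
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(m$format, "clustx-index")) {
    stop(sprintf("not a clustx manifest: %s", mpath))
  }
  m$dir <- dirname(db_prefix)
  m
}
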
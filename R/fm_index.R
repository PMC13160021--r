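#' Build an FM-index over a reference chunk
#'
#' Member sequences are concatenated with a record-separator symbol between
#' them (so matches can never span record boundaries) and a terminal
#' sentinel. The index stores the Burrows-Wheeler transform, cumulative
#' symbol counts, a checkpointed rank (Occ) structure, and the suffix array.
#' The suffix array is kept in full by default; `sa_sample_rate > 1` retains
#' every rate-th row and recovers the rest by LF-walking, trading locate
#' speed for memory.
#'
#' N bases are indexed as an ordinary symbol, but query patterns containing
#' N never match (ambiguous bases cannot anchor an exact seed).
#'
#' @param chunk a `reference_chunk` (see [partition_references()]).
#' @param sa_sample_rate integer >= 1; suffix-array row sampling rate.
#' @param occ_checkpoint integer; spacing of Occ rank checkpoints.
#' @return object of class `fm_index`.
#' @export
build_fm_index <- function(chunk, sa_sample_rate = 1L, occ_checkpoint = 64L) {
  if (!inherits(chunk, "reference_chunk")) stop("chunk must be a reference_chunk")
  seqs <- as.character(chunk$sequences)
  if (length(seqs) == 0L) stop("cannot index an empty chunk")
  codes <- lapply(seqs, encode_dna)
  widths <- lengths(codes)
  # interleave record separators, append sentinel
  pieces <- vector("list", 2L * length(codes))
  pieces[seq(1L, length(pieces), by = 2L)] <- codes
  if (length(codes) > 1L) {
    pieces[seq(2L, length(pieces) - 1L, by = 2L)] <- list(.CODE_SEP)
  }
  pieces[[length(pieces)]] <- .CODE_SENTINEL
  text <- unlist(pieces, use.names = FALSE)
  boundaries <- unname(c(0L, cumsum(widths[-length(widths)] + 1L)))

  sa <- sa_build_cpp(text)
  n <- length(text)
  prev <- ifelse(sa == 0L, n - 1L, sa - 1L)
  bwt <- text[prev + 1L]
  derived <- .fm_derive(bwt, occ_checkpoint)
  sa_sample_rate <- as.integer(sa_sample_rate)
  stopifnot(sa_sample_rate >= 1L)
  sa_vals <- if (sa_sample_rate == 1L) sa else sa[seq(1L, n, by = sa_sample_rate)]

  structure(list(text_length = n,
                 text = text,
                 bwt = bwt,
                 suffix_array = sa_vals,
                 sa_sample_rate = sa_sample_rate,
                 c_table = derived$c_table,
                 occ = derived$occ,
                 occ_checkpoint = derived$occ_checkpoint,
                 boundaries = boundaries,
                 member_ids = names(seqs),
                 member_lengths = as.integer(widths)),
            class = "fm_index")
}

# C table and checkpointed Occ matrix from a BWT code vector.
.fm_derive <- function(bwt, occ_checkpoint) {
  occ_checkpoint <- as.integer(occ_checkpoint)
  stopifnot(occ_checkpoint >= 1L)
  n <- length(bwt)
  counts <- tabulate(bwt + 1L, nbins = 7L)
  c_table <- c(0L, cumsum(counts))[1:7]
  cp <- seq(0L, n %/% occ_checkpoint * occ_checkpoint, by = occ_checkpoint)
  occ <- matrix(0L, nrow = length(cp), ncol = 7L)
  for (s in 0:6) {
    cum <- cumsum(bwt == s)
    occ[, s + 1L] <- as.integer(c(0L, cum[cp[-1L]]))
  }
  list(c_table = as.integer(c_table), occ = occ, occ_checkpoint = occ_checkpoint)
}

.fm_check_pattern <- function(pattern) {
  if (length(pattern) != 1L || is.na(pattern) || nchar(pattern) == 0L) {
    stop("pattern must be a single non-empty string")
  }
  normalize_dna(pattern)
}

#' Count exact occurrences of a pattern
#'
#' Backward search over the BWT. Patterns containing N (or any character
#' outside ACGT, which normalizes to N) return 0.
#'
#' @param index an `fm_index`.
#' @param pattern a single DNA string.
#' @return integer occurrence count in the concatenated text.
#' @export
fm_count <- function(index, pattern) {
  pattern <- .fm_check_pattern(pattern)
  if (grepl("N", pattern, fixed = TRUE)) return(0L)
  rng <- fm_search_cpp(index$bwt, index$c_table, index$occ,
                       index$occ_checkpoint, index$suffix_array,
                       index$sa_sample_rate, encode_dna(pattern))
  rng[2L] - rng[1L]
}

#' Locate exact occurrences of a pattern
#'
#' Occurrences are reported per member sequence as 0-based local offsets on
#' the forward strand; searching the reverse strand is the caller's
#' responsibility (reverse-complement the query, not the index).
#'
#' @inheritParams fm_count
#' @return data.frame with columns `accession`, `offset` (0-based),
#'   `strand` (always "forward"), sorted by (accession, offset).
#' @export
fm_locate <- function(index, pattern) {
  pattern <- .fm_check_pattern(pattern)
  empty <- data.frame(accession = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (grepl("N", pattern, fixed = TRUE)) return(empty)
  rng <- fm_search_cpp(index$bwt, index$c_table, index$occ,
                       index$occ_checkpoint, index$suffix_array,
                       index$sa_sample_rate, encode_dna(pattern))
  if (rng[2L] <= rng[1L]) return(empty)
  rows <- seq.int(rng[1L], rng[2L] - 1L)
  pos <- sa_lookup_cpp(rows, index$bwt, index$c_table, index$occ,
                       index$occ_checkpoint, index$suffix_array,
                       index$sa_sample_rate)
  loc <- global_to_local(index, pos)
  loc <- loc[order(loc$accession, loc$offset), , drop = FALSE]
  rownames(loc) <- NULL
  loc$strand <- "forward"
  loc
}

# Map global text positions to (accession, local 0-based offset).
global_to_local <- function(index, pos) {
  member <- findInterval(pos, index$boundaries)
  data.frame(accession = index$member_ids[member],
             offset = as.integer(pos - index$boundaries[member]),
             stringsAsFactors = FALSE)
}

# Inverse of global_to_local.
local_to_global <- function(index, accession, offset) {
  member <- match(accession, index$member_ids)
  if (anyNA(member)) stop("unknown accession")
  as.integer(index$boundaries[member] + offset)
}

.FM_MAGIC <- "TXAFMIDX"
.FM_VERSION <- 1L

#' Save / load an FM-index
#'
#' The on-disk layout is a versioned binary format: an 8-byte magic string,
#' a format version, the integer header (text length, member count, suffix
#' array sampling rate), member ids, boundaries and lengths, the text and
#' BWT as one byte per symbol, and the stored suffix-array values.
#' Truncated or foreign files are rejected as a whole; a load never returns
#' a partial index.
#'
#' @param index an `fm_index`.
#' @param path file path.
#' @return `save_index` returns the path invisibly; `load_index` returns an
#'   `fm_index` equivalent to the saved one for every query.
#' @export
save_index <- function(index, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.FM_MAGIC), con)
  writeBin(c(.FM_VERSION, index$text_length, length(index$member_ids),
             index$sa_sample_rate, index$occ_checkpoint,
             length(index$suffix_array)),
           con, size = 4L, endian = "little")
  id_blob <- charToRaw(paste(index$member_ids, collapse = "\n"))
  writeBin(length(id_blob), con, size = 4L, endian = "little")
  writeBin(id_blob, con)
  writeBin(index$boundaries, con, size = 4L, endian = "little")
  writeBin(index$member_lengths, con, size = 4L, endian = "little")
  writeBin(as.raw(index$text), con)
  writeBin(as.raw(index$bwt), con)
  writeBin(index$suffix_array, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  .take <- function(what, n, size = NA_integer_) {
    got <- if (identical(what, "raw")) {
      readBin(con, "raw", n = n)
    } else {
      readBin(con, "integer", n = n, size = 4L, endian = "little")
    }
    if (length(got) != n) stop("corrupt or truncated index file: ", path)
    got
  }
  magic <- rawToChar(.take("raw", nchar(.FM_MAGIC)))
  if (!identical(magic, .FM_MAGIC)) {
    stop("not a taxalign index file (bad magic number): ", path)
  }
  header <- .take("integer", 6L)
  if (header[1L] != .FM_VERSION) {
    stop("unsupported index format version ", header[1L], ": ", path)
  }
  n <- header[2L]; n_members <- header[3L]
  sa_rate <- header[4L]; occ_cp <- header[5L]; n_sa <- header[6L]
  id_len <- .take("integer", 1L)
  member_ids <- strsplit(rawToChar(.take("raw", id_len)), "\n", fixed = TRUE)[[1L]]
  if (length(member_ids) != n_members) stop("corrupt or truncated index file: ", path)
  boundaries <- .take("integer", n_members)
  member_lengths <- .take("integer", n_members)
  text <- as.integer(.take("raw", n))
  bwt <- as.integer(.take("raw", n))
  sa_vals <- .take("integer", n_sa)
  derived <- .fm_derive(bwt, occ_cp)
  structure(list(text_length = n,
                 text = text,
                 bwt = bwt,
                 suffix_array = sa_vals,
                 sa_sample_rate = sa_rate,
                 c_table = derived$c_table,
                 occ = derived$occ,
                 occ_checkpoint = derived$occ_checkpoint,
                 boundaries = boundaries,
                 member_ids = member_ids,
                 member_lengths = member_lengths),
            class = "fm_index")
}
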
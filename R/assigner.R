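#' Seeding parameters for taxonomic assignment
#'
#' Defaults target 150 bp reads: 18-mer seeds every 9 bases (plus a final
#' seed flush with the read end), at least two seeds agreeing on a diagonal
#' before a candidate is aligned, and a 5-base diagonal tolerance.
#'
#' @param seed_length seed length in bases (>= 10).
#' @param seed_interval bases between seed start offsets (>= 1).
#' @param min_seed_hits minimum seed support for a candidate region (>= 1).
#' @param diagonal_tolerance maximum diagonal spread within one candidate.
#' @return object of class `seeding_params`.
#' @export
seeding_params <- function(seed_length = 18L, seed_interval = 9L,
                           min_seed_hits = 2L, diagonal_tolerance = 5L) {
  seed_length <- as.integer(seed_length)
  seed_interval <- as.integer(seed_interval)
  min_seed_hits <- as.integer(min_seed_hits)
  diagonal_tolerance <- as.integer(diagonal_tolerance)
  if (seed_length < 10L) stop("seed_length must be >= 10")
  if (seed_interval < 1L) stop("seed_interval must be >= 1")
  if (min_seed_hits < 1L) stop("min_seed_hits must be >= 1")
  if (diagonal_tolerance < 0L) stop("diagonal_tolerance must be >= 0")
  structure(list(seed_length = seed_length, seed_interval = seed_interval,
                 min_seed_hits = min_seed_hits,
                 diagonal_tolerance = diagonal_tolerance),
            class = "seeding_params")
}

.seed_offsets <- function(read_length, params) {
  if (read_length < params$seed_length) return(integer(0))
  offs <- seq.int(0L, read_length - params$seed_length,
                  by = params$seed_interval)
  last <- read_length - params$seed_length
  if (offs[length(offs)] != last) offs <- c(offs, last)
  offs
}

#' Decompose a read into fixed-length seeds
#'
#' The spaced schedule starts at offset 0 and advances by `seed_interval`,
#' with one final seed ending at the last base if the schedule did not
#' already emit it. The same schedule is applied to the reverse complement
#' (offsets measured on the reverse-complemented read). Seeds containing N
#' are omitted; a read shorter than one seed yields an empty set (the read
#' is later reported unassigned, not an error).
#'
#' @param read_sequence a single DNA string.
#' @param params a [seeding_params()].
#' @return data.frame with columns `read_offset` (0-based), `seed`, `strand`.
#' @export
extract_seeds <- function(read_sequence, params = seeding_params()) {
  read_sequence <- normalize_dna(read_sequence)
  offs <- .seed_offsets(nchar(read_sequence), params)
  empty <- data.frame(read_offset = integer(0), seed = character(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (length(offs) == 0L) return(empty)
  both <- lapply(c(forward = read_sequence, reverse = revcomp(read_sequence)),
                 function(s) {
                   data.frame(read_offset = offs,
                              seed = substring(s, offs + 1L,
                                               offs + params$seed_length),
                              stringsAsFactors = FALSE)
                 })
  out <- rbind(cbind(both$forward, strand = "forward"),
               cbind(both$reverse, strand = "reverse"))
  out <- out[!grepl("N", out$seed, fixed = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster seed hits into candidate regions
#'
#' Seed matches are grouped per (accession, strand) by alignment diagonal
#' (`ref_offset - read_offset`, with reverse-strand read offsets measured on
#' the reverse-complemented read). A greedy pass over sorted diagonals opens
#' a new cluster whenever the diagonal drifts more than
#' `diagonal_tolerance` from the cluster's smallest diagonal. Clusters with
#' support below `min_seed_hits` are dropped. Candidates are returned in
#' descending support order; ties break by (taxid, accession,
#' projected_start, strand) so evaluation order is reproducible.
#'
#' @param seed_matches data.frame with columns `read_offset`, `accession`,
#'   `ref_offset`, `strand`.
#' @param taxonomy a [taxonomy_map()].
#' @param params a [seeding_params()].
#' @return data.frame of candidate regions: `accession`, `taxid`, `strand`,
#'   `projected_start`, `support`.
#' @export
collect_candidates <- function(seed_matches, taxonomy,
                               params = seeding_params()) {
  empty <- data.frame(accession = character(0), taxid = integer(0),
                      strand = character(0), projected_start = integer(0),
                      support = integer(0), stringsAsFactors = FALSE)
  if (nrow(seed_matches) == 0L) return(empty)
  d <- seed_matches
  d$diag <- d$ref_offset - d$read_offset
  d <- d[order(d$accession, d$strand, d$diag, d$read_offset), , drop = FALSE]
  out <- list()
  i0 <- 1L
  n <- nrow(d)
  for (i in seq_len(n)) {
    boundary <- i == n ||
      d$accession[i + 1L] != d$accession[i0] ||
      d$strand[i + 1L] != d$strand[i0] ||
      d$diag[i + 1L] - d$diag[i0] > params$diagonal_tolerance
    if (boundary) {
      support <- i - i0 + 1L
      if (support >= params$min_seed_hits) {
        out[[length(out) + 1L]] <- data.frame(
          accession = d$accession[i0],
          taxid = unname(taxonomy$accession_to_taxid[d$accession[i0]]),
          strand = d$strand[i0],
          projected_start = d$diag[i0],
          support = support,
          stringsAsFactors = FALSE)
      }
      i0 <- i + 1L
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$support, res$taxid, res$accession,
                   res$projected_start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Align a read against a candidate reference window
#'
#' Semi-global unit-cost edit distance: the full read must align, with free
#' gaps at both window ends. The result is reported only when the distance
#' is within `max_edits`. Coordinates are window-relative (half-open);
#' [assign_read()] shifts them to sequence coordinates. The kernel's score
#' contract is exact: it agrees with the plain quadratic dynamic program.
#'
#' @param read_sequence a single DNA string.
#' @param reference_window the reference slice to align against.
#' @param max_edits maximum edit distance accepted.
#' @return list with `edit_distance`, `start`, `end` (window-relative,
#'   half-open), or NULL if no alignment within `max_edits` (or the window
#'   is empty).
#' @export
align_candidate <- function(read_sequence, reference_window, max_edits) {
  if (is.null(reference_window) || nchar(reference_window) == 0L) return(NULL)
  res <- align_semiglobal_cpp(encode_dna(normalize_dna(read_sequence)),
                              encode_dna(normalize_dna(reference_window)))
  if (res[1L] > max_edits) return(NULL)
  list(edit_distance = res[1L], start = res[2L], end = res[3L])
}

.strand_labels <- c("forward", "reverse")

.member_taxids <- function(index, taxonomy) {
  mtax <- unname(taxonomy$accession_to_taxid[index$member_ids])
  if (anyNA(mtax)) {
    stop("index member(s) missing from taxonomy: ",
         paste(index$member_ids[is.na(mtax)], collapse = ", "))
  }
  as.integer(mtax)
}

.recompute_status <- function(report) {
  if (nrow(report) == 0L) {
    report$status <- character(0)
    return(report)
  }
  ntax <- stats::ave(report$taxid, report$read_id,
                     FUN = function(x) length(unique(x)))
  report$status <- ifelse(ntax > 1L, "multi_taxon", "unique")
  report
}

.empty_report <- function() {
  data.frame(read_id = character(0), taxid = integer(0),
             accession = character(0), ref_start = integer(0),
             ref_end = integer(0), strand = character(0),
             edit_distance = integer(0), status = character(0),
             stringsAsFactors = FALSE)
}

#' Assign reads to taxa against one chunk index
#'
#' For each read: extract spaced seeds on both strands, look them up in the
#' FM-index, cluster hits into candidate regions, and evaluate candidates in
#' descending seed-support order with threshold-bounded semi-global
#' alignment. Once a passing alignment is found for a taxon, no further
#' candidates of that taxon are aligned (per-taxon early stop), so each
#' read records at most one hit per taxid. Reverse-strand hits are reported
#' on the forward reference strand with `strand = "reverse"`.
#'
#' @param reads named character vector or [Biostrings::DNAStringSet]
#'   (names become read ids; unnamed reads get `read_<i>`).
#' @param index an `fm_index` built by [build_fm_index()].
#' @param taxonomy a [taxonomy_map()] resolving every index member.
#' @param params a [seeding_params()].
#' @param max_edits maximum accepted edit distance (default 7, about 5% of
#'   a 150 bp read).
#' @param early_stop logical; FALSE aligns every candidate and records every
#'   passing alignment (audit mode; hits are then not unique per taxid).
#' @return data.frame report: `read_id`, `taxid`, `accession`, `ref_start`,
#'   `ref_end` (0-based half-open), `strand`, `edit_distance`, `status`.
#'   Attributes: `align_calls` (total alignments evaluated), `n_reads`.
#' @export
assign_reads <- function(reads, index, taxonomy, params = seeding_params(),
                         max_edits = 7L, early_stop = TRUE) {
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  mtax <- .member_taxids(index, taxonomy)
  arank <- match(index$member_ids, sort(index$member_ids))
  pad <- as.integer(max_edits) + 5L
  res <- assign_reads_cpp(index$text, index$boundaries, index$member_lengths,
                          mtax, arank, index$bwt, index$c_table, index$occ,
                          index$occ_checkpoint, index$suffix_array,
                          index$sa_sample_rate, unname(reads),
                          params$seed_length, params$seed_interval,
                          params$min_seed_hits, params$diagonal_tolerance,
                          as.integer(max_edits), pad, isTRUE(early_stop))
  report <- data.frame(read_id = ids[res$read],
                       taxid = mtax[res$member],
                       accession = index$member_ids[res$member],
                       ref_start = res$ref_start,
                       ref_end = res$ref_end,
                       strand = .strand_labels[res$strand + 1L],
                       edit_distance = res$edit_distance,
                       stringsAsFactors = FALSE)
  report <- .recompute_status(report)
  if (nrow(report) == 0L) report <- .empty_report()
  attr(report, "align_calls") <- res$align_calls
  attr(report, "n_reads") <- length(reads)
  report
}

#' Assign a single read
#'
#' Thin wrapper around [assign_reads()] returning the per-read assignment
#' structure: the hit set (at most one per taxid) and a status of
#' `unassigned`, `unique`, or `multi_taxon`.
#'
#' @param read a single DNA string.
#' @param index,taxonomy,params,max_edits see [assign_reads()].
#' @param read_id identifier used in the report.
#' @return list with `read_id`, `hits` (data.frame), `status`.
#' @export
assign_read <- function(read, index, taxonomy, params = seeding_params(),
                        max_edits = 7L, read_id = "read") {
  rep1 <- assign_reads(stats::setNames(read, read_id), index, taxonomy,
                       params, max_edits)
  status <- if (nrow(rep1) == 0L) "unassigned"
            else if (length(unique(rep1$taxid)) == 1L) "unique"
            else "multi_taxon"
  hits <- rep1[, setdiff(names(rep1), "status"), drop = FALSE]
  structure(list(read_id = read_id, hits = hits, status = status),
            class = "read_assignment")
}

#' Merge per-chunk assignment reports
#'
#' Reports from independently processed chunks are unioned per read.
#' Exact duplicate rows (same read, taxid, accession, ref_start) are
#' silently deduplicated; when the same taxid is hit from multiple chunks,
#' the hit with the lowest edit distance is kept (ties: lexicographically
#' smallest accession, then smallest ref_start). Status is recomputed on
#' the merged hit sets.
#'
#' @param reports list of data.frames as returned by [assign_reads()].
#' @return merged report data.frame.
#' @export
merge_reports <- function(reports) {
  reports <- Filter(function(r) nrow(r) > 0L, reports)
  if (length(reports) == 0L) return(.empty_report())
  all <- do.call(rbind, lapply(reports, function(r) {
    r[, c("read_id", "taxid", "accession", "ref_start", "ref_end",
          "strand", "edit_distance")]
  }))
  key <- paste(all$read_id, all$taxid, all$accession, all$ref_start, sep = "\r")
  all <- all[!duplicated(key), , drop = FALSE]
  ord <- order(all$read_id, all$taxid, all$edit_distance, all$accession,
               all$ref_start)
  all <- all[ord, , drop = FALSE]
  keep <- !duplicated(paste(all$read_id, all$taxid, sep = "\r"))
  merged <- all[keep, , drop = FALSE]
  rownames(merged) <- NULL
  .recompute_status(merged)
}

#' Resolve ambiguous multi-taxon assignments
#'
#' Two optional filters applied to a merged per-sample report. First, for
#' each read, hits whose edit distance exceeds the read's best distance
#' plus `edit_slack` are dropped. Second, per-taxon sample support is
#' computed as the fraction of (assigned) reads whose hit set includes the
#' taxon; hits to taxa below `min_taxon_read_fraction` are dropped unless
#' removal would empty a read's hit set, in which case the read keeps its
#' minimum-edit-distance hit (ties: smallest taxid). Both filters default
#' to off (`edit_slack = Inf` would also disable the first; the default 0
#' keeps only best-distance hits when the resolution step is invoked).
#'
#' @param report merged assignment report.
#' @param edit_slack non-negative number (Inf disables the distance filter).
#' @param min_taxon_read_fraction abundance threshold in [0, 1].
#' @return filtered report with recomputed status.
#' @export
resolve_ambiguity <- function(report, edit_slack = 0,
                              min_taxon_read_fraction = 0) {
  if (nrow(report) == 0L) return(report)
  best <- stats::ave(report$edit_distance, report$read_id, FUN = min)
  keep <- report$edit_distance <= best + edit_slack
  report <- report[keep, , drop = FALSE]

  if (min_taxon_read_fraction > 0) {
    n_reads <- length(unique(report$read_id))
    support <- tapply(report$read_id, report$taxid,
                      function(x) length(unique(x))) / n_reads
    low_tax <- as.integer(names(support)[support < min_taxon_read_fraction])
    is_low <- report$taxid %in% low_tax
    all_low <- stats::ave(is_low, report$read_id, FUN = all) > 0
    rescue <- rep(FALSE, nrow(report))
    if (any(all_low)) {
      # keep the min-edit hit (tie: smallest taxid) for reads losing all hits
      ord <- order(report$read_id, report$edit_distance, report$taxid)
      first <- !duplicated(report$read_id[ord])
      rescue[ord][first] <- TRUE
    }
    report <- report[!is_low | (all_low & rescue), , drop = FALSE]
  }
  rownames(report) <- NULL
  .recompute_status(report)
}

#' Read/write assignment reports as TSV
#'
#' @param report assignment report data.frame.
#' @param path file path.
#' @return `write_assignments` returns the path invisibly;
#'   `read_assignments` returns the report data.frame.
#' @export
write_assignments <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(read_id = "character"))
  if (nrow(d) == 0L) return(.empty_report())
  d
}
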
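#' Taxon-resolved count matrices
#'
#' A `count_matrix` bundles an integer matrix of read counts with its row
#' keys — (taxid, feature-or-ortholog-group id) pairs — its ordered sample
#' ids, and an aggregation level: `species_gene`, `species_OG`, or
#' `genus_OG` (genus roll-ups of gene-level matrices are labelled
#' `genus_gene`).
#'
#' @param counts integer matrix, rows aligned with `keys`.
#' @param keys data.frame with columns `taxid`, `feature`.
#' @param level aggregation level label.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, keys, level) {
  stopifnot(nrow(counts) == nrow(keys), all(counts >= 0),
            all(c("taxid", "feature") %in% names(keys)))
  key <- paste(keys$taxid, keys$feature, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (taxid, feature) row keys")
  structure(list(counts = counts, keys = keys,
                 samples = colnames(counts), level = level),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix [", x$level, "]: ", nrow(x$counts), " rows x ",
      length(x$samples), " samples, total ", sum(x$counts), " counts\n",
      sep = "")
  invisible(x)
}

.tally_matrix <- function(long, samples, level) {
  # long: data.frame(taxid, feature, sample, w)
  rkey <- paste(long$taxid, long$feature, sep = "\r")
  ukey <- sort(unique(rkey))
  ri <- match(rkey, ukey)
  ci <- match(long$sample, samples)
  m <- matrix(0, nrow = length(ukey), ncol = length(samples),
              dimnames = list(NULL, samples))
  for (k in seq_len(nrow(long))) {
    m[ri[k], ci[k]] <- m[ri[k], ci[k]] + long$w[k]
  }
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  keys <- data.frame(taxid = as.integer(vapply(parts, `[[`, "", 1L)),
                     feature = vapply(parts, `[[`, "", 2L),
                     stringsAsFactors = FALSE)
  list(m = m, keys = keys)
}

# Round a non-negative numeric vector to integers preserving its rounded
# total (largest-remainder rule; ties broken by position).
.largest_remainder <- function(x) {
  target <- round(sum(x))
  fl <- floor(x)
  rem <- as.integer(target - sum(fl))
  if (rem > 0L) {
    ord <- order(-(x - fl), seq_along(x))
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Aggregate gene assignments into a taxon-by-gene count matrix
#'
#' Each sample's primary gene assignments are tallied per (taxid,
#' feature_id). Intergenic reads never count. Reads flagged `multi_taxon`
#' are excluded by default to avoid double counting; with
#' `multi = "fractional"` each such read is split evenly across its taxa
#' and per-sample column totals are restored to integers by
#' largest-remainder rounding.
#'
#' @param assignments named list of per-sample gene-assignment data.frames
#'   (see [assign_genes_report()]); names are sample ids.
#' @param multi "exclude" (default) or "fractional".
#' @return a `count_matrix` at level `species_gene`.
#' @export
aggregate_counts <- function(assignments, multi = c("exclude", "fractional")) {
  multi <- match.arg(multi)
  samples <- names(assignments)
  if (is.null(samples)) stop("assignments must be a named list (sample ids)")
  longs <- lapply(samples, function(s) {
    d <- assignments[[s]]
    d <- d[d$feature_id != .INTERGENIC, , drop = FALSE]
    if ("status" %in% names(d)) {
      if (multi == "exclude") {
        d <- d[d$status != "multi_taxon", , drop = FALSE]
        w <- rep(1, nrow(d))
      } else {
        k <- stats::ave(rep(1, nrow(d)), d$read_id, FUN = sum)
        w <- 1 / k
      }
    } else {
      w <- rep(1, nrow(d))
    }
    if (nrow(d) == 0L) return(NULL)
    data.frame(taxid = d$taxid, feature = d$feature_id, sample = s, w = w,
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, longs)
  if (is.null(long) || nrow(long) == 0L) {
    return(count_matrix(matrix(0L, 0L, length(samples),
                               dimnames = list(NULL, samples)),
                        data.frame(taxid = integer(0), feature = character(0)),
                        "species_gene"))
  }
  tl <- .tally_matrix(long, samples, "species_gene")
  m <- tl$m
  if (multi == "fractional") {
    m <- apply(m, 2L, .largest_remainder)
    if (is.null(dim(m))) m <- matrix(m, ncol = length(samples))
    colnames(m) <- samples
  }
  storage.mode(m) <- "integer"
  count_matrix(m, tl$keys, "species_gene")
}

#' Collapse gene rows to ortholog groups
#'
#' Rows sharing (taxid, OG) are summed. Features absent from the map are
#' kept under their own feature id (`unmapped = "keep"`, which conserves
#' column totals) or dropped.
#'
#' @param matrix a `count_matrix` at level `species_gene`.
#' @param og_map data.frame with columns `feature_id`, `og_id` (many-to-one).
#' @param unmapped "keep" or "drop".
#' @return a `count_matrix` at level `species_OG`.
#' @export
collapse_to_og <- function(matrix, og_map, unmapped = c("keep", "drop")) {
  unmapped <- match.arg(unmapped)
  stopifnot(inherits(matrix, "count_matrix"))
  if (matrix$level != "species_gene") {
    stop("collapse_to_og expects a species_gene matrix, got ", matrix$level)
  }
  og <- og_map$og_id[match(matrix$keys$feature, og_map$feature_id)]
  if (unmapped == "keep") {
    og[is.na(og)] <- matrix$keys$feature[is.na(og)]
    keep <- rep(TRUE, length(og))
  } else {
    keep <- !is.na(og)
  }
  .regroup(matrix, matrix$keys$taxid[keep], og[keep], keep, "species_OG")
}

#' Roll species up to genus
#'
#' Rows sharing (genus, OG) are summed; column totals are conserved.
#' Species without a genus ancestor surface the error from [genus_of()].
#'
#' @param matrix a `count_matrix` at level `species_OG`.
#' @param taxonomy a [taxonomy_map()].
#' @return a `count_matrix` at level `genus_OG`.
#' @export
collapse_to_genus <- function(matrix, taxonomy) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (!matrix$level %in% c("species_OG", "species_gene")) {
    stop("collapse_to_genus expects a species-level matrix, got ",
         matrix$level)
  }
  genus <- genus_of(taxonomy, matrix$keys$taxid)
  level <- if (matrix$level == "species_OG") "genus_OG" else "genus_gene"
  .regroup(matrix, genus, matrix$keys$feature, rep(TRUE, nrow(matrix$counts)),
           level)
}

.regroup <- function(matrix, taxid, feature, keep, level) {
  m <- matrix$counts[keep, , drop = FALSE]
  key <- paste(taxid, feature, sep = "\r")
  g <- rowsum(m, group = key, reorder = TRUE)
  parts <- strsplit(rownames(g), "\r", fixed = TRUE)
  keys <- data.frame(taxid = as.integer(vapply(parts, `[[`, "", 1L)),
                     feature = vapply(parts, `[[`, "", 2L),
                     stringsAsFactors = FALSE)
  rownames(g) <- NULL
  storage.mode(g) <- "integer"
  count_matrix(g, keys, level)
}

#' Filter low-abundance rows
#'
#' Keeps a row only if, within each sample group, at least `min_samples`
#' samples have a count of at least `min_count` (defaults 5 reads in 3
#' samples). `scope = "any"` switches to requiring the threshold in at
#' least one group. Values of surviving rows are unchanged, so the filter
#' is idempotent. A summary of rows in/out is attached as attribute
#' `filter_report`.
#'
#' @param matrix a `count_matrix`.
#' @param sample_groups named character/factor vector mapping every sample
#'   to its group.
#' @param min_count minimum per-sample count (0 disables the filter).
#' @param min_samples minimum number of qualifying samples per group.
#' @param scope "each" (default) or "any".
#' @return the filtered `count_matrix`.
#' @export
filter_low_abundance <- function(matrix, sample_groups, min_count = 5L,
                                 min_samples = 3L, scope = c("each", "any")) {
  scope <- match.arg(scope)
  stopifnot(inherits(matrix, "count_matrix"))
  missing <- setdiff(matrix$samples, names(sample_groups))
  if (length(missing) > 0L) {
    stop("sample(s) missing a group label: ", paste(missing, collapse = ", "))
  }
  groups <- as.character(sample_groups[matrix$samples])
  per_group <- do.call(cbind, lapply(unique(groups), function(g) {
    sub <- matrix$counts[, groups == g, drop = FALSE]
    rowSums(sub >= min_count) >= min_samples
  }))
  keep <- if (scope == "each") apply(per_group, 1L, all)
          else apply(per_group, 1L, any)
  if (min_count <= 0L) keep <- rep(TRUE, nrow(matrix$counts))
  out <- count_matrix(matrix$counts[keep, , drop = FALSE],
                      matrix$keys[keep, , drop = FALSE], matrix$level)
  attr(out, "filter_report") <- list(n_in = nrow(matrix$counts),
                                     n_kept = sum(keep),
                                     n_dropped = sum(!keep))
  out
}

#' Write a count matrix as dense and triplet TSV
#'
#' The dense layout has the two row-key columns (`taxid`, `feature`)
#' followed by one column per sample — directly loadable by differential
#' expression tools. The optional triplet layout lists (taxid, feature,
#' sample, count) for nonzero cells.
#'
#' @param matrix a `count_matrix`.
#' @param path dense TSV path.
#' @param triplet_path optional triplet TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path, triplet_path = NULL) {
  dense <- cbind(matrix$keys, as.data.frame(matrix$counts))
  utils::write.table(dense, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(triplet_path)) {
    nz <- which(matrix$counts > 0L, arr.ind = TRUE)
    trip <- data.frame(taxid = matrix$keys$taxid[nz[, 1L]],
                       feature = matrix$keys$feature[nz[, 1L]],
                       sample = matrix$samples[nz[, 2L]],
                       count = matrix$counts[nz],
                       stringsAsFactors = FALSE)
    trip <- trip[order(trip$taxid, trip$feature, trip$sample), , drop = FALSE]
    utils::write.table(trip, triplet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
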
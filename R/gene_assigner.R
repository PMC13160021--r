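#' Parse CDS features from a GFF3 file
#'
#' Only rows of type CDS are kept: in bacterial annotation they are the
#' reliably present, protein-linked record. GFF's 1-based inclusive
#' coordinates are converted to the package's 0-based half-open convention;
#' the printed start is retained as `source_start_1based`. The feature id
#' is resolved as the first available of `locus_tag`, `ID`, `Name`.
#'
#' @param gff3_path path to a GFF3 file.
#' @param accession_filter optional character vector; rows on other
#'   sequences are skipped (with a message giving the skipped count).
#' @return data.frame of gene features: `feature_id`, `gene_name`,
#'   `product`, `protein_id`, `accession`, `start`, `end` (0-based
#'   half-open), `strand`, `source_start_1based`.
#' @export
parse_gff <- function(gff3_path, accession_filter = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  mc <- S4Vectors::mcols(gr)
  grab <- function(col) {
    if (col %in% names(mc)) {
      v <- mc[[col]]
      if (methods::is(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) if (length(x) == 0L) NA_character_
                    else as.character(x[[1L]]), character(1L))
      }
      as.character(v)
    } else {
      rep(NA_character_, length(gr))
    }
  }
  feature_id <- grab("locus_tag")
  id2 <- grab("ID"); id3 <- grab("Name")
  feature_id[is.na(feature_id)] <- id2[is.na(feature_id)]
  feature_id[is.na(feature_id)] <- id3[is.na(feature_id)]
  if (anyNA(feature_id)) {
    stop("CDS row without locus_tag/ID/Name in ", gff3_path)
  }
  blank <- function(x) ifelse(is.na(x), "", x)
  features <- data.frame(
    feature_id = feature_id,
    gene_name = blank(grab("gene")),
    product = blank(grab("product")),
    protein_id = blank(grab("protein_id")),
    accession = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    source_start_1based = GenomicRanges::start(gr),
    stringsAsFactors = FALSE)
  if (!is.null(accession_filter)) {
    drop <- !(features$accession %in% accession_filter)
    if (any(drop)) {
      message("parse_gff: skipped ", sum(drop),
              " CDS row(s) on sequences outside the accession filter")
    }
    features <- features[!drop, , drop = FALSE]
  }
  bad <- features$start >= features$end
  if (any(bad)) {
    stop("CDS with start > end rejected: ", features$feature_id[bad][1L])
  }
  rownames(features) <- NULL
  features
}

#' Write gene features as GFF3
#'
#' Inverse of [parse_gff()] for the feature table used throughout the
#' package (internal 0-based half-open coordinates become 1-based
#' inclusive).
#'
#' @param features feature data.frame (see [parse_gff()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- sprintf("ID=%s;locus_tag=%s", features$feature_id,
                   features$feature_id)
  opt <- function(key, val) ifelse(nchar(val) > 0L,
                                   sprintf(";%s=%s", key, val), "")
  attrs <- paste0(attrs, opt("gene", features$gene_name),
                  opt("product", features$product),
                  opt("protein_id", features$protein_id))
  lines <- sprintf("%s\ttaxalign\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                   features$accession, features$start + 1L, features$end,
                   features$strand, attrs)
  writeLines(lines, con)
  invisible(path)
}

#' Build an interval index over gene features
#'
#' One interval structure per reference sequence, supporting overlap
#' queries by (accession, start, end) in the package's 0-based half-open
#' coordinates.
#'
#' @param features feature data.frame from [parse_gff()].
#' @return object of class `gene_index`.
#' @export
build_gene_index <- function(features) {
  idx_by_acc <- split(seq_len(nrow(features)), features$accession)
  ranges <- lapply(idx_by_acc, function(ii) {
    IRanges::IRanges(start = features$start[ii] + 1L, end = features$end[ii])
  })
  structure(list(features = features, idx_by_acc = idx_by_acc,
                 ranges = ranges, feature_count = nrow(features)),
            class = "gene_index")
}

#' Query features overlapping an interval
#'
#' @param gene_index a `gene_index`.
#' @param accession reference sequence id.
#' @param start,end 0-based half-open query interval.
#' @return feature data.frame rows with an `overlap_bases` column, ordered
#'   by decreasing overlap (ties: smallest start, then feature_id).
#' @export
query_gene_overlaps <- function(gene_index, accession, start, end) {
  empty <- cbind(gene_index$features[0L, , drop = FALSE],
                 overlap_bases = integer(0))
  if (!accession %in% names(gene_index$ranges)) return(empty)
  q <- IRanges::IRanges(start = start + 1L, end = end)
  hits <- IRanges::findOverlaps(q, gene_index$ranges[[accession]])
  sub <- S4Vectors::subjectHits(hits)
  if (length(sub) == 0L) return(empty)
  rows <- gene_index$idx_by_acc[[accession]][sub]
  f <- gene_index$features[rows, , drop = FALSE]
  f$overlap_bases <- as.integer(pmin(f$end, end) - pmax(f$start, start))
  f <- f[order(-f$overlap_bases, f$start, f$feature_id), , drop = FALSE]
  rownames(f) <- NULL
  f
}

.INTERGENIC <- "intergenic"

.resolve_min_overlap <- function(min_overlap, span) {
  if (min_overlap < 1) ceiling(min_overlap * span) else min_overlap
}

#' Assign one alignment to a gene
#'
#' Among features overlapping the aligned span `[ref_start, ref_end)` by at
#' least `min_overlap` bases, the primary assignment is the feature with
#' the maximum overlap (ties: smallest start, then lexicographic
#' feature_id). With no qualifying feature the read is `intergenic`.
#' Strand is ignored unless `stranded = TRUE` (unstranded RNA-seq
#' protocols are common); when stranded, a forward-strand alignment
#' matches "+" features and a reverse-strand alignment "-" features.
#'
#' @param alignment a one-row data.frame (or list) with `read_id`, `taxid`,
#'   `accession`, `ref_start`, `ref_end`, `strand`.
#' @param gene_index a `gene_index`.
#' @param min_overlap minimum overlap: bases if >= 1, else fraction of the
#'   aligned span.
#' @param stranded restrict overlaps to the alignment strand.
#' @return one-row data.frame: `read_id`, `taxid`, `accession`,
#'   `feature_id` (or "intergenic"), `gene_name`, `product`, `protein_id`,
#'   `overlap_bases`.
#' @export
assign_genes <- function(alignment, gene_index, min_overlap = 1,
                         stranded = FALSE) {
  al <- as.data.frame(alignment, stringsAsFactors = FALSE)
  res <- assign_genes_report(al, gene_index, min_overlap = min_overlap,
                             stranded = stranded, warn_missing = TRUE)
  res[1L, , drop = FALSE]
}

#' Assign genes for a whole taxonomic report
#'
#' Vectorized gene assignment: every row of a (merged) taxonomic
#' assignment report is converted into its primary gene assignment using
#' the same rules as [assign_genes()]. Rows on accessions absent from the
#' index become `intergenic` (a message reports the count).
#'
#' @param report taxonomic assignment report (see [assign_reads()]).
#' @param gene_index a `gene_index`.
#' @param min_overlap,stranded see [assign_genes()].
#' @param warn_missing message when accessions are absent from the index.
#' @return data.frame with one row per report row: `read_id`, `taxid`,
#'   `accession`, `feature_id`, `gene_name`, `product`, `protein_id`,
#'   `overlap_bases`, plus `status` when present in the input.
#' @export
assign_genes_report <- function(report, gene_index, min_overlap = 1,
                                stranded = FALSE, warn_missing = TRUE) {
  n <- nrow(report)
  out <- data.frame(read_id = report$read_id, taxid = report$taxid,
                    accession = report$accession,
                    feature_id = rep(.INTERGENIC, n),
                    gene_name = rep("", n), product = rep("", n),
                    protein_id = rep("", n),
                    overlap_bases = rep(0L, n),
                    stringsAsFactors = FALSE)
  missing_acc <- 0L
  for (acc in unique(report$accession)) {
    rows <- which(report$accession == acc)
    if (!acc %in% names(gene_index$ranges)) {
      missing_acc <- missing_acc + length(rows)
      next
    }
    q <- IRanges::IRanges(start = report$ref_start[rows] + 1L,
                          end = report$ref_end[rows])
    hits <- IRanges::findOverlaps(q, gene_index$ranges[[acc]])
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    frow <- gene_index$idx_by_acc[[acc]][S4Vectors::subjectHits(hits)]
    f <- gene_index$features[frow, , drop = FALSE]
    rs <- report$ref_start[rows][qh]
    re <- report$ref_end[rows][qh]
    ov <- as.integer(pmin(f$end, re) - pmax(f$start, rs))
    min_ov <- .resolve_min_overlap(min_overlap, re - rs)
    keep <- ov >= min_ov
    if (stranded) {
      al_strand <- ifelse(report$strand[rows][qh] == "forward", "+", "-")
      keep <- keep & (f$strand == al_strand)
    }
    if (!any(keep)) next
    qh <- qh[keep]; f <- f[keep, , drop = FALSE]; ov <- ov[keep]
    ord <- order(qh, -ov, f$start, f$feature_id)
    first <- !duplicated(qh[ord])
    pick <- ord[first]
    tgt <- rows[qh[pick]]
    out$feature_id[tgt] <- f$feature_id[pick]
    out$gene_name[tgt] <- f$gene_name[pick]
    out$product[tgt] <- f$product[pick]
    out$protein_id[tgt] <- f$protein_id[pick]
    out$overlap_bases[tgt] <- ov[pick]
  }
  if (missing_acc > 0L && warn_missing) {
    message("assign_genes_report: ", missing_acc,
            " alignment(s) on accessions absent from the gene index ",
            "reported as intergenic")
  }
  if ("status" %in% names(report)) out$status <- report$status
  out
}

#' Export proteins for assigned genes
#'
#' Writes each distinct assigned feature's protein once, FASTA, with the
#' feature id as the record id (headers compatible with downstream ortholog
#' annotators). The reference protein FASTA is keyed by `protein_id`.
#' Assigned features without a protein record are skipped and counted in a
#' message.
#'
#' @param gene_assignments data.frame from [assign_genes_report()].
#' @param protein_fasta_path reference protein FASTA path.
#' @param out_path output FASTA path.
#' @return number of protein records written.
#' @export
export_proteins <- function(gene_assignments, protein_fasta_path, out_path) {
  aa <- Biostrings::readAAStringSet(protein_fasta_path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  genic <- gene_assignments[gene_assignments$feature_id != .INTERGENIC,
                            c("feature_id", "protein_id"), drop = FALSE]
  genic <- genic[!duplicated(genic$feature_id), , drop = FALSE]
  found <- genic$protein_id %in% names(aa)
  if (any(!found)) {
    message("export_proteins: ", sum(!found),
            " assigned feature(s) had no protein record and were skipped")
  }
  out <- aa[genic$protein_id[found]]
  names(out) <- genic$feature_id[found]
  Biostrings::writeXStringSet(out, out_path)
  length(out)
}
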
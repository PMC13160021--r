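#' Build a taxonomy map from reference metadata
#'
#' The metadata table is self-contained: it carries, for every reference
#' accession, its species taxid and the genus that species belongs to, so no
#' live taxonomy service is needed. Species-to-genus links are the minimum
#' required for genus-level count aggregation; deeper taxonomies can be built
#' directly from parent/rank vectors for testing.
#'
#' @param metadata data.frame with columns `accession`, `taxid`,
#'   `species_name`, `genus_taxid`, `genus_name`.
#' @return An object of class `taxonomy_map` with named members
#'   `accession_to_taxid`, `taxid_to_name`, `taxid_to_parent`, `rank_of`.
#' @export
taxonomy_map <- function(metadata) {
  required <- c("accession", "taxid", "species_name", "genus_taxid", "genus_name")
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0L) {
    stop("metadata is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(metadata$accession)) {
    stop("duplicate accession in metadata: ",
         metadata$accession[duplicated(metadata$accession)][1L])
  }
  acc2tax <- as.integer(metadata$taxid)
  names(acc2tax) <- metadata$accession
  if (any(acc2tax <= 0L)) stop("taxids must be positive")

  sp <- unique(data.frame(taxid = as.integer(metadata$taxid),
                          name = metadata$species_name,
                          parent = as.integer(metadata$genus_taxid)))
  if (anyDuplicated(sp$taxid)) {
    stop("species taxid maps to more than one genus: ",
         sp$taxid[duplicated(sp$taxid)][1L])
  }
  ge <- unique(data.frame(taxid = as.integer(metadata$genus_taxid),
                          name = metadata$genus_name))
  if (anyDuplicated(ge$taxid)) {
    stop("genus taxid has inconsistent names: ",
         ge$taxid[duplicated(ge$taxid)][1L])
  }
  taxid_to_name <- c(stats::setNames(sp$name, sp$taxid),
                     stats::setNames(ge$name, ge$taxid))
  taxid_to_parent <- c(stats::setNames(sp$parent, sp$taxid),
                       stats::setNames(rep(NA_integer_, nrow(ge)), ge$taxid))
  rank_of <- c(stats::setNames(rep("species", nrow(sp)), sp$taxid),
               stats::setNames(rep("genus", nrow(ge)), ge$taxid))
  structure(list(accession_to_taxid = acc2tax,
                 taxid_to_name = taxid_to_name,
                 taxid_to_parent = taxid_to_parent,
                 rank_of = rank_of),
            class = "taxonomy_map")
}

#' Load reference sequences and their taxonomy
#'
#' Reads a multi-record reference FASTA and its accompanying tab-separated
#' metadata. Sequences are uppercased and any character outside ACGT is
#' normalized to N. FASTA record ids are truncated at the first whitespace.
#'
#' @param fasta_path path to the reference FASTA.
#' @param metadata_path path to the tab-separated metadata file (columns
#'   `accession`, `taxid`, `species_name`, `genus_taxid`, `genus_name`).
#' @return list with `sequences` (a named [Biostrings::DNAStringSet]) and
#'   `taxonomy` (a [taxonomy_map()]).
#' @export
load_references <- function(fasta_path, metadata_path) {
  raw <- Biostrings::readBStringSet(fasta_path)
  if (length(raw) == 0L) stop("empty FASTA: ", fasta_path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate accession in FASTA: ", ids[duplicated(ids)][1L])
  }
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  taxonomy <- taxonomy_map(metadata)
  absent <- setdiff(ids, names(taxonomy$accession_to_taxid))
  if (length(absent) > 0L) {
    stop("no metadata row for accession(s): ", paste(absent, collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(normalize_dna(as.character(raw)))
  names(seqs) <- ids
  list(sequences = seqs, taxonomy = taxonomy)
}

#' Resolve the genus of a species taxid
#'
#' Walks parent links upward until a node of rank "genus" is found.
#' Vectorized over `species_taxid`.
#'
#' @param taxonomy a [taxonomy_map()].
#' @param species_taxid integer vector of taxids present in the map.
#' @return integer vector of genus taxids.
#' @export
genus_of <- function(taxonomy, species_taxid) {
  one <- function(tid) {
    cur <- as.character(tid)
    if (!cur %in% names(taxonomy$rank_of)) {
      stop("unknown taxid: ", tid)
    }
    for (i in seq_len(length(taxonomy$rank_of) + 1L)) {
      if (identical(taxonomy$rank_of[[cur]], "genus")) {
        return(as.integer(cur))
      }
      parent <- taxonomy$taxid_to_parent[[cur]]
      if (is.na(parent)) {
        stop("taxid ", tid, " has no genus ancestor")
      }
      cur <- as.character(parent)
      if (!cur %in% names(taxonomy$rank_of)) {
        stop("broken parent link above taxid ", tid)
      }
    }
    stop("cycle detected in parent links above taxid ", tid)
  }
  vapply(species_taxid, one, integer(1L))
}

#' Partition a reference collection into indexable chunks
#'
#' Sequences are assigned to chunks greedily in input order: a new chunk is
#' opened whenever adding the next sequence would exceed `max_chunk_bases`.
#' A single sequence larger than the limit occupies a chunk of its own.
#' Chunks therefore partition the collection: concatenating their members in
#' chunk order reproduces the input exactly.
#'
#' @param sequences a named [Biostrings::DNAStringSet].
#' @param max_chunk_bases positive integer, target maximum bases per chunk.
#' @return list of `reference_chunk` objects with fields `chunk_id`
#'   (consecutive from 0), `sequences`, `total_bases`.
#' @export
partition_references <- function(sequences, max_chunk_bases) {
  stopifnot(max_chunk_bases > 0)
  if (length(sequences) == 0L) stop("no sequences to partition")
  widths <- Biostrings::width(sequences)
  groups <- integer(length(sequences))
  cur <- 0L
  acc <- 0
  for (i in seq_along(sequences)) {
    if (acc > 0 && acc + widths[i] > max_chunk_bases) {
      cur <- cur + 1L
      acc <- 0
    }
    groups[i] <- cur
    acc <- acc + widths[i]
  }
  lapply(unique(groups), function(g) {
    reference_chunk(g, sequences[groups == g])
  })
}

#' @rdname partition_references
#' @param chunk_id integer chunk identifier (0-based).
#' @export
reference_chunk <- function(chunk_id, sequences) {
  stopifnot(length(sequences) > 0L)
  structure(list(chunk_id = as.integer(chunk_id),
                 sequences = sequences,
                 total_bases = sum(Biostrings::width(sequences))),
            class = "reference_chunk")
}

#' Write a chunk membership manifest
#'
#' @param chunks list of `reference_chunk` objects.
#' @param path output TSV path (columns `chunk_id`, `accession`).
#' @return the path, invisibly.
#' @export
write_chunk_manifest <- function(chunks, path) {
  rows <- do.call(rbind, lapply(chunks, function(ch) {
    data.frame(chunk_id = ch$chunk_id, accession = names(ch$sequences),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
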
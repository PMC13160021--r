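# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (sliding-window scans, quadratic DP,
# linear scans) and never call the code paths they check.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Naive per-member substring search: every occurrence of pattern in each
# member sequence, as (accession, 0-based offset). Patterns containing N
# never match (same rule the index applies).
naive_locate <- function(sequences, pattern) {
  if (grepl("N", pattern, fixed = TRUE)) {
    return(data.frame(accession = character(0), offset = integer(0)))
  }
  rows <- lapply(names(sequences), function(acc) {
    hits <- Biostrings::matchPattern(pattern,
                                     Biostrings::DNAString(
                                       as.character(sequences[[acc]])))
    data.frame(accession = rep(acc, length(hits)),
               offset = BiocGenerics::start(hits) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$accession, out$offset), , drop = FALSE]
}

# Quadratic semi-global edit distance oracle (full read, free end gaps on
# the window), distance only, vectorized by DP row.
oracle_semiglobal_dist <- function(read, window) {
  r <- strsplit(read, "")[[1]]
  w <- strsplit(window, "")[[1]]
  m <- length(r); n <- length(w)
  prev <- rep(0L, n + 1L)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    cur[1L] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j] + (r[i] != w[j]),
                         prev[j + 1L] + 1L,
                         cur[j] + 1L)
    }
    prev <- cur
  }
  min(prev)
}

# Plain Levenshtein (global) oracle via adist for cross-checks.
oracle_levenshtein <- function(a, b) as.integer(utils::adist(a, b))

make_chunk <- function(seqs) {
  reference_chunk(0L, Biostrings::DNAStringSet(seqs))
}

# Minimal taxonomy over explicit accession/taxid/genus triples.
make_taxonomy <- function(accession, taxid,
                          genus_taxid = taxid + 100000L) {
  taxonomy_map(data.frame(accession = accession, taxid = taxid,
                          species_name = paste0("sp", taxid),
                          genus_taxid = genus_taxid,
                          genus_name = paste0("g", genus_taxid),
                          stringsAsFactors = FALSE))
}

# Reads sampled uniformly from a set of genome strings, exact copies,
# forward strand; returns named character vector.
exact_reads_from <- function(seqs, n, read_length, seed) {
  withr::with_seed(seed, {
    src <- sample(seq_along(seqs), n, replace = TRUE)
    starts <- vapply(src, function(i) {
      sample.int(nchar(seqs[[i]]) - read_length + 1L, 1L)
    }, integer(1L))
    reads <- substring(unlist(seqs)[src], starts, starts + read_length - 1L)
    stats::setNames(reads, sprintf("r%04d", seq_len(n)))
  })
}

# A tiny annotated community used by gene/quantify tests; cached per run.
tiny_pipeline_fixture <- function(n_reads = 400L, sub_rate = 0,
                                  seed = 7L) {
  comm <- simulate_community(n_species = 4L, genome_length = 20000L,
                             n_genes = 10L, sister_divergence = 0.15,
                             seed = seed)
  prof <- community_profile(comm$taxids, sigma = 0.5, seed = seed + 1L)
  sim <- simulate_reads(comm$genomes, prof, n_reads, 150L,
                        sub_rate = sub_rate, seed = seed + 2L)
  dir <- tempfile("fixture")
  paths <- write_truth_and_annotations(comm$genomes, dir,
                                       genus_map = comm$genus_map,
                                       alias_diverged_ogs = TRUE,
                                       profile = prof)
  refs <- load_references(paths$ref_fasta, paths$metadata)
  list(community = comm, profile = prof, sim = sim, paths = paths,
       refs = refs)
}
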
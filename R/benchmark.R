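#' Run the end-to-end accuracy benchmark
#'
#' Simulates a synthetic community, builds the chunked index, assigns every
#' read through the full seeding + alignment pipeline, merges per-chunk
#' reports, and scores the result against the simulation truth. This is the
#' package's self-contained accuracy experiment: the default configuration
#' is 20 well-separated species (ten ancestor/sister pairs at 10%
#' divergence, 100 kb genomes, 50 CDSs each) and 50,000 150 bp single-end
#' reads carrying 0.5% substitutions, assigned with the default seeding
#' parameters and edit-distance threshold.
#'
#' @param seed integer seed driving every random draw.
#' @param n_species,genome_length,n_genes,sister_divergence,paired see
#'   [simulate_community()].
#' @param n_reads,read_length,sub_rate see [simulate_reads()].
#' @param sigma abundance spread, see [community_profile()].
#' @param n_chunks number of index chunks the reference is split into
#'   (exercises the merge path; results are chunking-invariant).
#' @param params a [seeding_params()].
#' @param max_edits maximum accepted edit distance.
#' @return list with `accuracy` (an `accuracy_report`), `report` (merged
#'   assignments), `truth`, `community`, and `profile`.
#' @export
run_accuracy_benchmark <- function(seed, n_species = 20L,
                                   genome_length = 100000L, n_genes = 50L,
                                   sister_divergence = 0.10, paired = TRUE,
                                   n_reads = 50000L, read_length = 150L,
                                   sub_rate = 0.005, sigma = 1,
                                   n_chunks = 2L,
                                   params = seeding_params(),
                                   max_edits = 7L) {
  seed <- as.integer(seed) %% 1000000L
  community <- simulate_community(n_species, genome_length, n_genes,
                                  sister_divergence, paired, seed = seed)
  profile <- community_profile(community$taxids, sigma = sigma,
                               seed = seed + 1L)
  sim <- simulate_reads(community$genomes, profile, n_reads, read_length,
                        sub_rate = sub_rate, seed = seed + 2L)

  seqs <- Biostrings::DNAStringSet(vapply(community$genomes,
                                          function(g) g$sequence,
                                          character(1L)))
  names(seqs) <- vapply(community$genomes, function(g) g$accession,
                        character(1L))
  taxonomy <- taxonomy_map(data.frame(
    accession = names(seqs),
    taxid = community$taxids,
    species_name = sprintf("species_%d", community$taxids),
    genus_taxid = community$genus_map$genus_taxid[
      match(community$taxids, community$genus_map$taxid)],
    genus_name = community$genus_map$genus_name[
      match(community$taxids, community$genus_map$taxid)],
    stringsAsFactors = FALSE))

  chunk_bases <- ceiling(sum(Biostrings::width(seqs)) / n_chunks)
  chunks <- partition_references(seqs, chunk_bases)
  reports <- lapply(chunks, function(ch) {
    assign_reads(sim$reads, build_fm_index(ch), taxonomy, params, max_edits)
  })
  merged <- merge_reports(reports)
  accuracy <- evaluate_assignments(sim$truth, merged,
                                   expected_taxa = community$taxids)
  list(accuracy = accuracy, report = merged, truth = sim$truth,
       community = community, profile = profile)
}
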
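# taxalign

Joint taxonomic and gene assignment for metatranscriptomic reads.

Metatranscriptomic workflows typically split read classification from
functional profiling: k-mer classifiers resolve *who* is active but discard
genomic coordinates, while translated-protein searches resolve *what* is
expressed but collapse the nucleotide variation that separates closely
related species. `taxalign` is a nucleotide full-alignment engine that does
both in a single pass: each read is assigned to a species **and** to the
gene its alignment overlaps, so expression can be attributed to individual
organisms instead of being averaged across a genus.

The package is aimed at microbiome researchers analysing bacterial
community RNA-seq against a curated reference collection, and at method
developers who need a transparent, fully testable implementation of
seed-and-extend read classification with per-read truth labels.

## Method

1. **Chunked FM-index.** Reference genomes are partitioned into chunks of
   configurable size, each indexed independently (Burrows–Wheeler
   transform, checkpointed rank structure, suffix array — full or
   row-sampled). Chunking bounds memory and allows incremental database
   updates; the merge contract guarantees results identical to a
   single-chunk run.
2. **Seeding.** Each read is decomposed into fixed-length seeds (default
   18-mers every 9 bases, both strands). Exact seed hits are clustered by
   alignment diagonal; clusters with at least `min_seed_hits` seeds become
   candidate regions, evaluated in descending seed-support order.
3. **Threshold-bounded alignment.** Candidates are verified by semi-global
   alignment under unit-cost edit distance *d*(read, window): the full
   read must align, end gaps on the reference window are free, and a hit
   is accepted iff *d* ≤ `max_edits` (default 7 ≈ 5% of a 150 bp read).
   Once a taxon has one passing alignment the remaining candidates for
   that taxon are skipped (taxon-aware early stop) — the hit *set* is
   provably unchanged, only redundant work is avoided.
4. **Gene assignment.** The retained alignment coordinates are queried
   against interval-indexed GFF3 CDS features; the primary gene is the
   maximum-overlap feature, and the matching protein sequences can be
   exported for downstream ortholog annotation.
5. **Quantification.** Per-sample gene assignments are aggregated into a
   (taxon × gene) count matrix, collapsed to ortholog groups via a
   supplied mapping, optionally rolled up from species to genus, and
   filtered with the low-abundance rule (keep a row only if ≥ 5 reads in
   ≥ 3 samples per group) before export to differential-expression tools.

A synthetic-community simulator (annotated genomes, log-normal abundance
profiles, mutated reads with per-read truth records) provides the fixture
engine for every accuracy claim the package makes.

## Worked example

```r
library(taxalign)

community <- simulate_community(n_species = 4, genome_length = 20000,
                                n_genes = 10, sister_divergence = 0.10,
                                seed = 42)
profile <- community_profile(community$taxids, sigma = 1, seed = 43)
sim <- simulate_reads(community$genomes, profile, n_reads = 2000,
                      read_length = 150, sub_rate = 0.005, seed = 44)
out <- write_truth_and_annotations(community$genomes, tempdir(),
                                   genus_map = community$genus_map,
                                   alias_diverged_ogs = TRUE)

refs <- load_references(out$ref_fasta, out$metadata)
chunks <- partition_references(refs$sequences, max_chunk_bases = 50000)
reports <- lapply(chunks, function(ch)
  assign_reads(sim$reads, build_fm_index(ch), refs$taxonomy))
merged <- merge_reports(reports)
head(merged, 3)
#>        read_id taxid  accession ref_start ref_end  strand edit_distance status
#> 1 read_0000001  1001  SYN001001      5242    5392 forward             0 unique
#> 2 read_0000002  1004 SYN001004D     13399   13549 reverse             1 unique
#> 3 read_0000003  1001  SYN001001     16746   16896 reverse             0 unique
```

Each row is one passing alignment: the species (`taxid`), the genome and
0-based half-open span it aligned to, the strand, and the edit distance.
`status` records whether the read resolved to a single species.

```r
evaluate_assignments(sim$truth, merged, expected_taxa = community$taxids)
#> accuracy over 2000 reads:
#>   assigned:        100.000%
#>   correct:         100.000%
#>   unique species:  99.450%
#>   unexpected species: 0 (0 reads exclusively)
```

With four species arranged as two 10%-diverged sister pairs, every read is
assigned, every hit set contains the true source species, and 99.45% of
reads resolve unambiguously — the remainder land in conserved stretches
shared by a sister pair and are reported as multi-taxon.

```r
genes <- assign_genes_report(merged, build_gene_index(parse_gff(out$gff)))
cm <- aggregate_counts(list(sample1 = genes))
og <- collapse_to_og(cm, read.delim(out$og_map))
og
#> count_matrix [species_OG]: 40 rows x 1 samples, total 1989 counts
collapse_to_genus(og, refs$taxonomy)
#> count_matrix [genus_OG]: 20 rows x 1 samples, total 1989 counts
```

Counting is conservative: multi-taxon reads are excluded by default, and
column totals are conserved through the ortholog-group and genus
roll-ups (40 species×OG rows collapse to 20 genus×OG rows here because
each sister pair shares a genus and its gene families).

A command-line front-end over the same functions ships in
`inst/cli/taxalign.R` with subcommands `index`, `assign`, `genes`,
`quantify`, `simulate`, and `evaluate`.

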
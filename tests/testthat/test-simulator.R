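test_that("genome generation is deterministic with GC on target", {
  g1 <- generate_genome(5L, 10000L, 10L, seed = 1L)
  g2 <- generate_genome(5L, 10000L, 10L, seed = 1L)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  expect_false(identical(g1$sequence,
                         generate_genome(5L, 10000L, 10L, seed = 2L)$sequence))

  # empirical GC within a binomial bound at 100 kb
  g <- generate_genome(6L, 100000L, 0L, gc_fraction = 0.5, seed = 3L)
  gc <- sum(strsplit(g$sequence, "")[[1L]] %in% c("G", "C")) / 100000
  expect_gt(gc, 0.48); expect_lt(gc, 0.52)
  expect_equal(nrow(g$features), 0L)

  # features are in-bounds, disjoint, multiples of 3, >= 150 bp
  gf <- generate_genome(7L, 50000L, 40L, seed = 4L)$features
  expect_true(all(gf$start >= 0L & gf$end <= 50000L))
  len <- gf$end - gf$start
  expect_true(all(len %% 3L == 0L & len >= 150L))
  expect_true(all(gf$start[-1L] >= gf$end[-nrow(gf)]))  # sorted + disjoint

  # impossible density errors
  expect_error(generate_genome(8L, 3000L, 11L), "density")
})

test_that("divergence applies the requested substitution load", {
  g <- generate_genome(9L, 100000L, 5L, seed = 10L)
  same <- diverge_genome(g, 0, 91L, seed = 11L)
  expect_identical(same$sequence, g$sequence)
  expect_identical(diverge_genome(g, 0.1, 91L, seed = 12L)$sequence,
                   diverge_genome(g, 0.1, 91L, seed = 12L)$sequence)
  div <- diverge_genome(g, 0.1, 91L, seed = 12L)
  hd <- sum(strsplit(g$sequence, "")[[1L]] !=
              strsplit(div$sequence, "")[[1L]]) / 100000
  expect_gt(hd, 0.09); expect_lt(hd, 0.11)
  # features inherited at identical coordinates, ids re-prefixed
  expect_equal(div$features$start, g$features$start)
  expect_equal(div$features$end, g$features$end)
  expect_false(any(div$features$feature_id %in% g$features$feature_id))
  expect_identical(div$og_seed, g$og_seed)
})

test_that("community profiles are positive and normalized", {
  p <- community_profile(1:20, sigma = 1, seed = 5L)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_identical(p, community_profile(1:20, sigma = 1, seed = 5L))
})

test_that("read simulation respects the abundance profile and truth labels", {
  genomes <- list(generate_genome(1L, 30000L, 20L, seed = 20L),
                  generate_genome(2L, 30000L, 20L, seed = 21L))
  # single-taxon profile: every read from taxon 1
  sim1 <- simulate_reads(genomes, c("1" = 1.0), 500L, seed = 22L)
  expect_true(all(sim1$truth$true_taxid == 1L))
  expect_true(all(Biostrings::width(sim1$reads) == 150L))

  # 90/10 profile: taxon-1 fraction within 3 binomial s.e. of 0.9
  sim2 <- simulate_reads(genomes, c("1" = 0.9, "2" = 0.1), 20000L,
                         seed = 23L)
  frac <- mean(sim2$truth$true_taxid == 1L)
  se <- sqrt(0.9 * 0.1 / 20000)
  expect_lt(abs(frac - 0.9), 3 * se)

  # a profile taxon with no genome is an error
  expect_error(simulate_reads(genomes, c("9" = 1.0), 10L, seed = 1L),
               "without a genome")
})

test_that("clean reads are exact substrings of their source features", {
  g <- generate_genome(3L, 30000L, 15L, seed = 30L)
  sim <- simulate_reads(list(g), c("3" = 1.0), 300L, sub_rate = 0,
                        indel_rate = 0, seed = 31L)
  expect_true(all(sim$truth$n_subs == 0L & sim$truth$n_indels == 0L))
  for (i in seq_len(50L)) {
    tr <- sim$truth[i, ]
    span <- substring(g$sequence, tr$true_start + 1L, tr$true_end)
    if (tr$strand == "-") {
      span <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(span)))
    }
    expect_identical(as.character(sim$reads[[i]]), span)
    # the source span lies inside the recorded feature
    f <- g$features[g$features$feature_id == tr$true_feature_id, ]
    expect_gte(tr$true_start, f$start)
    expect_lte(tr$true_end, f$end)
  }
})

test_that("recorded mutations reconstruct every read exactly", {
  g <- generate_genome(4L, 30000L, 15L, seed = 40L)
  for (rates in list(c(0.02, 0), c(0.01, 0.005))) {
    sim <- simulate_reads(list(g), c("4" = 1.0), 150L,
                          sub_rate = rates[1L], indel_rate = rates[2L],
                          seed = 41L)
    rebuilt <- mapply(reconstruct_read, sim$truth$src_window,
                      sim$truth$mutations, MoreArgs = list(read_length = 150L))
    expect_identical(unname(rebuilt), unname(as.character(sim$reads)))
    if (rates[2L] == 0) {
      expect_true(any(sim$truth$n_subs > 0L))
      expect_true(all(sim$truth$n_indels == 0L))
    } else {
      expect_true(any(sim$truth$n_indels > 0L))
    }
  }
})

test_that("annotation export round-trips and aliases diverged OGs", {
  comm <- simulate_community(n_species = 4L, genome_length = 15000L,
                             n_genes = 8L, seed = 50L)
  dir <- tempfile()
  paths <- write_truth_and_annotations(comm$genomes, dir,
                                       genus_map = comm$genus_map,
                                       alias_diverged_ogs = TRUE)
  # reference + GFF round-trip through the package's own parsers
  refs <- load_references(paths$ref_fasta, paths$metadata)
  expect_equal(as.character(refs$sequences),
               vapply(comm$genomes, function(g) g$sequence, ""),
               ignore_attr = TRUE)
  feats <- parse_gff(paths$gff)
  all_feats <- do.call(rbind, lapply(comm$genomes, function(g) g$features))
  expect_equal(feats[, c("feature_id", "accession", "start", "end", "strand")],
               all_feats[, c("feature_id", "accession", "start", "end",
                             "strand")],
               ignore_attr = TRUE)

  # proteins: translated CDS length, trailing stop trimmed
  aa <- Biostrings::readAAStringSet(paths$proteins)
  g1 <- comm$genomes[[1L]]
  f1 <- g1$features[1L, ]
  cds <- substring(g1$sequence, f1$start + 1L, f1$end)
  if (f1$strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds)))
  }
  aa1 <- as.character(aa[[f1$protein_id]])
  want <- sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(cds))))
  expect_identical(aa1, want)

  # diverged sister genomes share OG ids with their ancestors
  og <- read.delim(paths$og_map)
  anc <- comm$genomes[[1L]]; sis <- comm$genomes[[2L]]
  og_anc <- og$og_id[match(anc$features$feature_id, og$feature_id)]
  og_sis <- og$og_id[match(sis$features$feature_id, og$feature_id)]
  expect_identical(og_anc, og_sis)
  # without aliasing every feature is its own OG
  paths2 <- write_truth_and_annotations(comm$genomes, tempfile())
  og2 <- read.delim(paths2$og_map)
  expect_equal(anyDuplicated(og2$og_id), 0L)
})

test_that("accuracy metrics match constructed outcomes", {
  truth <- data.frame(read_id = sprintf("r%02d", 1:10),
                      true_taxid = rep(c(1L, 2L), 5L),
                      stringsAsFactors = FALSE)
  hit <- function(rid, tax) {
    data.frame(read_id = rid, taxid = tax, accession = "a", ref_start = 0L,
               ref_end = 150L, strand = "forward", edit_distance = 0L,
               status = "unique", stringsAsFactors = FALSE)
  }
  # perfect single-hit assignments
  perfect <- do.call(rbind, mapply(hit, truth$read_id, truth$true_taxid,
                                   SIMPLIFY = FALSE))
  acc <- evaluate_assignments(truth, perfect, expected_taxa = c(1L, 2L))
  expect_equal(acc$fraction_assigned, 1)
  expect_equal(acc$fraction_correct, 1)
  expect_equal(acc$fraction_unique_species, 1)
  expect_equal(acc$unexpected_species_count, 0L)
  expect_equal(acc$reads_to_unexpected, 0L)

  # nothing assigned: undefined ratios are NA
  none <- evaluate_assignments(truth, perfect[0L, ], c(1L, 2L))
  expect_equal(none$fraction_assigned, 0)
  expect_true(is.na(none$fraction_correct))
  expect_true(is.na(none$fraction_unique_species))

  # corrupt k of n assignments: fraction_correct == (n - k)/n
  withr::with_seed(61, {
    for (k in c(1L, 3L, 5L)) {
      bad <- perfect
      flip <- sample(nrow(bad), k)
      bad$taxid[flip] <- 99L  # unexpected wrong taxon
      a <- evaluate_assignments(truth, bad, c(1L, 2L))
      expect_equal(a$fraction_correct, (10 - k) / 10)
      expect_equal(a$unexpected_species_count, 1L)
      expect_equal(a$reads_to_unexpected, k)
    }
  })

  # assignment ids missing from truth are an error
  stray <- hit("zz", 1L)
  expect_error(evaluate_assignments(truth, stray, 1:2), "absent from truth")
})

test_that("a clean mid-size community is assigned perfectly end to end", {
  comm <- simulate_community(n_species = 6L, genome_length = 30000L,
                             n_genes = 15L, seed = 70L)
  prof <- community_profile(comm$taxids, sigma = 1, seed = 71L)
  sim <- simulate_reads(comm$genomes, prof, 2000L, sub_rate = 0, seed = 72L)
  dir <- tempfile()
  paths <- write_truth_and_annotations(comm$genomes, dir,
                                       genus_map = comm$genus_map)
  refs <- load_references(paths$ref_fasta, paths$metadata)
  idx <- build_fm_index(reference_chunk(0L, refs$sequences))
  rep <- merge_reports(list(assign_reads(sim$reads, idx, refs$taxonomy)))
  acc <- evaluate_assignments(sim$truth, rep, comm$taxids)
  expect_equal(acc$fraction_assigned, 1)
  expect_equal(acc$fraction_correct, 1)
})
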
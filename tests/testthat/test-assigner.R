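test_that("seed schedule tiles the read with a final flush seed", {
  p <- seeding_params(seed_length = 18L, seed_interval = 9L)
  read <- random_dna(150L, seed = 1L)
  seeds <- extract_seeds(read, p)
  fwd <- seeds[seeds$strand == "forward", ]
  expect_equal(fwd$read_offset, c(seq(0L, 126L, by = 9L), 132L))
  expect_equal(nrow(fwd), 16L)
  expect_equal(fwd$seed,
               substring(read, fwd$read_offset + 1L, fwd$read_offset + 18L))
  # reverse-strand seeds follow the same schedule on the reverse complement
  rev <- seeds[seeds$strand == "reverse", ]
  expect_equal(rev$read_offset, fwd$read_offset)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  expect_equal(rev$seed, substring(rc, rev$read_offset + 1L,
                                   rev$read_offset + 18L))

  # a read exactly one seed long yields one seed per strand
  one <- extract_seeds(random_dna(18L, seed = 2L), p)
  expect_equal(nrow(one), 2L)
  expect_setequal(one$strand, c("forward", "reverse"))

  # N exclusion and short reads
  expect_equal(nrow(extract_seeds(strrep("N", 150L), p)), 0L)
  expect_equal(nrow(extract_seeds("ACGT", p)), 0L)
})

test_that("candidate clustering groups diagonals and orders deterministically", {
  tax <- make_taxonomy(c("accA", "accB"), c(1L, 2L))
  p <- seeding_params(min_seed_hits = 2L, diagonal_tolerance = 5L)
  # three seeds on one diagonal: one region with support 3
  m <- data.frame(read_offset = c(0L, 9L, 18L), accession = "accA",
                  ref_offset = c(100L, 109L, 118L), strand = "forward")
  cand <- collect_candidates(m, tax, p)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$support, 3L)
  expect_equal(cand$projected_start, 100L)

  # diagonals {100, 103, 250}: clusters of support 2 and 1; only the first
  # survives min_seed_hits = 2
  m2 <- data.frame(read_offset = c(0L, 9L, 0L), accession = "accA",
                   ref_offset = c(100L, 112L, 250L), strand = "forward")
  cand2 <- collect_candidates(m2, tax, p)
  expect_equal(nrow(cand2), 1L)
  expect_equal(cand2$support, 2L)

  # equal support on two accessions: tie broken by taxid then accession
  m3 <- rbind(
    data.frame(read_offset = c(0L, 9L), accession = "accB",
               ref_offset = c(50L, 59L), strand = "forward"),
    data.frame(read_offset = c(0L, 9L), accession = "accA",
               ref_offset = c(70L, 79L), strand = "forward"))
  cand3 <- collect_candidates(m3, tax, p)
  expect_equal(cand3$accession, c("accA", "accB"))
  expect_equal(cand3$taxid, c(1L, 2L))
})

test_that("alignment kernel matches hand-computed and oracle distances", {
  # identical read and window slice
  res <- align_candidate("ACGTACGT", "ACGTACGT", 2L)
  expect_equal(res$edit_distance, 0L)
  expect_equal(c(res$start, res$end), c(0L, 8L))

  # one substitution
  res1 <- align_candidate("ACGTACGT", "ACGAACGT", 1L)
  expect_equal(res1$edit_distance, 1L)
  # over threshold: no result
  expect_null(align_candidate("ACGTACGT", "TTTTTTTT", 3L))
  # empty window: no result
  expect_null(align_candidate("ACGT", "", 3L))

  # free end gaps: read inside a larger window costs nothing extra
  win <- paste0("GGGGG", "ACGTACGT", "CCCCC")
  resw <- align_candidate("ACGTACGT", win, 0L)
  expect_equal(resw$edit_distance, 0L)
  expect_equal(c(resw$start, resw$end), c(5L, 13L))
})

test_that("alignment kernel equals the quadratic DP oracle on random pairs", {
  withr::with_seed(17, {
    for (trial in seq_len(500L)) {
      L <- sample(20:60, 1L)
      read <- random_dna(L)
      if (trial %% 3L == 0L) {
        # unrelated window
        window <- random_dna(L + sample(0:20, 1L))
      } else {
        # window containing a mutated copy of the read
        k <- sample(0:5, 1L)
        chars <- strsplit(read, "")[[1L]]
        if (k > 0L) {
          pos <- sample(L, k)
          bases <- c("A", "C", "G", "T")
          chars[pos] <- bases[(match(chars[pos], bases) - 1L +
                                 sample(3L, k, TRUE)) %% 4L + 1L]
        }
        window <- paste0(random_dna(sample(0:10, 1L)),
                         paste(chars, collapse = ""),
                         random_dna(sample(0:10, 1L)))
        planted_k <- k
      }
      got <- align_semiglobal_cpp(taxalign:::encode_dna(read),
                                  taxalign:::encode_dna(window))
      want <- oracle_semiglobal_dist(read, window)
      expect_equal(got[1L], want)
      if (trial %% 3L != 0L) expect_lte(got[1L], planted_k)
    }
  })
})

# -- fixtures for read-level assignment ---------------------------------------

make_assign_fixture <- function(seed = 101L) {
  withr::with_seed(seed, {
    gA <- random_dna(4000L)
    gB <- random_dna(4000L)
    shared <- random_dna(600L)  # identical gene present in both taxa
    seqs <- c(A1 = paste0(gA, shared), B1 = paste0(gB, shared))
  })
  tax <- make_taxonomy(c("A1", "B1"), c(10L, 20L))
  idx <- build_fm_index(make_chunk(seqs))
  list(seqs = seqs, tax = tax, idx = idx)
}

test_that("assign_read finds unique and shared-region hits", {
  fx <- make_assign_fixture()
  # read from a region unique to taxon A
  readA <- substring(fx$seqs[["A1"]], 1001L, 1150L)
  ra <- assign_read(readA, fx$idx, fx$tax)
  expect_equal(ra$status, "unique")
  expect_equal(ra$hits$taxid, 10L)
  expect_equal(ra$hits$ref_start, 1000L)
  expect_equal(ra$hits$ref_end, 1150L)
  expect_equal(ra$hits$edit_distance, 0L)

  # read from the gene shared by both taxa: multi-taxon pre-resolution
  readS <- substring(fx$seqs[["A1"]], 4101L, 4250L)
  rs <- assign_read(readS, fx$idx, fx$tax)
  expect_equal(rs$status, "multi_taxon")
  expect_setequal(rs$hits$taxid, c(10L, 20L))

  # garbage read: unassigned
  ru <- assign_read(strrep("AC", 75L), fx$idx, fx$tax)
  expect_equal(ru$status, "unassigned")
  expect_equal(nrow(ru$hits), 0L)
})

test_that("reverse-complemented reads hit the same loci with strand flipped", {
  fx <- make_assign_fixture(202L)
  withr::with_seed(7, {
    reads <- exact_reads_from(as.list(fx$seqs), 60L, 150L, seed = 8L)
  })
  fwd <- assign_reads(reads, fx$idx, fx$tax)
  rc <- stats::setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads))), names(reads))
  rev <- assign_reads(rc, fx$idx, fx$tax)
  key <- function(d) d[order(d$read_id, d$taxid, d$accession),
                       c("read_id", "taxid", "accession", "ref_start",
                         "ref_end", "edit_distance")]
  expect_equal(key(fwd), key(rev), ignore_attr = TRUE)
  flip <- c(forward = "reverse", reverse = "forward")
  a <- fwd[order(fwd$read_id, fwd$taxid, fwd$accession), ]
  b <- rev[order(rev$read_id, rev$taxid, rev$accession), ]
  expect_equal(unname(flip[a$strand]), b$strand)
})

test_that("per-taxon early stop records one alignment and preserves hit sets", {
  # three genomes of one taxon sharing a region; plus one other taxon
  withr::with_seed(55, {
    core <- random_dna(2000L)
    seqs <- c(T1a = paste0(random_dna(500L), core),
              T1b = paste0(random_dna(800L), core),
              T1c = paste0(core, random_dna(400L)),
              T2a = random_dna(2500L))
  })
  tax <- make_taxonomy(c("T1a", "T1b", "T1c", "T2a"),
                       c(100L, 100L, 100L, 200L))
  idx <- build_fm_index(make_chunk(seqs))
  withr::with_seed(56, {
    starts <- sample.int(nchar(core) - 150L, 80L)
    reads <- stats::setNames(substring(core, starts, starts + 149L),
                             sprintf("c%03d", seq_len(80L)))
  })
  early <- assign_reads(reads, idx, tax, early_stop = TRUE)
  exhaustive <- assign_reads(reads, idx, tax, early_stop = FALSE)

  # at most one accepted alignment per (read, taxid) under early stop
  expect_equal(max(table(paste(early$read_id, early$taxid))), 1L)
  # the exhaustive variant aligns strictly more candidates
  expect_gt(attr(exhaustive, "align_calls"), attr(early, "align_calls"))
  # ... but the per-read taxid sets agree
  tax_sets <- function(d) lapply(split(d$taxid, d$read_id),
                                 function(x) sort(unique(x)))
  expect_equal(tax_sets(early), tax_sets(exhaustive))
})

test_that("raising max_edits or lowering min_seed_hits never shrinks hit sets", {
  fx <- tiny_pipeline_fixture(n_reads = 150L, sub_rate = 0.01, seed = 31L)
  chunk <- reference_chunk(0L, fx$refs$sequences)
  idx <- build_fm_index(chunk)
  hit_count <- function(max_edits, min_hits) {
    rep <- assign_reads(fx$sim$reads, idx, fx$refs$taxonomy,
                        seeding_params(min_seed_hits = min_hits),
                        max_edits = max_edits)
    nrow(rep)
  }
  h_me <- vapply(c(2L, 5L, 8L), hit_count, integer(1L), min_hits = 2L)
  expect_true(all(diff(h_me) >= 0L))
  h_sh <- vapply(c(1L, 3L, 6L), hit_count, integer(1L), max_edits = 7L)
  expect_true(all(diff(h_sh) <= 0L))
})

test_that("merge_reports unions chunks, keeps best duplicates, dedupes", {
  r1 <- data.frame(read_id = "r1", taxid = 1L, accession = "a",
                   ref_start = 10L, ref_end = 160L, strand = "forward",
                   edit_distance = 2L, status = "unique",
                   stringsAsFactors = FALSE)
  r2 <- data.frame(read_id = "r1", taxid = c(1L, 2L), accession = c("a2", "b"),
                   ref_start = c(5L, 7L), ref_end = c(155L, 157L),
                   strand = "forward", edit_distance = c(1L, 3L),
                   status = "multi_taxon", stringsAsFactors = FALSE)
  m <- merge_reports(list(r1, r2))
  expect_equal(nrow(m), 2L)
  # taxid 1 keeps the distance-1 hit from chunk 2
  expect_equal(m$edit_distance[m$taxid == 1L], 1L)
  expect_equal(m$accession[m$taxid == 1L], "a2")
  expect_equal(unique(m$status), "multi_taxon")
  # exact duplicate rows collapse silently
  dup <- merge_reports(list(r1, r1))
  expect_equal(nrow(dup), 1L)
})

test_that("assignments are invariant to how the reference is chunked", {
  fx <- tiny_pipeline_fixture(n_reads = 300L, sub_rate = 0.005, seed = 63L)
  tax <- fx$refs$taxonomy
  whole <- assign_reads(fx$sim$reads,
                        build_fm_index(reference_chunk(0L, fx$refs$sequences)),
                        tax)
  whole <- merge_reports(list(whole))
  for (limit in c(25000, 45000)) {
    chunks <- partition_references(fx$refs$sequences, limit)
    expect_gt(length(chunks), 1L)
    reps <- lapply(chunks, function(ch) {
      assign_reads(fx$sim$reads, build_fm_index(ch), tax)
    })
    merged <- merge_reports(reps)
    expect_equal(merged, whole, ignore_attr = TRUE)
  }
})

test_that("ambiguity resolution filters by edit slack and taxon support", {
  mk <- function(read_id, taxid, edit) {
    data.frame(read_id = read_id, taxid = taxid,
               accession = paste0("acc", taxid), ref_start = 0L,
               ref_end = 150L, strand = "forward", edit_distance = edit,
               status = "multi_taxon", stringsAsFactors = FALSE)
  }
  # slack 0 keeps only the best hit
  rep1 <- rbind(mk("r1", 1L, 1L), mk("r1", 2L, 3L))
  res1 <- resolve_ambiguity(rep1, edit_slack = 0)
  expect_equal(res1$taxid, 1L)
  expect_equal(res1$status, "unique")

  # slack Inf and threshold 0 is the identity transform
  res_id <- resolve_ambiguity(rep1, edit_slack = Inf,
                              min_taxon_read_fraction = 0)
  expect_equal(res_id[, names(rep1)], rep1, ignore_attr = TRUE)

  # a taxon present in 1 of 1000 reads is removed where alternatives exist
  bulk <- do.call(rbind, lapply(sprintf("b%04d", 1:999), mk,
                                taxid = 1L, edit = 0L))
  rare <- rbind(mk("b0001", 99L, 0L))   # read b0001 also hits rare taxon
  rep2 <- rbind(bulk, rare)
  res2 <- resolve_ambiguity(rep2, edit_slack = Inf,
                            min_taxon_read_fraction = 1e-2)
  expect_false(99L %in% res2$taxid)
  expect_true("b0001" %in% res2$read_id)

  # ... but a read whose only hit is rare keeps its best hit
  only_rare <- mk("solo", 99L, 2L)
  rep3 <- rbind(bulk, only_rare)
  res3 <- resolve_ambiguity(rep3, edit_slack = Inf,
                            min_taxon_read_fraction = 1e-2)
  expect_equal(res3$taxid[res3$read_id == "solo"], 99L)
})
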
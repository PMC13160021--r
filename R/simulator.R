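#' Generate a synthetic annotated genome
#'
#' Bases are drawn i.i.d. at the requested GC content. Non-overlapping CDS
#' features (lengths a multiple of 3, at least 150 bp) are placed uniformly
#' by rejection sampling; feature strands are random. Every generator in
#' this module is a pure function of its seed: the same seed reproduces the
#' genome bit for bit.
#'
#' @param taxid species taxid (> 0).
#' @param length genome length in bases.
#' @param n_genes number of CDS features (n_genes * 150 must not exceed
#'   half the genome).
#' @param gc_fraction target GC content in (0, 1).
#' @param seed integer RNG seed.
#' @param accession genome accession (default derived from the taxid).
#' @param gene_length_range CDS length bounds in bases; drawn lengths are
#'   rounded to multiples of 3 within the range.
#' @return object of class `synthetic_genome`: `accession`, `taxid`,
#'   `sequence`, `features` (a [parse_gff()]-style data.frame), `og_seed`
#'   (ancestral feature ids used for ortholog aliasing), `rng_seed`.
#' @export
generate_genome <- function(taxid, length, n_genes, gc_fraction = 0.5,
                            seed = 1L,
                            accession = sprintf("SYN%06d", taxid),
                            gene_length_range = c(300L, 900L)) {
  stopifnot(taxid > 0, length > 0, n_genes >= 0)
  if (n_genes * 150 > length / 2) {
    stop("gene density too high: n_genes * 150 must be <= length / 2")
  }
  withr::with_seed(seed, {
    probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
               gc_fraction / 2, (1 - gc_fraction) / 2)
    sequence <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                             prob = probs), collapse = "")
    starts <- integer(0)
    ends <- integer(0)
    if (n_genes > 0L) {
      lens <- sample(seq(gene_length_range[1L], gene_length_range[2L],
                         by = 3L), n_genes, replace = TRUE)
      lens <- pmax(150L, (lens %/% 3L) * 3L)
      for (g in seq_len(n_genes)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          s <- sample.int(length - lens[g] + 1L, 1L) - 1L
          e <- s + lens[g]
          if (all(e <= starts | s >= ends)) {
            starts <- c(starts, s); ends <- c(ends, e)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place gene ", g, " after 200 tries; ",
               "reduce gene density or genome occupancy")
        }
      }
      ord <- order(starts)
      starts <- starts[ord]; ends <- ends[ord]
    }
    strands <- if (n_genes > 0L) sample(c("+", "-"), n_genes, replace = TRUE)
               else character(0)
    feature_id <- sprintf("%s_%04d", accession, seq_len(n_genes))
    features <- data.frame(
      feature_id = feature_id,
      gene_name = rep("", n_genes),
      product = rep("hypothetical protein", n_genes),
      protein_id = sprintf("%s_p", feature_id),
      accession = rep(accession, n_genes),
      start = starts, end = ends, strand = strands,
      source_start_1based = starts + 1L,
      stringsAsFactors = FALSE)
    structure(list(accession = accession, taxid = as.integer(taxid),
                   sequence = sequence, features = features,
                   og_seed = feature_id, rng_seed = seed),
              class = "synthetic_genome")
  })
}

#' Derive a diverged genome (strain or sister species)
#'
#' Each base is substituted independently with probability
#' `substitution_rate` to a uniformly chosen different base. Features are
#' inherited at identical coordinates under new ids; the ancestral feature
#' ids are propagated in `og_seed` so diverged gene copies can share an
#' ortholog group.
#'
#' @param genome a `synthetic_genome`.
#' @param substitution_rate per-base substitution probability in [0, 0.3].
#' @param new_taxid taxid of the derived genome (same taxid models an
#'   additional strain of the species).
#' @param seed integer RNG seed.
#' @param accession accession of the derived genome.
#' @return a `synthetic_genome`.
#' @export
diverge_genome <- function(genome, substitution_rate, new_taxid,
                           seed = 1L,
                           accession = sprintf("SYN%06dD", new_taxid)) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.3)
  withr::with_seed(seed, {
    chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(chars)) < substitution_rate)
    if (length(hit) > 0L) {
      bases <- c("A", "C", "G", "T")
      cur <- match(chars[hit], bases)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- bases[(cur - 1L + shift) %% 4L + 1L]
    }
    features <- genome$features
    if (nrow(features) > 0L) {
      features$feature_id <- sprintf("%s_%04d", accession,
                                     seq_len(nrow(features)))
      features$protein_id <- paste0(features$feature_id, "_p")
      features$accession <- accession
    }
    structure(list(accession = accession, taxid = as.integer(new_taxid),
                   sequence = paste(chars, collapse = ""),
                   features = features,
                   og_seed = genome$og_seed, rng_seed = seed),
              class = "synthetic_genome")
  })
}

#' Sample a community abundance profile
#'
#' Relative abundances follow a log-normal law (the long-tailed shape of
#' benchmark microbial community profiles); `sigma` controls evenness
#' (0 = uniform community).
#'
#' @param taxids integer vector of community members.
#' @param sigma log-scale standard deviation.
#' @param seed integer RNG seed.
#' @return named numeric vector of abundances summing to 1.
#' @export
community_profile <- function(taxids, sigma = 1, seed = 1L) {
  withr::with_seed(seed, {
    w <- exp(stats::rnorm(length(taxids), 0, sigma))
    stats::setNames(w / sum(w), taxids)
  })
}

#' Simulate a synthetic community
#'
#' Builds a set of well-separated synthetic species. With `paired = TRUE`
#' (the default) half of the species are independent ancestors and each is
#' accompanied by a sister species diverged at `sister_divergence`
#' substitutions per base, the pair sharing a genus — the configuration
#' that exercises species separability. With `paired = FALSE` every species
#' is independent and monotypic.
#'
#' @param n_species number of species (even when `paired`).
#' @param genome_length genome length in bases.
#' @param n_genes CDS features per genome.
#' @param sister_divergence substitution rate separating sister species.
#' @param paired generate congeneric sister pairs.
#' @param gc_fraction GC content.
#' @param seed integer RNG seed.
#' @return list with `genomes` (list of `synthetic_genome`), `genus_map`
#'   (data.frame: taxid, genus_taxid, genus_name), `taxids`.
#' @export
simulate_community <- function(n_species = 20L, genome_length = 100000L,
                               n_genes = 50L, sister_divergence = 0.10,
                               paired = TRUE, gc_fraction = 0.5, seed = 1L) {
  n_species <- as.integer(n_species)
  seeds <- withr::with_seed(seed, {
    sample.int(1000000L, 2L * n_species)
  })
  genomes <- list()
  genus_rows <- list()
  if (paired) {
    if (n_species %% 2L != 0L) stop("paired communities need an even n_species")
    n_anc <- n_species %/% 2L
    for (i in seq_len(n_anc)) {
      anc_tax <- 1000L + i
      sis_tax <- 1000L + n_anc + i
      genus <- 5000L + i
      anc <- generate_genome(anc_tax, genome_length, n_genes, gc_fraction,
                             seed = seeds[2L * i - 1L])
      sis <- diverge_genome(anc, sister_divergence, sis_tax,
                            seed = seeds[2L * i])
      genomes[[length(genomes) + 1L]] <- anc
      genomes[[length(genomes) + 1L]] <- sis
      genus_rows[[length(genus_rows) + 1L]] <- data.frame(
        taxid = c(anc_tax, sis_tax), genus_taxid = genus,
        genus_name = sprintf("genus_%d", genus), stringsAsFactors = FALSE)
    }
  } else {
    for (i in seq_len(n_species)) {
      tax <- 1000L + i
      genomes[[i]] <- generate_genome(tax, genome_length, n_genes,
                                      gc_fraction, seed = seeds[i])
      genus_rows[[i]] <- data.frame(taxid = tax, genus_taxid = 5000L + i,
                                    genus_name = sprintf("genus_%d", 5000L + i),
                                    stringsAsFactors = FALSE)
    }
  }
  genus_map <- do.call(rbind, genus_rows)
  list(genomes = genomes, genus_map = genus_map,
       taxids = vapply(genomes, function(g) g$taxid, integer(1L)))
}

# Per-read mutation walk over the oriented source window. Emits up to
# read_length bases; insertions add uniform random bases, deletions skip
# source bases (geometric lengths, mean 2), substitutions replace with a
# uniformly chosen different base. Records the operations so the read can
# be reconstructed from the window.
.mutate_walk <- function(src, read_length, sub_rate, indel_rate) {
  schars <- strsplit(src, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  ops <- character(0)
  i <- 1L; nsub <- 0L; nind <- 0L
  while (length(out) < read_length && i <= length(schars)) {
    if (indel_rate > 0 && stats::runif(1L) < indel_rate) {
      nind <- nind + 1L
      k <- 1L + stats::rgeom(1L, 0.5)
      if (stats::runif(1L) < 0.5) {
        ins <- sample(bases, k, replace = TRUE)
        out <- c(out, ins)
        ops <- c(ops, paste0("I", i, ":", paste(ins, collapse = "")))
      } else {
        ops <- c(ops, paste0("D", i, ":", k))
        i <- i + k
        next
      }
    }
    b <- schars[i]
    if (stats::runif(1L) < sub_rate) {
      nsub <- nsub + 1L
      b2 <- sample(setdiff(bases, b), 1L)
      ops <- c(ops, paste0("S", i, ":", b2))
      b <- b2
    }
    out <- c(out, b)
    i <- i + 1L
  }
  list(read = paste(utils::head(out, read_length), collapse = ""),
       ops = paste(ops, collapse = ";"),
       n_subs = nsub, n_indels = nind, consumed = i - 1L)
}

#' Reconstruct a read from its truth record
#'
#' Replays the recorded mutation operations over the oriented source
#' window; the result must equal the emitted read exactly (the simulator's
#' self-consistency contract).
#'
#' @param src_window oriented source window (reverse-complemented for
#'   reverse-strand reads).
#' @param ops the truth record's `mutations` string.
#' @param read_length emitted read length.
#' @return the reconstructed read sequence.
#' @export
reconstruct_read <- function(src_window, ops, read_length) {
  schars <- strsplit(src_window, "", fixed = TRUE)[[1L]]
  if (!nzchar(ops)) {
    return(paste(schars[seq_len(min(read_length, length(schars)))],
                 collapse = ""))
  }
  out <- character(0)
  i <- 1L
  for (op in strsplit(ops, ";", fixed = TRUE)[[1L]]) {
    type <- substr(op, 1L, 1L)
    body <- strsplit(substr(op, 2L, nchar(op)), ":", fixed = TRUE)[[1L]]
    pos <- as.integer(body[1L])
    if (pos > i) {
      out <- c(out, schars[i:(pos - 1L)])
      i <- pos
    }
    if (type == "S") {
      out <- c(out, body[2L])
      i <- i + 1L
    } else if (type == "I") {
      out <- c(out, strsplit(body[2L], "", fixed = TRUE)[[1L]])
    } else if (type == "D") {
      i <- i + as.integer(body[2L])
    }
  }
  if (i <= length(schars)) out <- c(out, schars[i:length(schars)])
  paste(utils::head(out, read_length), collapse = "")
}

#' Simulate metatranscriptomic reads with truth labels
#'
#' Each read's source taxon is drawn from the abundance profile, its source
#' CDS uniformly weighted by feature length, its start uniformly within
#' the feature so the read fits, and its strand uniformly. Substitutions
#' are introduced i.i.d. per base; insertions and deletions (geometric
#' lengths) i.i.d. per source base. All mutations are recorded in the
#' truth table so every read is reconstructable from its source window.
#' Base qualities are constant 'I' (the pipeline never reads qualities;
#' quality control is an upstream concern).
#'
#' @param genomes list of `synthetic_genome` objects.
#' @param profile named abundance vector over taxids (see
#'   [community_profile()]).
#' @param n_reads number of reads.
#' @param read_length read length in bases (at most the shortest CDS).
#' @param sub_rate per-base substitution probability.
#' @param indel_rate per-base indel event probability.
#' @param seed integer RNG seed.
#' @return list with `reads` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame: read_id, true_taxid, true_accession,
#'   true_feature_id, true_start, true_end, strand, n_subs, n_indels,
#'   mutations, src_window).
#' @export
simulate_reads <- function(genomes, profile, n_reads, read_length = 150L,
                           sub_rate = 0, indel_rate = 0, seed = 1L) {
  tax_of <- vapply(genomes, function(g) g$taxid, integer(1L))
  ptax <- as.integer(names(profile))
  missing <- setdiff(ptax, tax_of)
  if (length(missing) > 0L) {
    stop("profile taxon without a genome: ", paste(missing, collapse = ", "))
  }
  extra <- if (indel_rate > 0) 30L else 0L
  W <- read_length + extra

  withr::with_seed(seed, {
    gi_of_tax <- match(ptax, tax_of)
    draw <- sample.int(length(ptax), n_reads, replace = TRUE, prob = profile)
    gidx <- gi_of_tax[draw]

    acc <- character(n_reads); fid <- character(n_reads)
    start <- integer(n_reads); win <- integer(n_reads)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    src <- character(n_reads)
    for (g in unique(gidx)) {
      rows <- which(gidx == g)
      gen <- genomes[[g]]
      f <- gen$features
      wdt <- f$end - f$start
      Wg <- pmin(W, max(wdt))
      ok <- wdt >= read_length
      if (!any(ok)) {
        stop("taxon ", gen$taxid, " has no CDS long enough for ",
             read_length, " bp reads")
      }
      okidx <- which(ok)
      fi <- okidx[sample.int(length(okidx), length(rows), replace = TRUE,
                             prob = wdt[okidx])]
      wr <- pmin(Wg, wdt[fi])
      s <- f$start[fi] + floor(stats::runif(length(rows)) *
                                 (wdt[fi] - wr + 1L))
      acc[rows] <- gen$accession
      fid[rows] <- f$feature_id[fi]
      start[rows] <- as.integer(s)
      win[rows] <- as.integer(wr)
      src[rows] <- substring(gen$sequence, s + 1L, s + wr)
    }
    rev <- strand == "-"
    if (any(rev)) src[rev] <- revcomp(src[rev])

    reads <- src
    ops <- character(n_reads)
    n_subs <- integer(n_reads)
    n_indels <- integer(n_reads)
    consumed <- win

    if (indel_rate > 0) {
      for (r in seq_len(n_reads)) {
        mw <- .mutate_walk(src[r], read_length, sub_rate, indel_rate)
        reads[r] <- mw$read
        ops[r] <- mw$ops
        n_subs[r] <- mw$n_subs
        n_indels[r] <- mw$n_indels
        consumed[r] <- mw$consumed
      }
    } else if (sub_rate > 0) {
      # vectorized substitution-only path
      bases <- c("A", "C", "G", "T")
      k <- stats::rbinom(n_reads, read_length, sub_rate)
      for (r in which(k > 0L)) {
        pos <- sort(sample.int(read_length, k[r]))
        chars <- strsplit(reads[r], "", fixed = TRUE)[[1L]]
        cur <- match(chars[pos], bases)
        alt <- bases[(cur - 1L + sample.int(3L, k[r], replace = TRUE)) %% 4L + 1L]
        chars[pos] <- alt
        reads[r] <- paste(chars, collapse = "")
        ops[r] <- paste(sprintf("S%d:%s", pos, alt), collapse = ";")
        n_subs[r] <- k[r]
      }
      consumed <- rep(read_length, n_reads)
    } else {
      reads <- substring(reads, 1L, read_length)
      consumed <- rep(read_length, n_reads)
    }

    # consumed source span on the forward genome strand
    true_start <- ifelse(rev, start + win - consumed, start)
    true_end <- ifelse(rev, start + win, start + consumed)

    ids <- sprintf("read_%07d", seq_len(n_reads))
    truth <- data.frame(read_id = ids,
                        true_taxid = ptax[draw],
                        true_accession = acc,
                        true_feature_id = fid,
                        true_start = as.integer(true_start),
                        true_end = as.integer(true_end),
                        strand = strand,
                        n_subs = n_subs, n_indels = n_indels,
                        mutations = ops,
                        src_window = src,
                        stringsAsFactors = FALSE)
    rs <- Biostrings::DNAStringSet(reads)
    names(rs) <- ids
    list(reads = rs, truth = truth)
  })
}

#' Write simulated reads as FASTQ
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param path output FASTQ path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  names(quals) <- names(reads)
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Write reference, annotation, and mapping files for a community
#'
#' Emits everything the pipeline consumes: the reference FASTA, GFF3
#' annotations, translated protein FASTA (standard genetic code, trailing
#' stop trimmed, keyed by protein_id), the accession/taxonomy metadata
#' TSV, and an ortholog-group map. By default each feature is its own OG;
#' `alias_diverged_ogs = TRUE` instead assigns diverged gene copies the OG
#' of their ancestral feature, so sister species share gene families.
#'
#' @param genomes list of `synthetic_genome` objects.
#' @param out_dir output directory (created if needed).
#' @param genus_map optional data.frame (taxid, genus_taxid, genus_name);
#'   by default every species is placed in its own genus.
#' @param alias_diverged_ogs share OGs across diverged gene copies.
#' @param profile optional abundance profile, written alongside.
#' @return named list of written paths.
#' @export
write_truth_and_annotations <- function(genomes, out_dir,
                                        genus_map = NULL,
                                        alias_diverged_ogs = FALSE,
                                        profile = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(ref_fasta = file.path(out_dir, "ref.fasta"),
                gff = file.path(out_dir, "ref.gff3"),
                proteins = file.path(out_dir, "proteins.faa"),
                metadata = file.path(out_dir, "metadata.tsv"),
                og_map = file.path(out_dir, "og_map.tsv"))

  seqs <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$sequence,
                                          character(1L)))
  names(seqs) <- vapply(genomes, function(g) g$accession, character(1L))
  Biostrings::writeXStringSet(seqs, paths$ref_fasta)

  features <- do.call(rbind, lapply(genomes, function(g) g$features))
  write_gff(features, paths$gff)

  prots <- list()
  for (g in genomes) {
    f <- g$features
    if (nrow(f) == 0L) next
    cds <- substring(g$sequence, f$start + 1L, f$end)
    minus <- f$strand == "-"
    if (any(minus)) cds[minus] <- revcomp(cds[minus])
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds)))
    aa <- sub("\\*$", "", aa)
    prots[[length(prots) + 1L]] <- stats::setNames(aa, f$protein_id)
  }
  prot_vec <- unlist(prots)
  if (is.null(prot_vec)) prot_vec <- character(0)
  aa_set <- Biostrings::AAStringSet(prot_vec)
  Biostrings::writeXStringSet(aa_set, paths$proteins)

  taxids <- vapply(genomes, function(g) g$taxid, integer(1L))
  if (is.null(genus_map)) {
    u <- unique(taxids)
    genus_map <- data.frame(taxid = u, genus_taxid = u + 100000L,
                            genus_name = sprintf("genus_%d", u + 100000L),
                            stringsAsFactors = FALSE)
  }
  gm <- genus_map[match(taxids, genus_map$taxid), , drop = FALSE]
  metadata <- data.frame(accession = names(seqs),
                         taxid = taxids,
                         species_name = sprintf("species_%d", taxids),
                         genus_taxid = gm$genus_taxid,
                         genus_name = gm$genus_name,
                         stringsAsFactors = FALSE)
  utils::write.table(metadata, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  og_rows <- do.call(rbind, lapply(genomes, function(g) {
    if (nrow(g$features) == 0L) return(NULL)
    og <- if (alias_diverged_ogs) g$og_seed else g$features$feature_id
    data.frame(feature_id = g$features$feature_id,
               og_id = paste0("OG_", og), stringsAsFactors = FALSE)
  }))
  if (is.null(og_rows)) {
    og_rows <- data.frame(feature_id = character(0), og_id = character(0))
  }
  utils::write.table(og_rows, paths$og_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (!is.null(profile)) {
    paths$profile <- file.path(out_dir, "profile.tsv")
    utils::write.table(data.frame(taxid = names(profile),
                                  abundance = as.numeric(profile)),
                       paths$profile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths
}

#' Score assignments against simulation truth
#'
#' Computes the headline accuracy metrics: the fraction of reads assigned
#' at all; of those, the fraction whose hit set contains the true source
#' species (containment semantics — a multi-taxon read counts as correct
#' if the true taxon is among its hits); of the correct reads, the
#' fraction unambiguously assigned to a single species; and the number of
#' species hit that are not in the expected community, with the count of
#' reads assigned exclusively to such unexpected species.
#'
#' @param truth truth data.frame from [simulate_reads()].
#' @param assignments (merged) assignment report; every read id must be
#'   present in `truth`.
#' @param expected_taxa integer vector of community taxids (default: the
#'   taxa in `truth`).
#' @return object of class `accuracy_report`: `fraction_assigned`,
#'   `fraction_correct`, `fraction_unique_species`,
#'   `unexpected_species_count`, `reads_to_unexpected`, `n_reads`.
#'   Fractions are in [0, 1]; undefined ratios (empty denominators) are NA.
#' @export
evaluate_assignments <- function(truth, assignments,
                                 expected_taxa = unique(truth$true_taxid)) {
  stray <- setdiff(unique(assignments$read_id), truth$read_id)
  if (length(stray) > 0L) {
    stop("assignment read id(s) absent from truth: ",
         paste(utils::head(stray, 3L), collapse = ", "))
  }
  n_total <- nrow(truth)
  hits_by_read <- split(assignments$taxid, assignments$read_id)
  n_assigned <- length(hits_by_read)
  true_tax <- truth$true_taxid[match(names(hits_by_read), truth$read_id)]
  correct <- if (n_assigned == 0L) logical(0) else
    mapply(function(hits, tt) tt %in% hits, hits_by_read, true_tax)
  n_correct <- sum(correct)
  n_unique <- sum(vapply(hits_by_read[correct],
                         function(h) length(unique(h)) == 1L, logical(1L)))
  unexpected <- setdiff(unique(assignments$taxid), expected_taxa)
  only_unexpected <- vapply(hits_by_read,
                            function(h) all(h %in% unexpected), logical(1L))
  structure(list(
    fraction_assigned = if (n_total > 0L) n_assigned / n_total else NA_real_,
    fraction_correct = if (n_assigned > 0L) n_correct / n_assigned else NA_real_,
    fraction_unique_species = if (n_correct > 0L) n_unique / n_correct
                              else NA_real_,
    unexpected_species_count = length(unexpected),
    reads_to_unexpected = if (length(unexpected) > 0L) sum(only_unexpected)
                          else 0L,
    n_reads = n_total), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.3f%%", 100 * v)
  cat("accuracy over ", x$n_reads, " reads:\n",
      "  assigned:        ", pct(x$fraction_assigned), "\n",
      "  correct:         ", pct(x$fraction_correct), "\n",
      "  unique species:  ", pct(x$fraction_unique_species), "\n",
      "  unexpected species: ", x$unexpected_species_count,
      " (", x$reads_to_unexpected, " reads exclusively)\n", sep = "")
  invisible(x)
}
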
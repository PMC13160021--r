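---
title: "Joint taxonomic and gene assignment: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint taxonomic and gene assignment: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Metatranscriptomic reads from a mixed bacterial community carry two pieces
of information at once: which organism transcribed them and which gene
they came from. Pipelines that classify reads with k-mer profiles lose the
genomic coordinate needed for the second question; pipelines that search
translated protein databases lose the nucleotide differences needed to
answer the first at species resolution. `taxalign` keeps both by aligning
each read at the nucleotide level against an indexed reference collection
and carrying the alignment coordinate forward into gene assignment.

## The assignment model

**Index.** A reference chunk is the concatenation of its member genomes
separated by a non-DNA separator symbol and terminated by a sentinel. Over
this text we build a suffix array (rank-doubling construction), its
Burrows–Wheeler transform, a cumulative symbol-count table, and a
checkpointed rank structure; backward search answers exact pattern counts
in time proportional to pattern length, and the suffix array resolves
match positions. The separator guarantees that no match spans a record
boundary. N is indexed as an ordinary fifth symbol but query patterns
containing N are rejected before search: an ambiguous base cannot anchor
an *exact* seed, and letting N match anything would require an
approximate-matching index.

**Seeding.** A read of length $L$ is cut into seeds of length $k$ at
offsets $0, s, 2s, \dots$ plus one final seed ending at the last base, on
both the read and its reverse complement (the index stores only the
forward strand; reverse-complementing the query halves index size). For
each seed hit at reference offset $r$ from read offset $q$ the alignment
diagonal is $r - q$. Hits on one (genome, strand) are sorted by diagonal
and clustered greedily: a new cluster opens when the diagonal drifts more
than the tolerance from the cluster's smallest diagonal. Clusters with at
least `min_seed_hits` seeds become candidate regions.

**Verification.** Candidates are evaluated in descending seed support;
ties break deterministically by (taxid, accession, projected start,
strand) so runs are bit-reproducible. The read is aligned to the window
$[p - \text{pad},\ p + L + \text{pad})$ around the projected start $p$
(pad = `max_edits` + 5, clamped to the sequence) under **semi-global
unit-cost edit distance**: the full read must be consumed, gaps at either
window end are free, and every substitution, insertion, or deletion costs
one. A candidate passes iff the distance is at most `max_edits`. The
kernel's contract is score-exact — it must agree with the plain
$O(nm)$ dynamic program, which the test suite enforces on hundreds of
random pairs — so any faster implementation is an optimization, never a
semantic change.

The choice of *semi-global edit distance* rather than local
(Smith–Waterman-style) scoring is deliberate: under unit costs a local
alignment degenerates toward short perfect fragments, whereas thresholding
on the edit distance of the *whole read* is what an accept/reject rule per
read actually requires. Local scoring with affine gaps would change which
borderline reads pass, not the architecture.

**Taxon-aware early stop.** Once a taxon has one passing alignment,
remaining candidates for that taxon are skipped. Because candidates only
ever *add* hits for a taxon already represented, the per-read set of hit
taxa is identical to exhaustive evaluation — only the chosen coordinate
within the taxon may differ. The suite audits this equivalence with an
instrumented exhaustive mode.

**Merging and ambiguity.** Chunks are processed independently and merged:
hits are unioned per read, duplicates collapse, and the same taxon seen
from several chunks keeps its lowest-edit-distance hit (ties:
lexicographically smallest accession, then smallest start). Merged results
are therefore invariant to how the reference was chunked, which the suite
checks by comparing single-chunk and split runs. Ambiguity resolution is
opt-in, matching the view that filtering is a per-study decision: an edit
slack drops hits worse than the read's best distance plus slack, and a
sample-level support threshold drops taxa seen in fewer than a given
fraction of assigned reads — never emptying a read's hit set (the read
then keeps its best hit). Reads with several surviving taxa are reported
as `multi_taxon`, not silently discarded.

## Gene assignment and quantification

CDS features parsed from GFF3 (CDS rather than gene/mRNA rows, because in
bacterial annotation CDS is the reliably present, protein-linked record)
are held in per-sequence interval indexes. An alignment span is assigned
to the overlapping feature with the most overlapping bases (ties: smallest
start, then feature id); below `min_overlap` — one base by default, or a
fraction of the span — the read is *intergenic*. Strand is ignored unless
requested, since unstranded RNA-seq protocols remain common.

Counts aggregate primary gene assignments per (taxon, gene, sample).
Multi-taxon reads are excluded by default to avoid double counting; a
fractional mode splits them evenly across their taxa and restores integer
column totals by largest-remainder rounding. Gene rows collapse to
ortholog groups through a supplied many-to-one map (unmapped features are
kept under their own ids by default, conserving totals), species roll up
to genus through the taxonomy, and the low-abundance filter keeps a row
only if at least `min_count = 5` reads appear in at least
`min_samples = 3` samples *within each* group. The per-group wording of
that rule is ambiguous between "each" and "any"; the stricter each-group
reading is the default and a flag selects the other.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `seed_length` | 18 | bases | exact-match anchor length; shorter is more sensitive, noisier |
| `seed_interval` | 9 | bases | seed spacing; half the seed length gives 2× tiling |
| `min_seed_hits` | 2 | seeds | diagonal support required before alignment |
| `diagonal_tolerance` | 5 | bases | indel slack within one candidate |
| `max_edits` | 7 | edits | accept threshold, ≈5% of a 150 bp read |
| `max_chunk_bases` | — | bases | index partition size; memory knob |
| `sa_sample_rate` | 1 | rows | suffix-array sampling; >1 trades locate speed for memory |
| `min_overlap` | 1 | bases (or fraction) | gene-overlap threshold |
| `min_count`, `min_samples` | 5, 3 | reads, samples | low-abundance filter |

With 18-mer seeds every 9 bases a 150 bp read carries 16 seeds per
strand; a read with $e$ scattered substitutions still retains roughly
$16 - 2e$ exact seeds, so the two-seed requirement tolerates the error
loads that `max_edits = 7` accepts. All parameters are exposed through
the function interfaces, the command-line flags, and a flat config file.

## What the simulator emulates — and what it does not

The simulator generates i.i.d.-base genomes at a target GC with
non-overlapping CDS features, sister species by per-base substitution at
a set divergence, log-normal community abundances (the long-tailed shape
of real community profiles; σ = 1 by default), and 150 bp single-end
reads drawn from CDSs in proportion to abundance and feature length, with
i.i.d. substitutions and geometric-length indels recorded per read. The
default benchmark — 20 species as ten ancestor/sister pairs at 10%
divergence, 100 kb genomes, 50 CDSs, 50,000 reads at 0.5% substitutions —
is sized so that a desk machine runs the entire experiment in well under
a minute while still exercising the discriminating case: congeneric
species whose conserved stretches produce genuine multi-taxon reads.

Real data differ in ways the simulator does not model: genome-scale
repeat structure and mobile elements, shared operons and horizontally
transferred genes between *distant* taxa, sequencer error profiles with
quality-dependent miscalls, rRNA carryover, and uneven coverage. Passing
the synthetic benchmarks therefore demonstrates the correctness of the
machinery (indexing, search, alignment, merging, counting) and its
behaviour under controlled divergence — not field accuracy on any
particular biome. Conversely, the synthetic database is *cleaner* than a
production reference, which makes the benchmark a fair lower-bound
setting for assignment and correctness rates.

## Numerical and degenerate-input choices

* All index-layer coordinates are 0-based half-open; conversion to GFF's
  1-based inclusive convention happens only at the GFF boundary, and a
  round-trip is asserted to be the identity.
* Alignment tie-breaks prefer diagonal over read-gap over window-gap
  moves and the smallest window end, making reported spans deterministic.
* Reads shorter than one seed, or consisting of Ns, are reported
  `unassigned` — never an error.
* An empty FASTQ yields a valid empty report; an empty FASTA or a missing
  metadata row is a hard error naming the accession.
* Index files carry a magic number and format version; truncated or
  foreign files are rejected whole rather than partially loaded.
* The largest-remainder rounding used by fractional counting breaks ties
  by row order, keeping exports reproducible.

## Known limitations

* The BWT is stored uncompressed; production-scale collections would want
  a run-length or wavelet-tree rank structure. Chunking is the supported
  memory lever.
* Paired-end mates are treated as independent single-end reads; there is
  no fragment-level rescue.
* Ambiguity resolution offers edit-slack and abundance filters but no
  lowest-common-ancestor reporting; unresolved reads stay multi-taxon.
* Differential expression itself is out of scope: the package emits
  filtered count matrices for external DE tools rather than fitting
  models.
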
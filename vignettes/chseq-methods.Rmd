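---
title: "Methods and design of the chseq pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the chseq pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chseq)
```

## The problem

Combinatorial split-pool indexing labels single cells without physical
compartments: cells are repeatedly pooled and redistributed across barcoded
wells, so each cell accumulates a path of well barcodes that, jointly with
the library's PCR indices, identifies it. In the hybridization variant
modelled here, reverse transcription introduces the first round of cell
barcodes (96 or 384 wells), oligo annealing without ligation introduces a
second round (768 wells), and library amplification adds i5/i7 sample
indices. Two rounds of 96 x 768 already give 73,728 cell labels per index
pair; with a 96 x 4 index plate and 384 first-round wells the label space
exceeds 10^8 (`combination_count(384, 768, 96, 4)`), which is what makes
million-cell experiments affordable.

The computational task this package implements has five parts:

1. a ground-truthed simulator of such libraries (two synthetic species,
   doublets, sequencing errors, PCR duplicates);
2. demultiplexing: sample-index splitting, Read1 segment extraction, and
   whitelist error correction;
3. quantification: transcript assignment, UMI deduplication, and the
   digital expression matrix;
4. species-mixing ("barnyard") quality control with the over-85% purity
   rule;
5. downstream statistics: time-associated genes by permutation Spearman
   correlation, L1 centroid perturbation, and pseudocell aggregation.

## Read structure and the dark-cycle window

Read1 sequences the barcode stack. Fixed linker bases between the barcode
blocks are skipped on-instrument as *dark cycles* — cycles run without
imaging — so the delivered read contains only informative bases. The
default layout models a 51-cycle Read1 with dark cycles 11–33: 28 delivered
bases laid out as bc2 (10 nt) + bc1 (10 nt) + UMI (8 nt), with a 100 nt
cDNA Read2. Real instruments deliver the i5/i7 index reads separately; the
simulator records them in the FASTQ header comment (`i5:SEQ i7:SEQ`), and
the demultiplexer reads them from there.

Segment lengths are not universal constants of the assay — they depend on
the oligo design — so the layout is fully overridable (`ch_read_layout()`),
with the 10/10/8 split as a realistic default for two-round schemes of this
size. All cycle coordinates in configs are 1-based inclusive.

```{r layout}
ch_read_layout()
```

## Whitelists and barcode correction

Whitelist oligo sets are modelled as seeded random sequence sets with an
enforced minimum pairwise Hamming distance (`random_whitelist()`); TSV
import/export is provided for real whitelists. Correction uses an exhaustive
substitution-neighbourhood index (`build_correction_index()`): every
sequence within `max_mismatch` substitutions of a whitelist entry maps to
that entry, sequences reachable from two or more entries are flagged
ambiguous, and ambiguous observations are *discarded, never guessed* —
determinism is preferred over yield. An exact whitelist hit always resolves
to itself with zero mismatches.

Two classical bounds drive the defaults, and `validate_scheme()` reports
them per round:

* minimum pairwise distance `2m + 1` guarantees that correction of up to
  `m` substitutions is unique;
* distance `2m + 2` additionally guarantees that a read carrying `m + 1`
  substitutions is rejected rather than silently assigned to a wrong well.

`max_mismatch` defaults to 1 per cell-barcode round, the common choice for
split-pool pipelines; budgets above 1 are refused outright because
two-substitution neighbourhoods of 768 ten-mers collide heavily and
correction stops being reliable. i5/i7 indices default to exact match —
PCR index sets are designed with large separations, and a wrong index
routes a read to the wrong sub-library, the costliest failure mode.

Per-round correction is independent (bc1 and bc2 are corrected against
separate lists rather than jointly over the concatenated barcode), matching
how the two rounds are physically independent.

## The simulator

`ch_sim_config()` fixes the study conditions; everything downstream of the
seed is deterministic, to the byte, including the gzipped FASTQ output.

* **Reference.** Two synthetic species (A and B) with uniform-random
  transcripts of 300–2000 nt, one transcript per gene by default. Random
  sequences of this length are pairwise unrelated, which is exactly the
  regime where exact k-mer assignment (below) is a faithful stand-in for
  alignment to a merged two-genome reference.
* **Cells.** Each cell gets a barcode tuple sampled without replacement
  from the scheme's combination space, a species, and a per-gene expression
  weight vector (species-level lognormal baseline with per-cell gamma
  jitter). Depth is lognormal with configurable spread.
* **Doublets.** Cross-species doublets are modelled as barcode collisions:
  one tuple carrying a 50:50 mixture of a species-A and a species-B
  profile, mirroring the HEK293T/NIH3T3 barnyard design. The realised count
  is exactly `round(doublet_fraction * n_cells)`. Same-species doublets are
  not simulated by default: the cross-species purity metric cannot see
  them, which is also why the report offers the doubled extrapolation as a
  separate field.
* **Molecules and duplicates.** UMIs are drawn uniformly per molecule;
  reads then resample molecules with replacement at a configurable
  duplicate rate, reproducing PCR duplicate structure. With
  `duplicate_rate = 0` every read is a distinct molecule.
* **Errors.** Independent per-base substitutions at `barcode_error_rate`
  (Read1 segments and both indices) and `cdna_error_rate` (Read2). Quality
  strings are constant Q37; quality-aware demultiplexing is out of scope.

The truth table records, per read pair, the true cell, gene, UMI, pre-error
barcode segments and per-segment error counts; `truth_molecule_table()`
collapses it to the distinct sequenced molecules, which is the exact target
a perfect pipeline must reproduce at zero error rates.

What the simulator deliberately does **not** emulate: per-cycle error
profiles, indels, ambient RNA, empty barcodes ("barcode soup"), intronic
or antisense reads, and batch structure. Passing tests therefore
demonstrate the correctness of the barcode logic, counting and statistics
under controlled conditions — not robustness to every artefact of real
libraries.

## Demultiplexing

`demux_run()` applies, in order: sample-index matching (exact by default),
truncation check against the delivered length, bc2 then bc1 correction, and
a UMI alphabet check (an `N` inside an 8-mer UMI corrupts deduplication, so
such reads are dropped as `bad_umi`). Every read ends in exactly one status
(`assigned`, `bad_index`, `truncated`, `no_match_bc1`, `no_match_bc2`,
`ambiguous_bc1`, `ambiguous_bc2`, `bad_umi`), and the report's status
counts sum to the input read count — a conservation invariant the tests
enforce. Assigned reads carry the cell key `(i7, i5, bc2, bc1)` built from
*corrected* sequences. Rejected reads are counted, not written.

## Quantification

Transcript assignment replaces genome alignment with a desk-scale
seed-and-verify exact-containment rule: a 21-mer seed from the read is
looked up in an index of all transcript 21-mers; a seed shared by two or
more genes marks the read multimapped (discarded, as in conventional
unique-assignment counting); a unique-gene seed is verified by exact
comparison of the full read at the implied offset. Seeds are tried at the
read start, middle and end. Consequences to be aware of:

* any substitution in Read2 fails verification, so the assigned fraction is
  about `(1 - e)^L` for error rate `e` and read length `L` — at the default
  0.5% and 100 nt, roughly 60%. This is by design: assignment is exact or
  absent, never approximate;
* `k = 21` makes chance seed sharing between random transcripts negligible
  (4^21 > 4 x 10^12), so multimapping arises only from genuinely shared
  sequence.

UMI deduplication defaults to **exact-unique** counting (distinct UMI
sequences per cell-gene pair), the behaviour of plain HTseq-style digital
expression. A **directional** single-mismatch collapse (merge a UMI into a
neighbour at Hamming distance 1 whose read count is at least twice its own
minus one) is available for comparison; neither is claimed to be "the"
original, since published pipelines differ here.

Cell filtering retains cells with UMIs strictly greater than 200. The
strict inequality follows the sharper of the two phrasings in circulation
("UMIs > 200" vs "less than 200 excluded", which disagree only at exactly
200); it is configurable (`strict = FALSE`).

## Barnyard quality control

Cells passing the UMI filter are classified by species purity: a cell with
strictly more than 85% of UMIs from one species is species-specific;
everything else is a collision. The strictness at the boundary (85.000%
exactly is a collision) and the filter-before-classify order are both
deliberate and tested. The collision rate is reported raw
(cross-species collisions / cells); `doublet_rate_extrapolated = 2 x` that
value estimates total doublets under a balanced design and is clearly
labelled as an extrapolation. UMIs (not reads) are the operative quantity
throughout. `autoplot()` draws the classic A-vs-B scatter.

## Time-associated genes

For one cell type observed over `S >= 3` ordered stages, each gene yields
two stage profiles: the mean expression per stage and the detection
fraction (share of cells with nonzero counts) per stage. Each profile is
correlated with the linear stage vector `1..S` by Spearman rank
correlation, and the null of no correlation is tested by permuting the
*stage-level values* — the correlation is defined over `S` stage summaries,
so the stage series is the exchangeable unit, and exact enumeration of all
`S!` orderings is feasible and removes Monte-Carlo noise (sampled
permutations take over beyond `S = 7`). P-values are two-sided; a gene is
called up- or down-regulated only when both p-values fall below `alpha`
and both correlations agree in sign. Genes with constant profiles have no
defined rank correlation and are flagged, never called.

The exact test is discrete: with `S = 5`, p-values live on the grid
`m/120`, the smallest attainable two-sided p is `2/120 ≈ 0.0167` (the
monotone profile and its reversal), and the next rung is already
`10/120 ≈ 0.083`. At `alpha = 0.05` the test therefore rejects a true null
with probability `2/120`, not 5% — it is conservative by construction, a
direct consequence of permuting five values. Users who need finer p-value
resolution at small `S` should aggregate fewer, better-estimated stage
summaries or add stages; the package reports the exact p rather than an
anti-conservative approximation.

## L1 centroid perturbation

Given any cells x D embedding (principal components, UMAP — the ledger is
embedding-agnostic and the choice is the caller's), cluster labels, and two
condition labels, `l1_perturbation()` computes per cluster the L1 distance
(sum of absolute coordinate differences) between the two condition
centroids, and as a comparison scale all pairwise L1 distances between
whole-cluster centroids. Overlap between the two distributions flags
clusters whose condition shift is as large as the separation between
distinct cell types. Clusters with fewer than 2 cells in either condition
are flagged and excluded from the within-distance rather than producing an
unstable centroid.

## Pseudocells and downsampling

`pseudocell_aggregate()` randomly partitions each cluster into groups of
`k = 50` cells and sums counts gene-wise; sums (not means) preserve count
semantics for downstream network inference. A remainder of at least `k/2`
cells stands alone, smaller remainders merge into the last full group, and
a cluster below `k/2` yields a single pseudocell with a warning. Total
counts are conserved exactly. `downsample_cells()` draws a seeded uniform
subset without replacement, for balancing conditions before merging.

## Numerical and engineering choices

* Seeds are mandatory for every random stage; the pipeline manifest records
  them together with a config hash and per-artifact MD5 checksums, and
  identical configs produce identical checksums.
* Barcode correction, demultiplexing and gene assignment are vectorised
  hash lookups (`match()` on precomputed k-mer tables); a 1.2-million-read
  library runs end to end in about a minute on one core.
* Counts are `Matrix::dgCMatrix` throughout, written and read as a
  MatrixMarket trio (`matrix.mtx`, `barcodes.tsv`, `features.tsv`, rows =
  cells); the round trip is lossless.
* Floating-point comparisons in the permutation test use a `1e-12` slack so
  ties in |rho| are counted as exceedances, the conservative direction.
* Test and verification scales were chosen to exercise every code path at
  full whitelist sizes while staying desk-sized: the end-to-end exactness
  check uses 500 cells at ~200 reads/cell; collision-rate recovery uses
  2,000 cells at ~650 reads/cell (about 1.2 million reads) with a planted
  10% doublet fraction; the statistic's calibration uses 2,000 null genes
  and 100 planted monotone genes over 5 stages of 200 cells.

## Known limitations

* The exact-containment assigner is intentionally unforgiving of cDNA
  errors; it validates counting logic, not mapping sensitivity.
* The simulator's error model is substitution-only and position-uniform.
* Same-species doublets are invisible to the purity metric and off by
  default in the simulator; the x2 extrapolation is a labelled estimate,
  not a measurement.
* The exact permutation test's conservativeness at small `S` (above) is a
  property of the statistic itself, not of this implementation.
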
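# chseq

Simulation, demultiplexing, quantification and quality control for
**combinatorial-hybridization split-pool single-cell RNA-seq** libraries,
plus the downstream statistics used to analyse them.

## The problem

Split-pool indexing barcodes single cells without droplets or wells: cells
are pooled and redistributed across barcoded plates in successive rounds,
so each cell accumulates a combination of well barcodes. In the
hybridization variant modelled here, reverse transcription adds the first
cell-barcode round (96 or 384 wells), oligo annealing without ligation adds
the second (768 wells), and PCR adds i5/i7 sample indices, giving a label
space of

    |bc1| x |bc2| x n_i5 x n_i7

combinations — 73,728 for 96 x 768 with one index pair, and above 10⁸ for
384 x 768 x 96 x 4. The computational pipeline must: extract and
error-correct the barcode segments of Read1 (delivered around an
on-instrument *dark cycle* window that skips fixed linker bases),
deduplicate molecules by UMI, assign cDNA reads to genes, build the digital
expression matrix, and quantify barcode collisions with a two-species
("barnyard") mixing design — a cell whose UMIs are not >85% from a single
species is labelled a **collision**.

`chseq` implements all of this against its own ground-truthed simulator, so
every stage is testable end to end without external data, and adds the
pipeline's in-house statistics:

* **time-associated genes** — for a cell type observed over S ordered
  stages, Spearman correlation of per-stage mean expression *and* detection
  fraction against the linear stage vector, with an exact stage-permutation
  p-value (all S! orderings enumerated for S ≤ 7);
* **L1 centroid perturbation** — per-cluster L1 distance between two
  conditions' centroids in any embedding, against the distribution of
  between-cluster centroid distances;
* **pseudocell aggregation** — seeded random partition of each cluster into
  groups of k = 50 cells, summed gene-wise, with exact count conservation.

## Worked example

Simulate a 500-cell barnyard library with 8% planted cross-species
doublets, realistic error and duplicate rates, then demultiplex, count and
classify:

```r
library(chseq)

scheme <- ch_default_scheme(n_bc1 = 96, n_bc2 = 768, n_i5 = 4, n_i7 = 4, seed = 1)
cfg    <- ch_sim_config(n_cells = 500, doublet_fraction = 0.08,
                        reads_per_cell = 400, barcode_error_rate = 0.005,
                        cdna_error_rate = 0.005, duplicate_rate = 0.3, seed = 2)
ref    <- generate_reference(50, seed = 3)

cells  <- generate_cells(cfg, scheme, ref)
lib    <- synthesize_reads(cells, ref, cfg, scheme)
dmx    <- demux_run(lib, scheme = scheme)
#> <ch_demux: 198479 reads, 92.1% assigned, 503 cell keys>

counts <- build_matrix(dmx$tagged, build_tx_index(ref))
#> <ch_counts: 503 cells x 100 genes, 78801 UMIs total>

bn <- barnyard_report(filter_cells(counts$matrix, 100), threshold = 0.85)
#> filter_cells: removed 76 of 503 cells (UMIs <= 100)
#> <ch_barnyard: 427 cells | 211 A, 182 B, 34 collisions (rate 0.080) | threshold 0.85>
```

Reading the numbers: 92.1% of reads survive index matching and barcode
correction at a 0.5% per-base error rate (the losses are dominated by the
exact-match i5/i7 policy); 503 cell keys appear because a few erroneous
barcode combinations still correct to valid wells; after the UMI filter the
collision rate of 8.0% recovers the planted 8% doublet fraction.
`tidy(bn)` returns the per-cell scatter table and `autoplot(bn)` draws the
classic species-A vs species-B UMI plot. `glance(bn)` also reports
`doublet_rate_extrapolated` (2x the raw rate), a labelled estimate
accounting for unseen same-species doublets.

The downstream statistics work on any cells x genes matrix:

```r
res <- time_assoc_genes(mat, stages, c("D30", "D35", "D45", "D50", "D70"))
tidy(res)      # per-gene rho and exact permutation p at both levels
led <- l1_perturbation(embedding, clusters, conditions)
autoplot(led)  # within- vs between-cluster L1 histogram
agg <- pseudocell_aggregate(mat, clusters, k = 50, seed = 1)
```

A command-line interface wrapping these functions is installed at
`exec/chseq` (`chseq simulate|demux|count|barnyard|stats|run`, YAML config,
JSON reports); `run_pipeline()` executes simulate → demux → count →
barnyard under one config and writes a manifest with seeds, a config hash
and per-artifact checksums.

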
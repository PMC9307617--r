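test_that("reference generation is seed-deterministic with distinct sequences", {
  r1 <- generate_reference(20L, seed = 1L)
  r2 <- generate_reference(20L, seed = 1L)
  expect_identical(r1, r2)
  expect_false(anyDuplicated(r1$sequence) > 0)
  expect_identical(nrow(generate_reference(1L, seed = 2L)), 2L)  # one gene per species
  expect_setequal(unique(r1$species), c("A", "B"))
  expect_true(all(nchar(r1$sequence) >= 300 & nchar(r1$sequence) <= 2000))

  d <- withr::local_tempdir()
  write_reference(r1, file.path(d, "ref.fa"), file.path(d, "ann.tsv"))
  back <- read_reference(file.path(d, "ref.fa"), file.path(d, "ann.tsv"))
  expect_identical(back$sequence, r1$sequence)
  expect_identical(back$gene_id, r1$gene_id)
})

test_that("cell generation honours doublet rounding and barcode uniqueness", {
  sch <- tiny_scheme()
  ref <- tiny_reference()
  cfg0 <- ch_sim_config(n_cells = 50L, doublet_fraction = 0, seed = 3L)
  cells0 <- generate_cells(cfg0, sch, ref)
  expect_identical(sum(cells0$cells$species == "doublet"), 0L)

  cfg <- ch_sim_config(n_cells = 100L, doublet_fraction = 0.1, seed = 3L)
  cells <- generate_cells(cfg, sch, ref)
  expect_identical(sum(cells$cells$species == "doublet"), 10L)
  key <- with(cells$cells, paste(i7, i5, bc2, bc1))
  expect_false(anyDuplicated(key) > 0)
  expect_equal(unname(rowSums(cells$weights)), rep(1, 100), tolerance = 1e-12)
  # singlets draw from exactly one species; doublets from both
  gene_sp <- ref$species[match(colnames(cells$weights), ref$gene_id)]
  for (i in seq_len(100)) {
    sp_used <- unique(gene_sp[cells$weights[i, ] > 0])
    if (cells$cells$species[i] == "doublet") {
      expect_setequal(sp_used, c("A", "B"))
    } else {
      expect_identical(sp_used, cells$cells$species[i])
    }
  }
  big <- ch_sim_config(n_cells = 12L * 24L * 2L * 2L + 1L, seed = 1L)
  expect_error(generate_cells(big, sch, ref), "exceeds")
})

test_that("error injection matches its rate and reports positions", {
  r0 <- inject_errors(strrep("ACGT", 25L), 0, seed = 1L)
  expect_identical(r0$seq, strrep("ACGT", 25L))
  expect_length(r0$positions, 0L)

  r1 <- inject_errors(strrep("ACGT", 25L), 1, seed = 1L)
  expect_length(r1$positions, 100L)
  expect_true(all(strsplit(r1$seq, "")[[1]] != strsplit(strrep("ACGT", 25L), "")[[1]]))

  long <- strrep("A", 100000L)
  r <- inject_errors(long, 0.01, seed = 7L)
  n <- length(r$positions)
  sd3 <- 3 * sqrt(1e5 * 0.01 * 0.99)
  expect_lt(abs(n - 1000), sd3)
  expect_identical(unique(substring(r$seq, r$positions, r$positions)) %in%
                     c("C", "G", "T"), rep(TRUE, length(unique(substring(r$seq, r$positions, r$positions)))))
})

test_that("synthesized libraries are deterministic and truth-complete", {
  sim1 <- tiny_library(seed = 9L, barcode_error_rate = 0.01,
                       cdna_error_rate = 0.01, duplicate_rate = 0.3)
  sim2 <- tiny_library(seed = 9L, barcode_error_rate = 0.01,
                       cdna_error_rate = 0.01, duplicate_rate = 0.3)
  expect_identical(sim1$lib, sim2$lib)

  lib <- sim1$lib
  expect_identical(length(lib$read1), nrow(lib$truth))
  expect_identical(length(lib$read2), nrow(lib$truth))
  expect_false(anyDuplicated(lib$truth$read_id) > 0)
  # read totals match the per-cell targets drawn in generate_cells
  expect_identical(nrow(lib$truth), sum(sim1$cells$cells$target_reads))
  expect_identical(as.integer(table(lib$truth$cell_id)[sim1$cells$cells$cell_id]),
                   as.integer(sim1$cells$cells$target_reads))
})

test_that("zero error rates give whitelist-exact segments and exact substrings", {
  sim <- tiny_library(seed = 4L)
  lib <- sim$lib
  seg <- parse_read1(lib$read1, sim$scheme$layout)
  expect_true(all(seg$bc1 %in% sim$scheme$bc1$sequences))
  expect_true(all(seg$bc2 %in% sim$scheme$bc2$sequences))
  expect_identical(seg$bc1, lib$truth$bc1)
  expect_identical(seg$bc2, lib$truth$bc2)
  expect_identical(seg$umi, lib$truth$umi)
  # every read2 is an exact substring of its source transcript
  tx <- sim$ref$sequence[match(lib$truth$tx_id, sim$ref$transcript_id)]
  expect_identical(substr(tx, lib$truth$r2_start,
                          lib$truth$r2_start + nchar(lib$read2) - 1L),
                   lib$read2)
})

test_that("written FASTQ libraries are byte-identical across runs", {
  sch <- tiny_scheme()
  cfg <- ch_sim_config(n_cells = 10L, reads_per_cell = 20, seed = 21L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_library(cfg, sch, out_dir = d1, n_genes_per_species = 5L)
  simulate_library(cfg, sch, out_dir = d2, n_genes_per_species = 5L)
  for (f in c("sim_R1.fastq.gz", "sim_R2.fastq.gz", "reference.fasta",
              "truth.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     label = f)
  }
})
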
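test_that("seed-and-verify assignment finds true genes and rejects junk", {
  ref <- tiny_reference(n_genes = 6L, seed = 8L)
  idx <- build_tx_index(ref)
  # error-free fragments map to their source gene
  set.seed(2)
  rows <- sample.int(nrow(ref), 50L, replace = TRUE)
  starts <- vapply(rows, function(i) sample.int(nchar(ref$sequence[i]) - 99L, 1L), 1L)
  reads <- substr(ref$sequence[rows], starts, starts + 99L)
  expect_identical(assign_genes(reads, idx), ref$gene_id[rows])
  # random sequences are absent from the reference
  junk <- chseq:::random_dna(50L, 100L)
  expect_false(any(vapply(junk, function(r) {
    any(grepl(r, ref$sequence, fixed = TRUE))
  }, logical(1))))
  expect_identical(assign_genes(junk, idx), rep("unassigned", 50L))
  # too short for the seed
  expect_identical(assign_genes("ACGT", idx), "unassigned")
})

test_that("sequence shared verbatim by two genes is multimapped", {
  shared <- chseq:::random_dna(1L, 400L)
  ref <- tibble::tibble(
    transcript_id = c("A_g1_tx1", "B_g2_tx1"),
    gene_id = c("A_g1", "B_g2"),
    species = c("A", "B"),
    sequence = c(paste0(shared, chseq:::random_dna(1L, 100L)),
                 paste0(chseq:::random_dna(1L, 100L), shared)))
  class(ref) <- c("ch_reference", class(ref))
  idx <- build_tx_index(ref)
  read <- substr(shared, 50L, 149L)
  expect_identical(assign_genes(read, idx), "multimapped")
})

test_that("UMI deduplication: exact-unique counts and directional collapse", {
  tagged <- tibble::tibble(
    cell_key = "c1", gene_id = "g1",
    umi = c(rep("AAAA", 5), rep("AAAT", 1), rep("CCCC", 3)))
  expect_identical(dedup_umis(tagged)$molecules, 3L)
  expect_identical(dedup_umis(tagged, "directional")$molecules,
                   bf_directional(c("AAAA", "AAAT", "CCCC"), c(5L, 1L, 3L)))
  expect_identical(dedup_umis(tagged, "directional")$molecules, 2L)
  # 5 reads of one UMI -> one molecule; empty input -> zero rows
  one <- tibble::tibble(cell_key = "c", gene_id = "g", umi = rep("GGGG", 5))
  expect_identical(dedup_umis(one)$molecules, 1L)
  expect_identical(nrow(dedup_umis(one[0, ])), 0L)
})

test_that("directional collapse matches brute force on random groups", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    umis <- unique(chseq:::random_dna(n, 4L))
    reads <- sample(1:20, length(umis), replace = TRUE)
    tagged <- tibble::tibble(cell_key = "c", gene_id = "g",
                             umi = rep(umis, reads))
    expect_identical(dedup_umis(tagged, "directional")$molecules,
                     bf_directional(umis, reads))
  }
})

test_that("error-free pipeline reproduces the truth molecule table exactly", {
  sim <- tiny_library(seed = 19L, duplicate_rate = 0.4)
  dmx <- demux_run(sim$lib, scheme = sim$scheme)
  counts <- build_matrix(dmx$tagged, build_tx_index(sim$ref))
  truth <- truth_molecule_table(sim$lib$truth)
  got <- Matrix::summary(counts$matrix)
  got <- tibble::tibble(cell_key = rownames(counts$matrix)[got$i],
                        gene_id = colnames(counts$matrix)[got$j],
                        molecules = as.integer(got$x)) |>
    dplyr::arrange(cell_key, gene_id)
  expect_identical(got, truth)
  # conservation: matrix total equals per-cell UMI totals
  expect_identical(as.numeric(sum(counts$matrix)),
                   as.numeric(sum(counts$cell_stats$umis)))
  expect_true(all(counts$cell_stats$umis <= counts$cell_stats$reads))
  expect_true(all(counts$cell_stats$genes <= counts$cell_stats$umis))
  expect_identical(counts$cell_stats$umis_a + counts$cell_stats$umis_b,
                   counts$cell_stats$umis)
  # cells from one species have zero UMIs on the other
  singlets <- sim$cells$cells
  a_cells <- singlets$cell_id[singlets$species == "A"]
  a_keys <- sim$lib$truth$cell_key[match(a_cells, sim$lib$truth$cell_id)]
  stats_a <- counts$cell_stats[counts$cell_stats$cell_key %in% a_keys, ]
  expect_true(all(stats_a$umis_b == 0))
})

test_that("UMI filter boundary is strict by default and configurable", {
  m <- Matrix::sparseMatrix(i = 1:3, j = rep(1, 3), x = c(199, 200, 201),
                            dims = c(3, 2),
                            dimnames = list(c("c199", "c200", "c201"),
                                            c("g1", "g2")))
  m <- methods::as(m, "dgCMatrix")
  expect_message(f <- filter_cells(m, 200L), "removed 2 of 3")
  expect_identical(rownames(f), "c201")
  expect_message(f2 <- filter_cells(m, 200L, strict = FALSE), "removed 1 of 3")
  expect_identical(rownames(f2), c("c200", "c201"))
  expect_error(filter_cells(m, -1L), ">= 0")
  expect_warning(filter_cells(m[0, , drop = FALSE]), "empty")
})

test_that("MatrixMarket trio round-trips losslessly", {
  sim <- tiny_library(seed = 29L, n_cells = 15L, reads_per_cell = 40)
  dmx <- demux_run(sim$lib, scheme = sim$scheme)
  counts <- build_matrix(dmx$tagged, build_tx_index(sim$ref))
  d <- withr::local_tempdir()
  write_matrix_dir(counts$matrix, d)
  back <- read_matrix_dir(d)
  expect_identical(as.matrix(back), as.matrix(counts$matrix))
  expect_identical(attr(back, "species"), attr(counts$matrix, "species"))
})

test_that("assigned fraction decreases monotonically with barcode error rate", {
  sch <- tiny_scheme()
  ref <- tiny_reference()
  rates <- c(0, 0.02, 0.08)
  for (seed in c(101L, 202L, 303L)) {
    fr <- vapply(rates, function(r) {
      sim <- tiny_library(seed = seed, barcode_error_rate = r,
                          n_cells = 25L, reads_per_cell = 40,
                          scheme = sch, ref = ref)
      demux_run(sim$lib, scheme = sch)$report$assigned_fraction
    }, 1)
    expect_true(all(diff(fr) < 0))
  }
})
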
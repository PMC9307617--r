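#' Simulation settings for a synthetic split-pool library
#'
#' Defines the study conditions for a simulated two-species (barnyard)
#' experiment: number of cells, cross-species doublet fraction, read depth
#' distribution, per-base substitution error rates, and PCR duplication.
#' Reads per cell are lognormal with mean `reads_per_cell` and log-scale
#' spread `depth_sdlog`. Doublets are barcode collisions carrying a 50:50
#' expression mixture of one species-A and one species-B profile.
#'
#' @param n_cells Number of barcoded cells.
#' @param doublet_fraction Fraction of cells that are cross-species
#'   doublets; the realised count is `round(doublet_fraction * n_cells)`.
#' @param reads_per_cell Mean sequenced reads per cell.
#' @param depth_sdlog Log-normal sigma of per-cell depth variation.
#' @param barcode_error_rate Per-base substitution probability in Read1
#'   segments and the i5/i7 indices.
#' @param cdna_error_rate Per-base substitution probability in Read2.
#' @param duplicate_rate Fraction of reads that are PCR re-reads of an
#'   already sampled molecule (0 = every read is a distinct molecule).
#' @param species_ratio Fraction of singlet cells from species A.
#' @param seed Integer seed; mandatory, every random stage derives from it.
#' @return A `ch_sim_config` list.
#' @export
ch_sim_config <- function(n_cells = 1000L, doublet_fraction = 0.05,
                          reads_per_cell = 500, depth_sdlog = 0.35,
                          barcode_error_rate = 0.005,
                          cdna_error_rate = 0.005,
                          duplicate_rate = 0.3,
                          species_ratio = 0.5,
                          seed = NULL) {
  if (is.null(seed)) stop("ch_sim_config() requires an explicit seed", call. = FALSE)
  stopifnot(n_cells >= 1L,
            doublet_fraction >= 0, doublet_fraction <= 1,
            barcode_error_rate >= 0, barcode_error_rate <= 1,
            cdna_error_rate >= 0, cdna_error_rate <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            species_ratio >= 0, species_ratio <= 1,
            reads_per_cell >= 1)
  structure(list(n_cells = as.integer(n_cells),
                 doublet_fraction = doublet_fraction,
                 reads_per_cell = reads_per_cell,
                 depth_sdlog = depth_sdlog,
                 barcode_error_rate = barcode_error_rate,
                 cdna_error_rate = cdna_error_rate,
                 duplicate_rate = duplicate_rate,
                 species_ratio = species_ratio,
                 seed = as.integer(seed)),
            class = "ch_sim_config")
}

#' Generate a synthetic two-species transcript reference
#'
#' Random transcript sequences (uniform ACGT) for two synthetic species
#' labelled A and B, one transcript per gene by default, with lengths drawn
#' uniformly in `len_range`. Gene ids carry the species prefix
#' (`A_gene0001`, ...). The draw is deterministic given the seed.
#'
#' @param n_genes_per_species Genes per species.
#' @param seed Integer seed.
#' @param len_range Transcript length range in nt.
#' @param transcripts_per_gene Transcripts per gene.
#' @return A `ch_reference`: tibble of `transcript_id`, `gene_id`,
#'   `species`, `sequence` with class attached.
#' @export
generate_reference <- function(n_genes_per_species, seed,
                               len_range = c(300L, 2000L),
                               transcripts_per_gene = 1L) {
  stopifnot(n_genes_per_species >= 1L, transcripts_per_gene >= 1L)
  local_rng(seed)
  rows <- purrr::map(c("A", "B"), function(sp) {
    gene_id <- sprintf("%s_gene%04d", sp, seq_len(n_genes_per_species))
    gene_id <- rep(gene_id, each = transcripts_per_gene)
    tx_n <- rep(seq_len(transcripts_per_gene), times = n_genes_per_species)
    lens <- sample(seq(len_range[1], len_range[2]), length(gene_id),
                   replace = TRUE)
    seqs <- vapply(lens, function(L) paste(sample(c("A", "C", "G", "T"), L,
                                                  replace = TRUE),
                                           collapse = ""), "")
    tibble::tibble(transcript_id = sprintf("%s_tx%d", gene_id, tx_n),
                   gene_id = gene_id, species = sp, sequence = seqs)
  })
  ref <- dplyr::bind_rows(rows)
  if (anyDuplicated(ref$sequence)) {
    # astronomically unlikely for >=300 nt random sequences; regenerate dupes
    dup <- which(duplicated(ref$sequence))
    for (i in dup) {
      ref$sequence[i] <- paste(sample(c("A", "C", "G", "T"),
                                      nchar(ref$sequence[i]),
                                      replace = TRUE), collapse = "")
    }
  }
  class(ref) <- c("ch_reference", class(ref))
  ref
}

#' Write a reference as FASTA plus annotation TSV
#'
#' @param ref A `ch_reference`.
#' @param fasta_path,annot_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_reference <- function(ref, fasta_path, annot_path) {
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- ref$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  write.table(ref[, c("transcript_id", "gene_id", "species")],
              annot_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, annotation = annot_path))
}

#' Read a reference from FASTA plus annotation TSV
#'
#' @param fasta_path FASTA of transcript sequences, ids matching the
#'   annotation's `transcript_id` column.
#' @param annot_path TSV with columns `transcript_id`, `gene_id`, `species`.
#' @return A `ch_reference`.
#' @export
read_reference <- function(fasta_path, annot_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- tibble::as_tibble(read.delim(annot_path, stringsAsFactors = FALSE))
  stopifnot(all(c("transcript_id", "gene_id", "species") %in% names(ann)))
  ids <- sub("\\s.*$", "", names(seqs))
  hit <- match(ann$transcript_id, ids)
  if (anyNA(hit)) stop("annotation transcript ids missing from FASTA", call. = FALSE)
  ann$sequence <- unname(as.character(seqs))[hit]
  class(ann) <- c("ch_reference", class(ann))
  ann
}

#' Draw the simulated cell population
#'
#' Assigns each cell a unique barcode tuple (sampled without replacement
#' from the scheme's combination space), a species (or cross-species doublet
#' status), a per-gene expression weight vector and a target read count.
#' Singlets draw genes from exactly one species; doublets mix one profile
#' from each species 50:50. The number of doublets is exactly
#' `round(doublet_fraction * n_cells)`.
#'
#' @param cfg A `ch_sim_config`.
#' @param scheme A `ch_scheme`.
#' @param ref A `ch_reference`.
#' @return A list with `cells` (tibble: `cell_id`, `species` in
#'   `{A, B, doublet}`, barcode ids and sequences, `target_reads`) and
#'   `weights` (cells x genes expression weight matrix, rows summing to 1).
#' @export
generate_cells <- function(cfg, scheme, ref) {
  stopifnot(inherits(cfg, "ch_sim_config"), inherits(scheme, "ch_scheme"))
  space <- combination_count(scheme,
                             n_i5 = length(scheme$i5$sequences),
                             n_i7 = length(scheme$i7$sequences))
  if (cfg$n_cells > space) {
    stop(sprintf("n_cells (%d) exceeds barcode combination space (%.0f)",
                 cfg$n_cells, space), call. = FALSE)
  }
  local_rng(cfg$seed + 1L)
  n <- cfg$n_cells

  draw_tuples <- function(n) {
    tibble::tibble(
      bc1 = sample.int(length(scheme$bc1$sequences), n, replace = TRUE),
      bc2 = sample.int(length(scheme$bc2$sequences), n, replace = TRUE),
      i5 = sample.int(length(scheme$i5$sequences), n, replace = TRUE),
      i7 = sample.int(length(scheme$i7$sequences), n, replace = TRUE))
  }
  tuples <- draw_tuples(n)
  key <- function(t) paste(t$i7, t$i5, t$bc2, t$bc1, sep = ".")
  while (anyDuplicated(key(tuples))) {
    dup <- which(duplicated(key(tuples)))
    tuples[dup, ] <- draw_tuples(length(dup))
  }

  n_doublet <- round(cfg$doublet_fraction * n)
  status <- rep("singlet", n)
  if (n_doublet > 0) status[sample.int(n, n_doublet)] <- "doublet"
  singlet_species <- sample(c("A", "B"), n, replace = TRUE,
                            prob = c(cfg$species_ratio, 1 - cfg$species_ratio))
  species <- ifelse(status == "doublet", "doublet", singlet_species)

  genes <- unique(ref$gene_id)
  gene_species <- ref$species[match(genes, ref$gene_id)]
  # per-species baseline abundance (lognormal) with per-cell gamma jitter
  base <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1)
  weights <- matrix(0, nrow = n, ncol = length(genes),
                    dimnames = list(NULL, genes))
  profile <- function(sp) {
    w <- base * stats::rgamma(length(genes), shape = 5, rate = 5)
    w[gene_species != sp] <- 0
    w / sum(w)
  }
  for (i in seq_len(n)) {
    weights[i, ] <- if (species[i] == "doublet") {
      0.5 * profile("A") + 0.5 * profile("B")
    } else {
      profile(species[i])
    }
  }

  target_reads <- pmax(1L, as.integer(round(stats::rlnorm(
    n, meanlog = log(cfg$reads_per_cell) - cfg$depth_sdlog^2 / 2,
    sdlog = cfg$depth_sdlog))))

  cells <- tibble::tibble(
    cell_id = sprintf("cell%05d", seq_len(n)),
    species = species,
    bc1 = tuples$bc1, bc2 = tuples$bc2, i5 = tuples$i5, i7 = tuples$i7,
    bc1_seq = scheme$bc1$sequences[tuples$bc1],
    bc2_seq = scheme$bc2$sequences[tuples$bc2],
    i5_seq = scheme$i5$sequences[tuples$i5],
    i7_seq = scheme$i7$sequences[tuples$i7],
    target_reads = target_reads)
  list(cells = cells, weights = weights)
}

#' Substitute bases at a fixed per-base error rate
#'
#' Each position is independently replaced by one of the three other bases
#' with probability `rate`.
#'
#' @param seq A single DNA string.
#' @param rate Per-base substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `seq` (mutated string) and `positions` (1-based
#'   positions that were substituted).
#' @export
inject_errors <- function(seq, rate, seed) {
  stopifnot(length(seq) == 1L, rate >= 0, rate <= 1)
  local_rng(seed)
  res <- inject_errors_vec(seq, rate)
  pos <- which(utf8ToInt(res$seqs) != utf8ToInt(seq))
  list(seq = res$seqs, positions = pos)
}

# Vectorised substitution errors over many sequences (uses the current RNG
# stream). Positions are swept column-wise so the work is O(width) vector ops.
# Returns mutated sequences and per-sequence error counts.
inject_errors_vec <- function(seqs, rate) {
  n_err <- integer(length(seqs))
  if (rate > 0 && length(seqs) > 0) {
    widths <- nchar(seqs)
    bases <- c("A", "C", "G", "T")
    for (p in seq_len(max(widths))) {
      live <- which(widths >= p)
      hit <- live[runif(length(live)) < rate]
      if (length(hit) == 0L) next
      orig <- match(substr(seqs[hit], p, p), bases)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      repl <- bases[((orig - 1L + shift) %% 4L) + 1L]
      substr(seqs[hit], p, p) <- repl
      n_err[hit] <- n_err[hit] + 1L
    }
  }
  list(seqs = seqs, n_err = n_err)
}

#' Synthesize paired reads and the ground-truth table
#'
#' Emits one Read1/Read2 pair per sequenced read. Read1 is the concatenation
#' of the delivered layout segments (cell barcodes and UMI) with per-base
#' substitution errors at `barcode_error_rate`; Read2 is a substring of the
#' molecule's transcript with errors at `cdna_error_rate`; the (possibly
#' errored) i5/i7 index reads are carried in the FASTQ header comment as
#' `i5:SEQ i7:SEQ`. Molecules get uniform random UMIs; reads resample
#' molecules with replacement when `duplicate_rate > 0`, reproducing PCR
#' duplicate structure. The truth table records, per read, the true cell,
#' gene, UMI and pre-error barcode segments plus per-segment error counts.
#'
#' @param cells Output of [generate_cells()].
#' @param ref A `ch_reference`.
#' @param cfg A `ch_sim_config`.
#' @param scheme A `ch_scheme`.
#' @return A list: `read1`, `read2` (character vectors), `headers`
#'   (FASTA/FASTQ description lines), and `truth` (tibble, one row per read
#'   pair).
#' @export
synthesize_reads <- function(cells, ref, cfg, scheme) {
  stopifnot(inherits(cfg, "ch_sim_config"), inherits(scheme, "ch_scheme"))
  local_rng(cfg$seed + 2L)
  layout <- scheme$layout
  genes <- colnames(cells$weights)
  tab <- cells$cells

  per_cell <- purrr::map(seq_len(nrow(tab)), function(i) {
    n_reads <- tab$target_reads[i]
    n_mol <- max(1L, as.integer(round(n_reads * (1 - cfg$duplicate_rate))))
    mol_gene <- sample.int(length(genes), n_mol, replace = TRUE,
                           prob = cells$weights[i, ])
    mol_umi <- random_dna(n_mol, layout$umi_length)
    mol_of_read <- if (cfg$duplicate_rate == 0) {
      seq_len(n_reads)
    } else {
      sample.int(n_mol, n_reads, replace = TRUE)
    }
    tibble::tibble(cell_row = i, gene_idx = mol_gene[mol_of_read],
                   umi = mol_umi[mol_of_read])
  })
  reads <- dplyr::bind_rows(per_cell)
  n <- nrow(reads)
  ci <- reads$cell_row

  # choose a transcript per read (uniform among the gene's transcripts)
  gene_id <- genes[reads$gene_idx]
  tx_by_gene <- split(seq_len(nrow(ref)), ref$gene_id)
  tx_row <- vapply(gene_id, function(g) {
    rows <- tx_by_gene[[g]]
    if (length(rows) == 1L) rows else rows[sample.int(length(rows), 1L)]
  }, 1L, USE.NAMES = FALSE)
  tx_len <- nchar(ref$sequence[tx_row])
  r2_len <- pmin(layout$read2_length, tx_len)
  r2_start <- floor(runif(n) * (tx_len - r2_len + 1)) + 1L
  read2_true <- substr(ref$sequence[tx_row], r2_start, r2_start + r2_len - 1L)

  seg_true <- list(bc2 = tab$bc2_seq[ci], bc1 = tab$bc1_seq[ci],
                   umi = reads$umi)
  seg_obs <- list(); seg_err <- list()
  for (nm in names(layout$segments)) {
    s <- if (nm == "fixed") {
      rep(strrep("A", layout$segments[[nm]]), n)
    } else seg_true[[nm]]
    mut <- inject_errors_vec(s, cfg$barcode_error_rate)
    seg_obs[[nm]] <- mut$seqs
    seg_err[[nm]] <- mut$n_err
  }
  read1 <- do.call(paste0, seg_obs[names(layout$segments)])

  i5_mut <- inject_errors_vec(tab$i5_seq[ci], cfg$barcode_error_rate)
  i7_mut <- inject_errors_vec(tab$i7_seq[ci], cfg$barcode_error_rate)
  r2_mut <- inject_errors_vec(read2_true, cfg$cdna_error_rate)

  read_id <- sprintf("r%09d", seq_len(n))
  headers <- paste0(read_id, " i5:", i5_mut$seqs, " i7:", i7_mut$seqs)

  truth <- tibble::tibble(
    read_id = read_id,
    cell_id = tab$cell_id[ci],
    species = tab$species[ci],
    gene_id = gene_id,
    umi = reads$umi,
    bc1 = tab$bc1_seq[ci], bc2 = tab$bc2_seq[ci],
    i5 = tab$i5_seq[ci], i7 = tab$i7_seq[ci],
    cell_key = paste(tab$i7_seq[ci], tab$i5_seq[ci],
                     tab$bc2_seq[ci], tab$bc1_seq[ci], sep = "-"),
    err_bc1 = seg_err$bc1, err_bc2 = seg_err$bc2, err_umi = seg_err$umi,
    err_i5 = i5_mut$n_err, err_i7 = i7_mut$n_err, err_read2 = r2_mut$n_err,
    tx_id = ref$transcript_id[tx_row], r2_start = as.integer(r2_start))

  list(read1 = read1, read2 = r2_mut$seqs, headers = headers, truth = truth)
}

#' Ground-truth molecule table
#'
#' Collapses a read-level truth table to the distinct molecules that were
#' actually sequenced: one row per (cell, gene, UMI). This is what a perfect
#' demultiplex + UMI deduplication recovers when error rates are zero.
#'
#' @param truth Truth tibble from [synthesize_reads()].
#' @return Tibble of `cell_key`, `gene_id`, `molecules` (distinct UMIs).
#' @export
truth_molecule_table <- function(truth) {
  truth |>
    dplyr::distinct(.data$cell_key, .data$gene_id, .data$umi) |>
    dplyr::count(.data$cell_key, .data$gene_id, name = "molecules") |>
    dplyr::arrange(.data$cell_key, .data$gene_id)
}

#' Simulate a complete library to disk
#'
#' Runs [generate_cells()] and [synthesize_reads()] and writes the paired
#' FASTQ files (gzipped), the reference FASTA + annotation TSV, the truth
#' table TSV and a cells TSV into `out_dir`. Deterministic given
#' `cfg$seed`: identical configs produce byte-identical outputs.
#'
#' @param cfg A `ch_sim_config`.
#' @param scheme A `ch_scheme`.
#' @param ref A `ch_reference`; generated from `cfg$seed` when `NULL`.
#' @param out_dir Output directory (created if missing).
#' @param n_genes_per_species Reference size when `ref` is `NULL`.
#' @return Invisibly, a list of output paths plus the in-memory `truth`
#'   tibble and `cells`.
#' @export
simulate_library <- function(cfg, scheme, ref = NULL, out_dir,
                             n_genes_per_species = 50L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(ref)) {
    ref <- generate_reference(n_genes_per_species, seed = cfg$seed + 7L)
  }
  cells <- generate_cells(cfg, scheme, ref)
  lib <- synthesize_reads(cells, ref, cfg, scheme)
  paths <- list(
    r1 = file.path(out_dir, "sim_R1.fastq.gz"),
    r2 = file.path(out_dir, "sim_R2.fastq.gz"),
    fasta = file.path(out_dir, "reference.fasta"),
    annotation = file.path(out_dir, "annotation.tsv"),
    truth_path = file.path(out_dir, "truth.tsv"),
    cells_path = file.path(out_dir, "cells.tsv"))
  write_fastq(lib$read1, lib$headers, paths$r1)
  write_fastq(lib$read2, lib$headers, paths$r2)
  write_reference(ref, paths$fasta, paths$annotation)
  write.table(lib$truth, paths$truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cells$cells, paths$cells_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, list(truth = lib$truth, cells = cells$cells,
                          reference = ref)))
}
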
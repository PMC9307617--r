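#' Read and validate a pipeline configuration
#'
#' YAML with sections `scheme`, `simulation`, `quantify`, `qc` and `paths`.
#' Every random stage must carry an explicit seed; thresholds are checked
#' against their documented ranges. Missing optional fields take the
#' package defaults.
#'
#' @param config Path to a YAML file, or an equivalent nested list.
#' @return The validated config list (class `ch_config`).
#' @export
read_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML file or a list", call. = FALSE)
  defaults <- list(
    scheme = list(n_bc1 = 96L, n_bc2 = 768L, n_i5 = 4L, n_i7 = 4L,
                  min_dist = 3L, max_mismatch = 1L),
    simulation = list(n_cells = 1000L, doublet_fraction = 0.05,
                      reads_per_cell = 500, depth_sdlog = 0.35,
                      barcode_error_rate = 0.005, cdna_error_rate = 0.005,
                      duplicate_rate = 0.3, species_ratio = 0.5,
                      n_genes_per_species = 50L),
    quantify = list(min_umi = 200L, umi_policy = "exact", k = 21L),
    qc = list(threshold = 0.85),
    paths = list(out_dir = "chseq_out"))
  for (sec in names(defaults)) {
    cfg[[sec]] <- utils::modifyList(defaults[[sec]], cfg[[sec]] %||% list())
  }
  for (sec in c("scheme", "simulation")) {
    if (is.null(cfg[[sec]]$seed)) {
      stop(sprintf("config section '%s' is missing a seed", sec), call. = FALSE)
    }
  }
  if (cfg$qc$threshold <= 0.5 || cfg$qc$threshold > 1) {
    stop("qc threshold must be in (0.5, 1]", call. = FALSE)
  }
  if (cfg$quantify$min_umi < 0) stop("min_umi must be >= 0", call. = FALSE)
  structure(cfg, class = c("ch_config", "list"))
}

#' Run the full pipeline: simulate, demultiplex, count, barnyard QC
#'
#' Executes the stages in order under one validated config, writes every
#' artifact (FASTQ pair, reference, truth table, assignment table, demux
#' report, MatrixMarket trio, cell stats, barnyard report) under
#' `paths$out_dir`, and records a manifest of stage outputs with MD5
#' checksums, the seeds used and a hash of the config. Identical configs
#' produce identical manifests.
#'
#' @param config Path to a YAML config or a config list (see
#'   [read_config()]).
#' @return Invisibly, a list: `manifest` tibble, `report` (per-stage
#'   summaries), and the in-memory `counts`, `barnyard` and `demux`
#'   objects.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  scheme <- run_stage("scheme", do.call(ch_default_scheme, cfg$scheme))
  sim_args <- cfg$simulation
  n_genes <- sim_args$n_genes_per_species
  sim_args$n_genes_per_species <- NULL
  sim_cfg <- run_stage("config", do.call(ch_sim_config, sim_args))
  sim <- run_stage("simulate",
                   simulate_library(sim_cfg, scheme, out_dir = out_dir,
                                    n_genes_per_species = n_genes))
  dmx <- run_stage("demux", demux_run(sim$r1, sim$r2, scheme))
  assign_path <- file.path(out_dir, "assignments.tsv")
  write.table(dmx$assignments, assign_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(dmx$report, file.path(out_dir, "demux_report.json"),
                       auto_unbox = TRUE, digits = NA)

  ref <- sim$reference
  idx <- run_stage("index", build_tx_index(ref, k = cfg$quantify$k))
  counts <- run_stage("count",
                      build_matrix(dmx$tagged, idx,
                                   umi_policy = cfg$quantify$umi_policy))
  mat_dir <- file.path(out_dir, "matrix")
  write_matrix_dir(counts$matrix, mat_dir)
  write.table(counts$cell_stats, file.path(out_dir, "cell_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  filtered <- run_stage("filter",
                        suppressMessages(filter_cells(counts$matrix,
                                                      cfg$quantify$min_umi)))
  bn <- run_stage("barnyard", barnyard_report(filtered, cfg$qc$threshold))
  write.table(bn$cells, file.path(out_dir, "barnyard_cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bn$summary[setdiff(names(bn$summary), "per_label")],
                       file.path(out_dir, "barnyard_report.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- c(r1 = sim$r1, r2 = sim$r2, fasta = sim$fasta,
             annotation = sim$annotation, truth = sim$truth_path,
             assignments = assign_path,
             matrix = file.path(mat_dir, "matrix.mtx"),
             barcodes = file.path(mat_dir, "barcodes.tsv"),
             features = file.path(mat_dir, "features.tsv"),
             cell_stats = file.path(out_dir, "cell_stats.tsv"),
             barnyard = file.path(out_dir, "barnyard_cells.tsv"))
  manifest <- tibble::tibble(
    stage = c("simulate", "simulate", "simulate", "simulate", "simulate",
              "demux", "count", "count", "count", "count", "barnyard"),
    file = basename(unname(files)),
    md5 = unname(tools::md5sum(unname(files))))
  manifest_all <- list(
    package_version = as.character(utils::packageVersion("chseq")),
    config_hash = digest_config(cfg),
    seeds = list(scheme = cfg$scheme$seed, simulation = cfg$simulation$seed),
    stages = c("scheme", "simulate", "demux", "count", "filter", "barnyard"),
    files = purrr::map2(manifest$file, manifest$md5,
                        function(f, m) list(file = f, md5 = m)))
  jsonlite::write_json(manifest_all, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, manifest_path = file.path(out_dir, "manifest.json"),
                 config = cfg, scheme = scheme, sim = sim, demux = dmx,
                 counts = counts, filtered = filtered, barnyard = bn))
}

# Stable MD5 of a config list (serialised to canonical YAML text).
digest_config <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[sort(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}
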
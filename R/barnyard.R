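#' Per-cell species UMI fractions
#'
#' For a two-species (barnyard) matrix, computes each cell's total UMIs and
#' the fraction attributed to each species. Cells with zero UMIs carry no
#' evidence and are excluded with a warning.
#'
#' @param mat Cells x genes count matrix with a `species` attribute (or a
#'   `ch_counts`).
#' @param species Per-gene species tags; defaults to the matrix attribute.
#' @return Tibble: `cell_key`, `umis`, `umis_a`, `umis_b`, `frac_a`,
#'   `frac_b` (fractions sum to 1).
#' @export
species_fractions <- function(mat, species = NULL) {
  m <- if (inherits(mat, "ch_counts")) mat$matrix else mat
  if (is.null(species)) species <- attr(m, "species")
  if (is.null(species) || anyNA(species)) {
    stop("every gene must carry a species tag", call. = FALSE)
  }
  stopifnot(length(species) == ncol(m))
  umis_a <- Matrix::rowSums(m[, species == "A", drop = FALSE])
  umis_b <- Matrix::rowSums(m[, species == "B", drop = FALSE])
  total <- umis_a + umis_b
  if (any(total == 0)) {
    warning(sprintf("excluding %d zero-UMI cell(s) from species fractions",
                    sum(total == 0)), call. = FALSE)
  }
  keep <- total > 0
  tibble::tibble(cell_key = rownames(m)[keep],
                 umis = as.integer(total[keep]),
                 umis_a = as.integer(umis_a[keep]),
                 umis_b = as.integer(umis_b[keep]),
                 frac_a = unname(umis_a[keep] / total[keep]),
                 frac_b = unname(umis_b[keep] / total[keep]))
}

#' Label cells by species purity
#'
#' A cell is species-specific when strictly more than `threshold` (default
#' 85%) of its UMIs come from one species; all remaining cells are labelled
#' collisions — barcode combinations that captured material from both
#' species.
#'
#' @param fractions Tibble from [species_fractions()].
#' @param threshold Purity threshold in `(0.5, 1]`; the comparison is strict
#'   (`frac > threshold`), so a cell at exactly the threshold is a
#'   collision.
#' @return The input tibble with a `label` column in
#'   `{species_A, species_B, collision}`.
#' @export
classify_cells <- function(fractions, threshold = 0.85) {
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must be in (0.5, 1] for labels to be exclusive", call. = FALSE)
  }
  fractions |>
    dplyr::mutate(label = dplyr::case_when(
      .data$frac_a > threshold ~ "species_A",
      .data$frac_b > threshold ~ "species_B",
      TRUE ~ "collision"))
}

#' Species-mixing (barnyard) QC report
#'
#' Applies the purity rule to a filtered matrix and summarises: per-cell
#' species fractions and labels (the barnyard scatter table), the collision
#' rate, and median UMIs/genes per label. The collision rate is reported
#' raw (cross-species collisions / cells); `doublet_rate_extrapolated`
#' doubles it to account for unseen same-species doublets under a balanced
#' 50:50 design and is a separate, clearly labelled estimate.
#'
#' @param mat Cells x genes count matrix with `species` attribute (a
#'   filtered matrix, e.g. from [filter_cells()]).
#' @param threshold Purity threshold, see [classify_cells()].
#' @return A `ch_barnyard`: `cells` (per-cell tibble with UMIs per species
#'   and label) and `summary` (n_cells, counts and collision_rate,
#'   doublet_rate_extrapolated, per-label median UMIs and genes, threshold).
#' @export
barnyard_report <- function(mat, threshold = 0.85) {
  m <- if (inherits(mat, "ch_counts")) mat$matrix else mat
  cells <- classify_cells(species_fractions(m), threshold)
  genes_det <- tibble::tibble(cell_key = rownames(m),
                              genes = as.integer(Matrix::rowSums(m > 0)))
  cells <- dplyr::left_join(cells, genes_det, by = "cell_key")
  n <- nrow(cells)
  n_coll <- sum(cells$label == "collision")
  per_label <- cells |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(),
                     median_umis = median(.data$umis),
                     median_genes = median(.data$genes), .groups = "drop")
  summary <- list(n_cells = n,
                  n_species_a = sum(cells$label == "species_A"),
                  n_species_b = sum(cells$label == "species_B"),
                  n_collisions = n_coll,
                  collision_rate = if (n > 0) n_coll / n else NA_real_,
                  doublet_rate_extrapolated = if (n > 0) 2 * n_coll / n else NA_real_,
                  threshold = threshold,
                  per_label = per_label)
  structure(list(cells = cells, summary = summary), class = "ch_barnyard")
}

#' @export
print.ch_barnyard <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ch_barnyard: %d cells | %d A, %d B, %d collisions (rate %.3f) | threshold %.2f>\n",
              s$n_cells, s$n_species_a, s$n_species_b, s$n_collisions,
              s$collision_rate, s$threshold))
  invisible(x)
}

#' Tidy the per-cell barnyard table
#'
#' @param x A `ch_barnyard`.
#' @param ... Unused.
#' @return Per-cell tibble with species UMIs, fractions and labels.
#' @method tidy ch_barnyard
#' @export
tidy.ch_barnyard <- function(x, ...) x$cells

#' One-row barnyard summary
#'
#' @param x A `ch_barnyard`.
#' @param ... Unused.
#' @return One-row tibble: cell counts per label, collision rate and
#'   threshold.
#' @method glance ch_barnyard
#' @export
glance.ch_barnyard <- function(x, ...) {
  s <- x$summary
  tibble::tibble(n_cells = s$n_cells, n_species_a = s$n_species_a,
                 n_species_b = s$n_species_b, n_collisions = s$n_collisions,
                 collision_rate = s$collision_rate,
                 doublet_rate_extrapolated = s$doublet_rate_extrapolated,
                 threshold = s$threshold)
}

#' Barnyard scatter plot
#'
#' Species-A UMIs against species-B UMIs per cell, coloured by label: the
#' classic mixed-species QC figure where pure cells hug the axes and
#' collisions sit on the diagonal.
#'
#' @param object A `ch_barnyard`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ch_barnyard
#' @export
autoplot.ch_barnyard <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$umis_a, y = .data$umis_b,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Species A UMIs", y = "Species B UMIs",
                  colour = NULL,
                  title = sprintf("Barnyard scatter (collision rate %.1f%%)",
                                  100 * object$summary$collision_rate)) +
    ggplot2::theme_minimal()
}
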
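#' L1 centroid perturbation ledger
#'
#' Quantifies how far each cell cluster moves between two conditions in an
#' embedding (any cells x D coordinate table — principal components, UMAP,
#' etc.; the analysis is embedding-agnostic). For every cluster containing
#' both conditions, the within-cluster perturbation is the L1 distance
#' (sum of absolute coordinate differences) between the two condition
#' centroids. As the comparison scale, all pairwise L1 distances between
#' whole-cluster centroids are computed. Overlap of the two distance
#' distributions indicates clusters perturbed as strongly as distinct cell
#' types differ from each other.
#'
#' @param embedding Data frame or matrix of cells x D numeric coordinates.
#' @param clusters Per-cell cluster labels.
#' @param conditions Per-cell condition labels; exactly two distinct values.
#' @param min_cells Minimum cells per condition within a cluster for its
#'   within-distance to be computed (smaller clusters are flagged and
#'   excluded).
#' @return A `ch_l1_perturb`: `within` (per-cluster tibble: cell counts per
#'   condition, `within_l1`, `flagged`), `between` (tibble of cluster pairs
#'   with `between_l1`), `between_matrix` (symmetric, zero diagonal) and
#'   `summary` (distribution overlap).
#' @export
l1_perturbation <- function(embedding, clusters, conditions, min_cells = 2L) {
  emb <- as.matrix(embedding)
  if (!is.numeric(emb)) stop("embedding must be numeric", call. = FALSE)
  n <- nrow(emb)
  stopifnot(length(clusters) == n, length(conditions) == n)
  cond_levels <- sort(unique(as.character(conditions)))
  if (length(cond_levels) != 2L) {
    stop("exactly two condition labels are required", call. = FALSE)
  }
  conditions <- as.character(conditions)
  clusters <- as.character(clusters)
  cl_levels <- sort(unique(clusters))

  centroid <- function(rows) colMeans(emb[rows, , drop = FALSE])
  l1 <- function(a, b) sum(abs(a - b))

  within <- purrr::map(cl_levels, function(cl) {
    in_cl <- clusters == cl
    n1 <- sum(in_cl & conditions == cond_levels[1])
    n2 <- sum(in_cl & conditions == cond_levels[2])
    ok <- n1 >= min_cells && n2 >= min_cells
    tibble::tibble(
      cluster = cl, n_cond1 = n1, n_cond2 = n2, flagged = !ok,
      within_l1 = if (ok) {
        l1(centroid(which(in_cl & conditions == cond_levels[1])),
           centroid(which(in_cl & conditions == cond_levels[2])))
      } else NA_real_)
  }) |> dplyr::bind_rows()

  cents <- t(vapply(cl_levels, function(cl) centroid(which(clusters == cl)),
                    numeric(ncol(emb))))
  K <- length(cl_levels)
  bm <- matrix(0, K, K, dimnames = list(cl_levels, cl_levels))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    bm[i, j] <- l1(cents[i, ], cents[j, ])
  }
  pairs <- which(upper.tri(bm), arr.ind = TRUE)
  between <- tibble::tibble(cluster1 = cl_levels[pairs[, 1]],
                            cluster2 = cl_levels[pairs[, 2]],
                            between_l1 = bm[pairs])

  w <- within$within_l1[!within$flagged]
  b <- between$between_l1
  summary <- list(
    conditions = cond_levels,
    n_within = length(w), n_between = length(b),
    median_within = if (length(w)) median(w) else NA_real_,
    median_between = if (length(b)) median(b) else NA_real_,
    frac_within_above_min_between =
      if (length(w) && length(b)) mean(w >= min(b)) else NA_real_,
    frac_between_below_max_within =
      if (length(w) && length(b)) mean(b <= max(w)) else NA_real_)
  structure(list(within = within, between = between, between_matrix = bm,
                 summary = summary),
            class = "ch_l1_perturb")
}

#' @export
print.ch_l1_perturb <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ch_l1_perturb: %d clusters (%s vs %s) | median within-L1 %.3g, median between-L1 %.3g>\n",
              nrow(x$within), s$conditions[1], s$conditions[2],
              s$median_within, s$median_between))
  invisible(x)
}

#' Combined within/between L1 distance table
#'
#' @param x A `ch_l1_perturb`.
#' @param ... Unused.
#' @return Long tibble with columns `type` (`within`/`between`), `label`
#'   and `l1`.
#' @method tidy ch_l1_perturb
#' @export
tidy.ch_l1_perturb <- function(x, ...) {
  dplyr::bind_rows(
    x$within |>
      dplyr::filter(!.data$flagged) |>
      dplyr::transmute(type = "within", label = .data$cluster,
                       l1 = .data$within_l1),
    x$between |>
      dplyr::transmute(type = "between",
                       label = paste(.data$cluster1, .data$cluster2, sep = "|"),
                       l1 = .data$between_l1))
}

#' One-row L1 perturbation summary
#'
#' @param x A `ch_l1_perturb`.
#' @param ... Unused.
#' @return One-row tibble of the overlap summary.
#' @method glance ch_l1_perturb
#' @export
glance.ch_l1_perturb <- function(x, ...) {
  tibble::as_tibble(x$summary[c("n_within", "n_between", "median_within",
                                "median_between",
                                "frac_within_above_min_between",
                                "frac_between_below_max_within")])
}

#' Histogram of within- versus between-cluster L1 distances
#'
#' @param object A `ch_l1_perturb`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ch_l1_perturb
#' @export
autoplot.ch_l1_perturb <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$l1, fill = .data$type)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "L1 centroid distance", y = "count", fill = NULL,
                  title = "Within-cluster condition shift vs between-cluster distances") +
    ggplot2::theme_minimal()
}
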
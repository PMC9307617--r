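#' Downsample cells uniformly without replacement
#'
#' Used to balance conditions before merging datasets (e.g. sampling a
#' matched number of cells from the larger condition).
#'
#' @param mat Cells x genes matrix.
#' @param n Number of cells to keep.
#' @param seed Integer seed.
#' @return The row-subset matrix (original row order preserved).
#' @export
downsample_cells <- function(mat, n, seed) {
  if (n > nrow(mat)) {
    stop(sprintf("cannot sample %d cells from %d", n, nrow(mat)), call. = FALSE)
  }
  local_rng(seed)
  keep <- sort(sample.int(nrow(mat), n))
  sp <- attr(mat, "species")
  out <- mat[keep, , drop = FALSE]
  attr(out, "species") <- sp
  out
}

#' Aggregate cells into pseudocells within clusters
#'
#' Within each cluster, cells are randomly partitioned into groups of `k`
#' (default 50) and each group's counts are summed gene-wise into one
#' pseudocell profile — the denoised units typically fed to gene regulatory
#' network inference. A remainder group is kept on its own when it has at
#' least `k/2` cells and merged into the last full group otherwise; a
#' cluster with fewer than `k/2` cells yields a single pseudocell with a
#' warning. Sums (not means) preserve count semantics; total counts are
#' conserved exactly.
#'
#' @param mat Cells x genes count matrix.
#' @param clusters Per-cell cluster labels.
#' @param k Cells per pseudocell.
#' @param seed Integer seed for the random partition.
#' @return A list: `matrix` (pseudocells x genes, `dgCMatrix`) and
#'   `mapping` (tibble `pseudocell`, `cell`, `cluster`).
#' @export
pseudocell_aggregate <- function(mat, clusters, k = 50L, seed = 1L) {
  stopifnot(length(clusters) == nrow(mat), k >= 1L)
  local_rng(seed)
  clusters <- as.character(clusters)
  cell_ids <- rownames(mat) %||% sprintf("cell%d", seq_len(nrow(mat)))
  mapping <- purrr::map(sort(unique(clusters)), function(cl) {
    rows <- which(clusters == cl)
    n <- length(rows)
    rows <- rows[sample.int(n)]
    n_full <- n %/% k
    r <- n - n_full * k
    if (n_full == 0L) {
      if (n < k / 2) {
        warning(sprintf("cluster %s has %d < k/2 cells; single pseudocell",
                        cl, n), call. = FALSE)
      }
      grp <- rep(1L, n)
    } else if (r == 0L) {
      grp <- rep(seq_len(n_full), each = k)
    } else if (r >= k / 2) {
      grp <- c(rep(seq_len(n_full), each = k), rep(n_full + 1L, r))
    } else {
      grp <- c(rep(seq_len(n_full), each = k), rep(n_full, r))
    }
    tibble::tibble(pseudocell = sprintf("%s_pc%03d", cl, grp),
                   cell = cell_ids[rows], row = rows, cluster = cl)
  }) |> dplyr::bind_rows()
  pcs <- unique(mapping$pseudocell)
  agg <- Matrix::sparseMatrix(
    i = match(mapping$pseudocell, pcs), j = mapping$row, x = 1,
    dims = c(length(pcs), nrow(mat)))
  out <- methods::as(agg %*% mat, "dgCMatrix")
  dimnames(out) <- list(pcs, colnames(mat))
  list(matrix = out, mapping = mapping[, c("pseudocell", "cell", "cluster")])
}
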
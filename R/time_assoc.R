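# All permutations of 1..n, as an n x n! matrix (columns are permutations).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  cols <- lapply(seq_len(n), function(pos) {
    m <- matrix(0L, n, ncol(sub))
    m[pos, ] <- n
    m[-pos, ] <- sub
    m
  })
  do.call(cbind, cols)
}

#' Per-stage expression and detection profiles
#'
#' Summarises a cells x genes matrix over an ordered series of stages: the
#' mean expression per stage (the "expression level") and the fraction of
#' cells with nonzero counts per stage (the "percentage level", or
#' detection fraction).
#'
#' @param mat Cells x genes matrix (dense or sparse); rows are cells of one
#'   cell type.
#' @param stages Per-cell stage labels.
#' @param stage_levels Stage order; defaults to factor levels or sorted
#'   unique values.
#' @return List of two stages x genes matrices, `expression` and
#'   `fraction`, plus `stage_levels`.
#' @export
stage_profiles <- function(mat, stages, stage_levels = NULL) {
  if (is.null(stage_levels)) {
    stage_levels <- if (is.factor(stages)) levels(stages) else sort(unique(stages))
  }
  stages <- factor(as.character(stages), levels = stage_levels)
  if (anyNA(stages)) stop("stages contain values outside stage_levels", call. = FALSE)
  if (length(stages) != nrow(mat)) stop("one stage label per cell required", call. = FALSE)
  expr <- do.call(rbind, lapply(stage_levels, function(s) {
    Matrix::colMeans(mat[stages == s, , drop = FALSE])
  }))
  frac <- do.call(rbind, lapply(stage_levels, function(s) {
    Matrix::colMeans(mat[stages == s, , drop = FALSE] > 0)
  }))
  rownames(expr) <- rownames(frac) <- stage_levels
  list(expression = expr, fraction = frac, stage_levels = stage_levels)
}

# Two-sided permutation Spearman test of stage profiles against the linear
# stage vector 1..S. `profiles` is an S x G matrix; `perm` an S x P matrix of
# stage-order permutations (identity included in exact mode). Returns rho,
# p, and a constant-gene flag. Spearman rho with ties is Pearson on average
# ranks, so permutation rhos reduce to one matrix product.
perm_spearman <- function(profiles, perm, exact) {
  S <- nrow(profiles); G <- ncol(profiles)
  ranks <- apply(profiles, 2L, rank)          # S x G, average ranks on ties
  rc <- sweep(ranks, 2L, colMeans(ranks))     # centered
  norm_r <- sqrt(colSums(rc^2))
  constant <- norm_r < 1e-12
  z <- seq_len(S) - (S + 1) / 2
  norm_z <- sqrt(sum(z^2))
  # W[i, j] = z at the position stage i occupies under permutation j
  P <- ncol(perm)
  W <- matrix(0, S, P)
  for (j in seq_len(P)) W[perm[, j], j] <- z
  rho_all <- crossprod(rc, W) / (norm_r %o% rep(norm_z, P))  # G x P
  rho_obs <- as.numeric(crossprod(rc, z) / (norm_r * norm_z))
  exceed <- unname(rowSums(abs(rho_all) >= abs(rho_obs) - 1e-12))
  p <- if (exact) exceed / P else (1 + exceed) / (P + 1)
  rho_obs[constant] <- NA_real_
  p[constant] <- NA_real_
  list(rho = unname(rho_obs), p = unname(p), constant = unname(constant))
}

#' Time-associated genes by permutation Spearman correlation
#'
#' For each gene, correlates the per-stage expression level (stage means)
#' and the per-stage detection fraction with the linear stage vector
#' `1..S` using Spearman rank correlation, and tests the null of no
#' correlation by permuting the stage-level values: exact enumeration of
#' all `S!` stage orderings when `S <= 7`, otherwise `n_perm` sampled
#' permutations. P-values are two-sided (nonzero-correlation alternative).
#' A gene is called time-associated (`direction` up or down) when both
#' p-values fall below `alpha` and both correlations share a sign; the
#' direction is the sign. Genes constant across stages have no defined
#' rank correlation and are flagged.
#'
#' @param mat Cells x genes matrix restricted to one cell type.
#' @param stages Per-cell stage labels (at least 3 distinct stages).
#' @param stage_levels Stage order (e.g. `c("D30","D35","D45","D50","D70")`).
#' @param alpha Selection threshold on both p-values.
#' @param mode `"auto"` (exact when `S! <= 5040`), `"exact"`, or
#'   `"sampled"`.
#' @param n_perm Number of sampled permutations when not exact.
#' @param seed Seed for sampled mode.
#' @return A `ch_time_assoc`; `tidy()` gives the per-gene table
#'   (`gene`, `rho_expression`, `p_expression`, `rho_fraction`,
#'   `p_fraction`, `direction`, `constant`), `glance()` the gene counts.
#' @export
time_assoc_genes <- function(mat, stages, stage_levels = NULL, alpha = 0.05,
                             mode = c("auto", "exact", "sampled"),
                             n_perm = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  prof <- stage_profiles(mat, stages, stage_levels)
  S <- length(prof$stage_levels)
  if (S < 3L) stop("at least 3 stages are required", call. = FALSE)
  if (mode == "auto") mode <- if (S <= 7L) "exact" else "sampled"
  if (mode == "exact" && S > 7L) {
    stop("exact enumeration is limited to S <= 7 stages", call. = FALSE)
  }
  perm <- if (mode == "exact") {
    all_permutations(S)
  } else {
    local_rng(seed)
    vapply(seq_len(n_perm), function(i) sample.int(S), integer(S))
  }
  expr <- perm_spearman(prof$expression, perm, exact = mode == "exact")
  frac <- perm_spearman(prof$fraction, perm, exact = mode == "exact")
  genes <- colnames(prof$expression) %||% sprintf("g%d", seq_along(expr$rho))
  res <- tibble::tibble(
    gene = genes,
    rho_expression = expr$rho, p_expression = expr$p,
    rho_fraction = frac$rho, p_fraction = frac$p,
    constant = expr$constant | frac$constant)
  selected <- !res$constant &
    res$p_expression < alpha & res$p_fraction < alpha &
    sign(res$rho_expression) == sign(res$rho_fraction) &
    sign(res$rho_expression) != 0
  res$direction <- ifelse(selected & res$rho_expression > 0, "up",
                          ifelse(selected, "down", "none"))
  structure(list(result = res, stage_levels = prof$stage_levels,
                 alpha = alpha, mode = mode,
                 n_perm = if (mode == "exact") factorial(S) else n_perm),
            class = "ch_time_assoc")
}

#' @export
print.ch_time_assoc <- function(x, ...) {
  cat(sprintf("<ch_time_assoc: %d genes over %d stages (%s, %d permutations); %d up, %d down>\n",
              nrow(x$result), length(x$stage_levels), x$mode, x$n_perm,
              sum(x$result$direction == "up"),
              sum(x$result$direction == "down")))
  invisible(x)
}

#' Per-gene time-association table
#'
#' @param x A `ch_time_assoc`.
#' @param ... Unused.
#' @return The per-gene tibble.
#' @method tidy ch_time_assoc
#' @export
tidy.ch_time_assoc <- function(x, ...) x$result

#' One-row time-association summary
#'
#' @param x A `ch_time_assoc`.
#' @param ... Unused.
#' @return One-row tibble with gene counts per direction and test settings.
#' @method glance ch_time_assoc
#' @export
glance.ch_time_assoc <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$result),
                 n_up = sum(x$result$direction == "up"),
                 n_down = sum(x$result$direction == "down"),
                 n_constant = sum(x$result$constant),
                 n_stages = length(x$stage_levels),
                 alpha = x$alpha, mode = x$mode, n_perm = x$n_perm)
}
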
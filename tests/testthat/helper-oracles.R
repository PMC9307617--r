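# Independent brute-force oracles and tiny fixtures shared across tests.
# These deliberately avoid the package's own code paths.

# Character-level Hamming distance, written independently of chseq::hamming.
bf_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Nearest-whitelist correction by linear scan: returns list(entry, status).
bf_correct <- function(sequences, obs, max_mismatch = 1L) {
  d <- unname(vapply(sequences, bf_hamming, 1, b = obs))
  dmin <- min(d)
  if (dmin > max_mismatch) return(list(entry = NA_integer_, status = "no_match"))
  if (dmin == 0L) return(list(entry = which(d == 0L)[1], status = "matched"))
  within <- which(d <= max_mismatch)
  if (length(within) > 1L) return(list(entry = NA_integer_, status = "ambiguous"))
  list(entry = within[1], status = "matched")
}

# Exact two-sided permutation Spearman p via explicit enumeration with
# stats::cor, independent of chseq's matrix algebra.
bf_perm_spearman_p <- function(values) {
  S <- length(values)
  perms <- gtools_permutations(S)
  rho_obs <- suppressWarnings(cor(values, seq_len(S), method = "spearman"))
  rhos <- apply(perms, 1, function(p) {
    suppressWarnings(cor(values[p], seq_len(S), method = "spearman"))
  })
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# All permutations of 1..n as an n! x n matrix (rows), iterative insertion.
gtools_permutations <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (m in 2L:n) {
    out <- do.call(rbind, lapply(seq_len(m), function(pos) {
      cbind(out[, seq_len(pos - 1L), drop = FALSE], m,
            out[, seq(pos, m - 1L)[seq_len(m - pos)], drop = FALSE])
    }))
  }
  out
}

# Brute-force L1 perturbation ledger with plain loops.
bf_l1 <- function(emb, clusters, conditions, min_cells = 2L) {
  emb <- as.matrix(emb)
  conds <- sort(unique(conditions))
  cls <- sort(unique(clusters))
  within <- sapply(cls, function(cl) {
    a <- emb[clusters == cl & conditions == conds[1], , drop = FALSE]
    b <- emb[clusters == cl & conditions == conds[2], , drop = FALSE]
    if (nrow(a) < min_cells || nrow(b) < min_cells) return(NA_real_)
    sum(abs(colMeans(a) - colMeans(b)))
  })
  between <- matrix(0, length(cls), length(cls), dimnames = list(cls, cls))
  for (i in seq_along(cls)) for (j in seq_along(cls)) {
    ci <- colMeans(emb[clusters == cls[i], , drop = FALSE])
    cj <- colMeans(emb[clusters == cls[j], , drop = FALSE])
    between[i, j] <- sum(abs(ci - cj))
  }
  list(within = within, between = between)
}

# Brute-force directional UMI collapse count (greedy by abundance).
bf_directional <- function(umis, reads) {
  ord <- order(-reads, umis)
  umis <- umis[ord]; reads <- reads[ord]
  kept_u <- character(0); kept_r <- integer(0)
  for (i in seq_along(umis)) {
    merged <- FALSE
    for (j in seq_along(kept_u)) {
      if (bf_hamming(kept_u[j], umis[i]) <= 1 && kept_r[j] >= 2 * reads[i] - 1) {
        merged <- TRUE; break
      }
    }
    if (!merged) { kept_u <- c(kept_u, umis[i]); kept_r <- c(kept_r, reads[i]) }
  }
  length(kept_u)
}

# Small shared fixtures -------------------------------------------------

# Tiny scheme: whitelists small enough for exhaustive checks but with the
# default read layout.
tiny_scheme <- function(seed = 42L, min_dist = 3L) {
  ch_scheme(
    bc1 = random_whitelist(12L, 10L, min_dist, "bc1", seed = seed),
    bc2 = random_whitelist(24L, 10L, min_dist, "bc2", seed = seed + 1L),
    i5 = random_whitelist(2L, 8L, min_dist, "i5", seed = seed + 2L),
    i7 = random_whitelist(2L, 8L, min_dist, "i7", seed = seed + 3L))
}

tiny_reference <- function(n_genes = 8L, seed = 42L) {
  generate_reference(n_genes, seed = seed, len_range = c(300L, 600L))
}

tiny_library <- function(n_cells = 40L, seed = 42L, doublet_fraction = 0,
                         barcode_error_rate = 0, cdna_error_rate = 0,
                         duplicate_rate = 0, reads_per_cell = 60,
                         scheme = tiny_scheme(), ref = tiny_reference()) {
  cfg <- ch_sim_config(n_cells = n_cells, doublet_fraction = doublet_fraction,
                       reads_per_cell = reads_per_cell,
                       barcode_error_rate = barcode_error_rate,
                       cdna_error_rate = cdna_error_rate,
                       duplicate_rate = duplicate_rate, seed = seed)
  cells <- generate_cells(cfg, scheme, ref)
  lib <- synthesize_reads(cells, ref, cfg, scheme)
  list(cfg = cfg, scheme = scheme, ref = ref, cells = cells, lib = lib)
}
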
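#' Build a k-mer seed index over a transcript reference
#'
#' Indexes every k-mer of every transcript. A k-mer occurring in transcripts
#' of a single gene stores one (transcript, offset) witness for verification;
#' a k-mer shared by two or more genes is marked multi-gene. The default
#' k = 21 makes chance k-mer sharing between random transcripts of a few
#' hundred to a few thousand nt essentially impossible (4^21 > 4e12).
#'
#' @param ref A `ch_reference`.
#' @param k Seed length in nt.
#' @return A `ch_tx_index`.
#' @export
build_tx_index <- function(ref, k = 21L) {
  k <- as.integer(k)
  stopifnot(k >= 8L)
  lens <- nchar(ref$sequence)
  if (any(lens < k)) stop("all transcripts must be at least k nt", call. = FALSE)
  per_tx <- purrr::map(seq_len(nrow(ref)), function(i) {
    n_k <- lens[i] - k + 1L
    tibble::tibble(
      kmer = substring(ref$sequence[i], seq_len(n_k), seq_len(n_k) + k - 1L),
      tx = i, offset = seq_len(n_k))
  })
  tab <- dplyr::bind_rows(per_tx)
  tab$gene <- ref$gene_id[tab$tx]
  ord <- order(tab$kmer)
  tab <- tab[ord, ]
  first <- !duplicated(tab$kmer)
  grp <- cumsum(first)
  multi <- vapply(split(tab$gene, grp), function(g) length(unique(g)) > 1L,
                  logical(1))
  keep <- tab[first, ]
  structure(list(k = k, kmer = keep$kmer, tx = keep$tx,
                 offset = keep$offset, gene = keep$gene,
                 multi = unname(multi),
                 tx_seq = ref$sequence, tx_gene = ref$gene_id,
                 genes = unique(ref$gene_id),
                 species = ref$species[match(unique(ref$gene_id),
                                             ref$gene_id)]),
            class = "ch_tx_index")
}

#' @export
print.ch_tx_index <- function(x, ...) {
  cat(sprintf("<ch_tx_index: k=%d, %d transcripts, %d genes, %d k-mers (%d multi-gene)>\n",
              x$k, length(x$tx_seq), length(x$genes), length(x$kmer),
              sum(x$multi)))
  invisible(x)
}

#' Assign reads to genes by seed-and-verify exact containment
#'
#' For each read, seed k-mers are looked up at up to three positions (start,
#' middle, end). A seed hitting a multi-gene k-mer marks the read
#' multimapped; a unique-gene seed is verified by exact comparison of the
#' full read against the witness transcript at the implied offset. Reads
#' with no verifying seed are unassigned, as are reads shorter than k.
#' Multimapped reads are discarded from counting, matching conventional
#' unique gene-level assignment.
#'
#' @param reads Character vector of Read2 sequences.
#' @param index A `ch_tx_index`.
#' @return Character vector: gene id, `"multimapped"`, or `"unassigned"`.
#' @export
assign_genes <- function(reads, index) {
  stopifnot(inherits(index, "ch_tx_index"))
  k <- index$k
  n <- length(reads)
  out <- rep("unassigned", n)
  widths <- nchar(reads)
  short <- widths < k
  todo <- which(!short)
  seed_at <- function(w, which_pos) {
    switch(which_pos,
           start = rep(1L, length(w)),
           mid = pmax(1L, (w - k) %/% 2L + 1L),
           end = pmax(1L, w - k + 1L))
  }
  for (pos_name in c("start", "mid", "end")) {
    if (length(todo) == 0L) break
    w <- widths[todo]
    sp <- seed_at(w, pos_name)
    seed <- substr(reads[todo], sp, sp + k - 1L)
    hit <- match(seed, index$kmer)
    found <- !is.na(hit)
    if (!any(found)) next
    h <- hit[found]
    idx <- todo[found]
    is_multi <- index$multi[h]
    out[idx[is_multi]] <- "multimapped"
    uq <- which(!is_multi)
    if (length(uq)) {
      i_r <- idx[uq]; i_h <- h[uq]
      tstart <- index$offset[i_h] - (sp[found][uq] - 1L)
      tlen <- nchar(index$tx_seq[index$tx[i_h]])
      inside <- tstart >= 1L & (tstart + widths[i_r] - 1L) <= tlen
      verified <- rep(FALSE, length(uq))
      if (any(inside)) {
        cmp <- substr(index$tx_seq[index$tx[i_h[inside]]],
                      tstart[inside],
                      tstart[inside] + widths[i_r[inside]] - 1L)
        verified[inside] <- cmp == reads[i_r[inside]]
      }
      out[i_r[verified]] <- index$gene[i_h[verified]]
    }
    done <- out[todo] != "unassigned"
    todo <- todo[!done]
  }
  out
}

#' Deduplicate UMIs within (cell, gene) groups
#'
#' Default policy `"exact"` counts the number of distinct UMI sequences per
#' group — no graph collapse, matching plain digital-expression counting.
#' Policy `"directional"` additionally merges a UMI into a more abundant
#' UMI at Hamming distance 1 when the abundant one has at least twice its
#' read count minus one (the standard directional-adjacency rule).
#'
#' @param tagged Tibble with columns `cell_key`, `gene_id`, `umi` (one row
#'   per read).
#' @param policy `"exact"` or `"directional"`.
#' @return Tibble `cell_key`, `gene_id`, `molecules`.
#' @export
dedup_umis <- function(tagged, policy = c("exact", "directional")) {
  policy <- match.arg(policy)
  if (nrow(tagged) == 0L) {
    return(tibble::tibble(cell_key = character(), gene_id = character(),
                          molecules = integer()))
  }
  if (policy == "exact") {
    tagged |>
      dplyr::distinct(.data$cell_key, .data$gene_id, .data$umi) |>
      dplyr::count(.data$cell_key, .data$gene_id, name = "molecules") |>
      dplyr::arrange(.data$cell_key, .data$gene_id)
  } else {
    tagged |>
      dplyr::count(.data$cell_key, .data$gene_id, .data$umi, name = "reads") |>
      dplyr::group_by(.data$cell_key, .data$gene_id) |>
      dplyr::summarise(molecules = directional_count(.data$umi, .data$reads),
                       .groups = "drop") |>
      dplyr::arrange(.data$cell_key, .data$gene_id)
  }
}

# Directional single-mismatch collapse: process UMIs by decreasing read
# count; umi b is absorbed by an already-kept umi a when hamming(a,b) <= 1
# and reads(a) >= 2*reads(b) - 1. Returns the number of surviving UMIs.
directional_count <- function(umis, reads) {
  if (length(umis) <= 1L) return(length(umis))
  ord <- order(-reads, umis)
  umis <- umis[ord]; reads <- reads[ord]
  kept <- character(0); kept_reads <- integer(0)
  for (i in seq_along(umis)) {
    absorbed <- FALSE
    if (length(kept)) {
      d <- hamming(kept, rep(umis[i], length(kept)))
      absorbed <- any(d <= 1L & kept_reads >= 2L * reads[i] - 1L)
    }
    if (!absorbed) {
      kept <- c(kept, umis[i])
      kept_reads <- c(kept_reads, reads[i])
    }
  }
  length(kept)
}

#' Build the digital expression matrix and per-cell statistics
#'
#' Assigns each tagged Read2 to a gene, deduplicates UMIs per (cell, gene),
#' and assembles a sparse cells x genes count matrix over all observed cell
#' keys plus per-cell statistics (reads, UMIs, genes detected, per-species
#' UMIs).
#'
#' @param tagged Tagged read tibble from [demux_run()] (`cell_key`, `umi`,
#'   `read2`).
#' @param index A `ch_tx_index` (or a `ch_reference`, indexed on the fly).
#' @param umi_policy UMI deduplication policy, see [dedup_umis()].
#' @return A `ch_counts` list: `matrix` (cells x genes `dgCMatrix` with
#'   `species` attribute), `cell_stats` tibble, `assign_stats` (assigned /
#'   multimapped / unassigned read counts).
#' @export
build_matrix <- function(tagged, index, umi_policy = "exact") {
  if (inherits(index, "ch_reference")) index <- build_tx_index(index)
  gene <- assign_genes(tagged$read2, index)
  ok <- !(gene %in% c("multimapped", "unassigned"))
  assign_stats <- list(n_reads = nrow(tagged),
                       assigned = sum(ok),
                       multimapped = sum(gene == "multimapped"),
                       unassigned = sum(gene == "unassigned"))
  assigned <- tibble::tibble(cell_key = tagged$cell_key[ok],
                             gene_id = gene[ok], umi = tagged$umi[ok])
  mol <- dedup_umis(assigned, policy = umi_policy)
  cells <- sort(unique(tagged$cell_key))
  genes <- index$genes
  mat <- Matrix::sparseMatrix(
    i = match(mol$cell_key, cells),
    j = match(mol$gene_id, genes),
    x = mol$molecules,
    dims = c(length(cells), length(genes)),
    dimnames = list(cells, genes))
  mat <- methods::as(mat, "dgCMatrix")
  attr(mat, "species") <- index$species
  reads_per_cell <- tagged |> dplyr::count(.data$cell_key, name = "reads")
  umis <- Matrix::rowSums(mat)
  genes_det <- Matrix::rowSums(mat > 0)
  umis_a <- Matrix::rowSums(mat[, index$species == "A", drop = FALSE])
  umis_b <- Matrix::rowSums(mat[, index$species == "B", drop = FALSE])
  cell_stats <- tibble::tibble(
    cell_key = cells,
    reads = reads_per_cell$reads[match(cells, reads_per_cell$cell_key)],
    umis = as.integer(umis), genes = as.integer(genes_det),
    umis_a = as.integer(umis_a), umis_b = as.integer(umis_b))
  structure(list(matrix = mat, cell_stats = cell_stats,
                 assign_stats = assign_stats),
            class = "ch_counts")
}

#' @export
print.ch_counts <- function(x, ...) {
  cat(sprintf("<ch_counts: %d cells x %d genes, %d UMIs total>\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  invisible(x)
}

#' Filter cells on total UMI count
#'
#' Retains cells whose UMI total is strictly greater than `min_umi`
#' (default 200); with `strict = FALSE` the boundary cell is kept instead.
#'
#' @param mat A cells x genes count matrix (`dgCMatrix` or `ch_counts`).
#' @param min_umi UMI threshold.
#' @param strict Use `umis > min_umi` (default) rather than `>=`.
#' @return The filtered matrix (same class as the input matrix), with the
#'   number of removed cells reported via message.
#' @export
filter_cells <- function(mat, min_umi = 200L, strict = TRUE) {
  if (min_umi < 0) stop("min_umi must be >= 0", call. = FALSE)
  m <- if (inherits(mat, "ch_counts")) mat$matrix else mat
  if (nrow(m) == 0L) {
    warning("empty matrix: no cells to filter", call. = FALSE)
    return(m)
  }
  umis <- Matrix::rowSums(m)
  keep <- if (strict) umis > min_umi else umis >= min_umi
  message(sprintf("filter_cells: removed %d of %d cells (UMIs %s %d)",
                  sum(!keep), length(keep), if (strict) "<=" else "<", min_umi))
  sp <- attr(m, "species")
  out <- m[keep, , drop = FALSE]
  attr(out, "species") <- sp
  out
}
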
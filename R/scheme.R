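#' Describe the delivered Read1 layout
#'
#' Split-pool libraries sequence Read1 through the barcode stack; fixed
#' linker bases between barcode blocks are skipped on-instrument as dark
#' cycles (cycles performed without imaging), so the delivered read is the
#' concatenation of the informative segments only. The default models a
#' 51-cycle Read1 with dark cycles 11-33: 28 delivered bases laid out as
#' bc2 (10 nt) + bc1 (10 nt) + UMI (8 nt).
#'
#' @param read1_total_cycles Total Read1 sequencing cycles.
#' @param dark_start,dark_end 1-based inclusive cycle window of the dark
#'   reaction (use `0, -1` for no dark window).
#' @param segments Named integer vector of delivered segment lengths in read
#'   order; names from `{"bc2", "bc1", "umi", "fixed"}`, exactly one `"umi"`.
#' @param read2_length Length of the cDNA read (Read2).
#' @return A `ch_read_layout` with per-segment delivered offsets.
#' @examples
#' ch_read_layout()
#' @export
ch_read_layout <- function(read1_total_cycles = 51L,
                           dark_start = 11L, dark_end = 33L,
                           segments = c(bc2 = 10L, bc1 = 10L, umi = 8L),
                           read2_length = 100L) {
  seg_names <- names(segments)
  segments <- as.integer(segments)
  names(segments) <- seg_names
  if (is.null(seg_names) || !all(seg_names %in% c("bc2", "bc1", "umi", "fixed"))) {
    stop("segment names must be among bc2, bc1, umi, fixed", call. = FALSE)
  }
  if (sum(seg_names == "umi") != 1L) {
    stop("layout must contain exactly one umi segment", call. = FALSE)
  }
  dark_len <- max(0L, as.integer(dark_end) - as.integer(dark_start) + 1L)
  delivered <- as.integer(read1_total_cycles) - dark_len
  if (sum(segments) != delivered) {
    stop(sprintf(
      "segment lengths sum to %d but delivered Read1 is %d cycles (%d total - %d dark)",
      sum(segments), delivered, read1_total_cycles, dark_len), call. = FALSE)
  }
  ends <- cumsum(segments)
  starts <- ends - segments + 1L
  structure(
    list(read1_total_cycles = as.integer(read1_total_cycles),
         dark_start = as.integer(dark_start), dark_end = as.integer(dark_end),
         segments = segments, starts = starts, ends = ends,
         delivered_length = delivered,
         umi_length = unname(segments[seg_names == "umi"]),
         read2_length = as.integer(read2_length)),
    class = "ch_read_layout"
  )
}

#' @export
print.ch_read_layout <- function(x, ...) {
  cat(sprintf("<ch_read_layout: %d cycles, dark %d-%d, delivered %d nt = %s; read2 %d nt>\n",
              x$read1_total_cycles, x$dark_start, x$dark_end,
              x$delivered_length,
              paste(sprintf("%s(%d)", names(x$segments), x$segments),
                    collapse = "+"),
              x$read2_length))
  invisible(x)
}

#' Assemble a barcode scheme
#'
#' Bundles the four whitelists (two rounds of cell barcodes plus the i5/i7
#' sample indices), the Read1 layout and the per-round correction budgets,
#' and pre-builds the correction indices the demultiplexer uses. Cell
#' barcodes are corrected within `max_mismatch` substitutions; sample
#' indices default to exact match, the common policy for PCR indices.
#'
#' @param bc1,bc2,i5,i7 `ch_whitelist` objects for the four rounds.
#' @param layout A `ch_read_layout`; segment lengths must match the bc1/bc2
#'   whitelist widths.
#' @param max_mismatch Substitutions tolerated per cell-barcode round (0 or 1).
#' @param index_mismatch Substitutions tolerated on i5/i7 (default 0).
#' @return A `ch_scheme`.
#' @export
ch_scheme <- function(bc1, bc2, i5, i7, layout = ch_read_layout(),
                      max_mismatch = 1L, index_mismatch = 0L) {
  for (wl in list(bc1, bc2, i5, i7)) stopifnot(inherits(wl, "ch_whitelist"))
  stopifnot(inherits(layout, "ch_read_layout"))
  if (layout$segments[["bc1"]] != bc1$width) {
    stop("bc1 whitelist width does not match layout bc1 segment", call. = FALSE)
  }
  if (layout$segments[["bc2"]] != bc2$width) {
    stop("bc2 whitelist width does not match layout bc2 segment", call. = FALSE)
  }
  structure(
    list(bc1 = bc1, bc2 = bc2, i5 = i5, i7 = i7, layout = layout,
         max_mismatch = as.integer(max_mismatch),
         index_mismatch = as.integer(index_mismatch),
         index_bc1 = build_correction_index(bc1, max_mismatch),
         index_bc2 = build_correction_index(bc2, max_mismatch),
         index_i5 = build_correction_index(i5, index_mismatch),
         index_i7 = build_correction_index(i7, index_mismatch)),
    class = "ch_scheme"
  )
}

#' @export
print.ch_scheme <- function(x, ...) {
  cat(sprintf("<ch_scheme: bc1 %d x bc2 %d cell barcodes, %d i5 x %d i7 indices, max_mismatch %d>\n",
              length(x$bc1$sequences), length(x$bc2$sequences),
              length(x$i5$sequences), length(x$i7$sequences), x$max_mismatch))
  print(x$layout)
  invisible(x)
}

#' Default synthetic barcode scheme
#'
#' Generates a full scheme from seeded random whitelists with enforced
#' minimum pairwise Hamming distance 3 (unique 1-substitution correction):
#' 96 bc1 and 768 bc2 cell barcodes of 10 nt, and 8 nt i5/i7 index sets.
#'
#' @param n_bc1,n_bc2 Cell-barcode whitelist sizes.
#' @param n_i5,n_i7 Sample-index whitelist sizes.
#' @param min_dist Minimum pairwise Hamming distance enforced per whitelist.
#' @param max_mismatch,index_mismatch Correction budgets, see [ch_scheme()].
#' @param seed Integer seed.
#' @return A `ch_scheme`.
#' @export
ch_default_scheme <- function(n_bc1 = 96L, n_bc2 = 768L, n_i5 = 4L, n_i7 = 4L,
                              min_dist = 3L, max_mismatch = 1L,
                              index_mismatch = 0L, seed = 1L) {
  ch_scheme(
    bc1 = random_whitelist(n_bc1, 10L, min_dist, "bc1", seed = seed + 11L),
    bc2 = random_whitelist(n_bc2, 10L, min_dist, "bc2", seed = seed + 13L),
    i5  = random_whitelist(n_i5, 8L, min_dist, "i5", seed = seed + 17L),
    i7  = random_whitelist(n_i7, 8L, min_dist, "i7", seed = seed + 19L),
    max_mismatch = max_mismatch, index_mismatch = index_mismatch
  )
}

#' Total barcode-combination space of a scheme
#'
#' The number of distinct cell labels a split-pool run can produce:
#' `|bc1| * |bc2| * n_i5 * n_i7`. With 384 x 768 cell barcodes and a 96 x 4
#' index plate this exceeds 1e8 combinations.
#'
#' @param scheme A `ch_scheme`, or an integer giving `|bc1|` directly.
#' @param n_bc2 `|bc2|` when `scheme` is given as an integer; ignored
#'   otherwise.
#' @param n_i5,n_i7 Numbers of i5/i7 indices used in the experiment.
#' @return The combination count as a double (counts exceed 32-bit range).
#' @examples
#' combination_count(96, 768, 1, 1)
#' @export
combination_count <- function(scheme, n_bc2 = NULL, n_i5 = 1, n_i7 = 1) {
  if (inherits(scheme, "ch_scheme")) {
    n1 <- length(scheme$bc1$sequences)
    n2 <- length(scheme$bc2$sequences)
  } else {
    n1 <- as.numeric(scheme)
    n2 <- as.numeric(n_bc2)
  }
  counts <- c(n1, n2, as.numeric(n_i5), as.numeric(n_i7))
  if (any(is.na(counts)) || any(counts <= 0) || any(counts != floor(counts))) {
    stop("all counts must be positive integers", call. = FALSE)
  }
  prod(counts)
}

#' Check correction guarantees of a scheme's whitelists
#'
#' Reports the minimum pairwise Hamming distance per whitelist and warns
#' when it falls below `2 * max_mismatch + 1`, the bound under which
#' correction within `max_mismatch` substitutions is guaranteed unique.
#' (Distance `2 * max_mismatch + 2` additionally guarantees that reads with
#' one error more than the budget are rejected rather than mis-assigned.)
#'
#' @param scheme A `ch_scheme`.
#' @return A tibble with one row per round: `round_id`, `n`, `width`,
#'   `min_distance`, `max_mismatch`, `correction_guaranteed`.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "ch_scheme"))
  rounds <- list(bc1 = scheme$bc1, bc2 = scheme$bc2,
                 i5 = scheme$i5, i7 = scheme$i7)
  budgets <- c(bc1 = scheme$max_mismatch, bc2 = scheme$max_mismatch,
               i5 = scheme$index_mismatch, i7 = scheme$index_mismatch)
  out <- purrr::imap(rounds, function(wl, id) {
    md <- min_pairwise_distance(wl$sequences)
    budget <- budgets[[id]]
    guaranteed <- if (is.na(md)) NA else md >= 2L * budget + 1L
    if (isFALSE(guaranteed)) {
      warning(sprintf(
        "whitelist %s: min pairwise distance %d < %d; correction of %d mismatch(es) not guaranteed unique",
        id, md, 2L * budget + 1L, budget), call. = FALSE)
    }
    tibble::tibble(round_id = id, n = length(wl$sequences), width = wl$width,
                   min_distance = md, max_mismatch = budget,
                   correction_guaranteed = guaranteed)
  })
  dplyr::bind_rows(out)
}
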
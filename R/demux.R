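#' Slice raw Read1 into its layout segments
#'
#' Pure substring extraction at the layout's delivered offsets; no
#' interpretation or correction. Reads shorter than the delivered length are
#' flagged truncated and their segments set to `NA`.
#'
#' @param read1 Character vector of delivered Read1 sequences.
#' @param layout A `ch_read_layout`.
#' @return Tibble with one column per non-fixed segment (`bc2`, `bc1`,
#'   `umi`) plus `truncated`.
#' @export
parse_read1 <- function(read1, layout) {
  stopifnot(inherits(layout, "ch_read_layout"))
  truncated <- nchar(read1) < layout$delivered_length
  out <- tibble::tibble(.rows = length(read1))
  for (nm in names(layout$segments)) {
    if (nm == "fixed") next
    i <- which(names(layout$segments) == nm)
    v <- substr(read1, layout$starts[i], layout$ends[i])
    v[truncated] <- NA_character_
    out[[nm]] <- v
  }
  out$truncated <- truncated
  out
}

# Parse "i5:SEQ i7:SEQ" from FASTQ description lines.
parse_index_headers <- function(headers) {
  i5 <- sub("^.*\\bi5:([ACGTN]+).*$", "\\1", headers)
  i7 <- sub("^.*\\bi7:([ACGTN]+).*$", "\\1", headers)
  i5[!grepl("\\bi5:", headers)] <- NA_character_
  i7[!grepl("\\bi7:", headers)] <- NA_character_
  if (all(is.na(i5)) || all(is.na(i7))) {
    stop("no i5/i7 index information found in read headers", call. = FALSE)
  }
  tibble::tibble(i5 = i5, i7 = i7)
}

#' Route reads into (i7, i5) sub-library streams
#'
#' Raw runs are split into i7-indexed sub-libraries before barcode
#' extraction. Index reads are taken from the header comment (`i5:SEQ
#' i7:SEQ`, the simulator convention) and matched against the scheme's index
#' whitelists under the scheme's `index_mismatch` policy (exact by default).
#' Reads whose indices fail to match are routed to `bad_index`.
#'
#' @param headers FASTQ description lines carrying the index reads.
#' @param scheme A `ch_scheme`.
#' @return Tibble with per-read `i5_entry`, `i7_entry` (whitelist positions
#'   or `NA`), `i5_seq`, `i7_seq` (corrected sequences), `stream` (`"i7.i5"`
#'   label or `"bad_index"`).
#' @export
split_by_sample_index <- function(headers, scheme) {
  idx <- parse_index_headers(headers)
  c5 <- correct_barcodes(scheme$index_i5, idx$i5)
  c7 <- correct_barcodes(scheme$index_i7, idx$i7)
  ok <- c5$status == "matched" & c7$status == "matched"
  tibble::tibble(
    i5_entry = ifelse(ok, c5$entry, NA_integer_),
    i7_entry = ifelse(ok, c7$entry, NA_integer_),
    i5_seq = ifelse(ok, scheme$i5$sequences[c5$entry], NA_character_),
    i7_seq = ifelse(ok, scheme$i7$sequences[c7$entry], NA_character_),
    stream = ifelse(ok,
                    paste(scheme$i7$well_labels[c7$entry],
                          scheme$i5$well_labels[c5$entry], sep = "."),
                    "bad_index"))
}

#' Correct parsed segments and assign reads to cells
#'
#' Corrects bc1 and bc2 independently against their whitelists within the
#' scheme's mismatch budget. Any no-match or ambiguous round rejects the
#' read with a specific status; UMIs pass through uncorrected but reads
#' whose UMI contains a non-ACGT base are rejected (`bad_umi`), since an
#' uncertain base in an 8-mer UMI corrupts deduplication.
#'
#' @param segments Tibble from [parse_read1()].
#' @param index Tibble from [split_by_sample_index()] (or `NULL` when the
#'   library has a single sample index).
#' @param scheme A `ch_scheme`.
#' @return Tibble: `status`, corrected `bc1_entry`/`bc2_entry`,
#'   `bc1_mm`/`bc2_mm` mismatch counts, `umi`, and `cell_key`
#'   (`i7-i5-bc2-bc1` corrected sequences) for assigned reads.
#' @export
correct_and_assign <- function(segments, index = NULL, scheme) {
  n <- nrow(segments)
  c1 <- correct_barcodes(scheme$index_bc1, segments$bc1)
  c2 <- correct_barcodes(scheme$index_bc2, segments$bc2)
  status <- rep("assigned", n)
  if (!is.null(index)) status[index$stream == "bad_index"] <- "bad_index"
  mark <- function(status, cond, label) {
    ifelse(status == "assigned" & cond, label, status)
  }
  status <- mark(status, segments$truncated, "truncated")
  status <- mark(status, c2$status == "no_match", "no_match_bc2")
  status <- mark(status, c2$status == "ambiguous", "ambiguous_bc2")
  status <- mark(status, c1$status == "no_match", "no_match_bc1")
  status <- mark(status, c1$status == "ambiguous", "ambiguous_bc1")
  status <- mark(status, grepl("[^ACGT]", segments$umi), "bad_umi")
  ok <- status == "assigned"
  cell_key <- rep(NA_character_, n)
  if (!is.null(index)) {
    i5s <- index$i5_seq; i7s <- index$i7_seq
  } else {
    i5s <- rep("NOI5", n); i7s <- rep("NOI7", n)
  }
  cell_key[ok] <- paste(i7s[ok], i5s[ok],
                        scheme$bc2$sequences[c2$entry[ok]],
                        scheme$bc1$sequences[c1$entry[ok]], sep = "-")
  tibble::tibble(
    status = status,
    bc1_entry = ifelse(ok, c1$entry, NA_integer_),
    bc2_entry = ifelse(ok, c2$entry, NA_integer_),
    bc1_mm = c1$mismatches, bc2_mm = c2$mismatches,
    umi = segments$umi, cell_key = cell_key)
}

#' Demultiplex a paired library
#'
#' Full demultiplex: sample-index splitting, Read1 segment extraction,
#' whitelist correction and per-read cell assignment. Every input read
#' appears exactly once across statuses.
#'
#' @param r1 Either the Read1 FASTQ path or an in-memory library list with
#'   elements `read1`, `read2`, `headers` (as produced by
#'   [synthesize_reads()]).
#' @param r2 Read2 FASTQ path (ignored for in-memory input).
#' @param scheme A `ch_scheme`.
#' @return A `ch_demux` list: `assignments` (tibble: `read_id`, `status`,
#'   `cell_key`, `umi`, `stream`, mismatch counts), `tagged` (tibble of
#'   surviving reads: `read_id`, `cell_key`, `umi`, `read2`), and `report`
#'   (status counts, per-stream counts, mismatch histograms, reads-per-cell
#'   histogram).
#' @export
demux_run <- function(r1, r2 = NULL, scheme) {
  if (is.list(r1) && !is.null(r1$read1)) {
    read1 <- r1$read1; read2 <- r1$read2; headers <- r1$headers
  } else {
    f1 <- read_fastq(r1); f2 <- read_fastq(r2)
    if (length(f1$seqs) != length(f2$seqs)) {
      stop("Read1 and Read2 FASTQ files have different read counts", call. = FALSE)
    }
    read1 <- f1$seqs; read2 <- f2$seqs; headers <- f1$headers
  }
  if (length(read1) == 0L) {
    warning("empty input: no reads to demultiplex", call. = FALSE)
    return(structure(list(
      assignments = tibble::tibble(read_id = character(), status = character(),
                                   cell_key = character(), umi = character()),
      tagged = tibble::tibble(read_id = character(), cell_key = character(),
                              umi = character(), read2 = character()),
      report = list(n_reads = 0L)), class = "ch_demux"))
  }
  read_id <- sub("\\s.*$", "", headers)
  index <- split_by_sample_index(headers, scheme)
  segments <- parse_read1(read1, scheme$layout)
  assign <- correct_and_assign(segments, index, scheme)
  assignments <- dplyr::bind_cols(
    tibble::tibble(read_id = read_id), assign,
    tibble::tibble(stream = index$stream))
  ok <- assignments$status == "assigned"
  tagged <- tibble::tibble(read_id = read_id[ok],
                           cell_key = assignments$cell_key[ok],
                           umi = assignments$umi[ok],
                           read2 = read2[ok])
  status_counts <- sort(table(assignments$status), decreasing = TRUE)
  per_cell <- table(assignments$cell_key[ok])
  report <- list(
    n_reads = length(read1),
    status_counts = as.list(status_counts),
    assigned_fraction = mean(ok),
    stream_counts = as.list(table(index$stream)),
    mismatch_histogram = list(
      bc1 = as.list(table(assign$bc1_mm[ok])),
      bc2 = as.list(table(assign$bc2_mm[ok]))),
    n_cell_keys = length(per_cell),
    reads_per_cell_summary = as.list(summary(as.integer(per_cell))))
  structure(list(assignments = assignments, tagged = tagged, report = report),
            class = "ch_demux")
}

#' @export
print.ch_demux <- function(x, ...) {
  cat(sprintf("<ch_demux: %d reads, %.1f%% assigned, %d cell keys>\n",
              x$report$n_reads, 100 * (x$report$assigned_fraction %||% 0),
              x$report$n_cell_keys %||% 0L))
  invisible(x)
}
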
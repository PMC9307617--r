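#' Hamming distance between equal-length DNA strings
#'
#' Counts mismatching positions between two sequences. Both arguments are
#' vectorised and recycled to a common length.
#'
#' @param a,b Character vectors of equal-length DNA strings.
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming("ACGT", "ACGA")
#' @export
hamming <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(integer(0))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("hamming() requires equal-length sequences", call. = FALSE)
  }
  mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

# Pairwise minimum Hamming distance of a set of equal-width strings.
# Returns NA for fewer than 2 sequences.
min_pairwise_distance <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(NA_integer_)
  m <- do.call(rbind, lapply(seqs, utf8ToInt))
  best <- nchar(seqs[[1]])
  for (i in seq_len(n - 1L)) {
    d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
    if (best == 0L) break
  }
  as.integer(best)
}

new_whitelist <- function(sequences, round_id, well_labels = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("whitelist is empty", call. = FALSE)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("whitelist sequences have mixed lengths (line %d: '%s')",
                 bad, sequences[bad]), call. = FALSE)
  }
  if (any(grepl("[^ACGT]", sequences))) {
    bad <- sequences[grepl("[^ACGT]", sequences)][1]
    stop(sprintf("whitelist contains non-ACGT sequence '%s'", bad),
         call. = FALSE)
  }
  if (anyDuplicated(sequences)) {
    dup <- sequences[duplicated(sequences)][1]
    stop(sprintf("whitelist contains duplicated sequence '%s'", dup),
         call. = FALSE)
  }
  if (is.null(well_labels)) {
    well_labels <- sprintf("%s_%03d", round_id, seq_along(sequences))
  }
  stopifnot(length(well_labels) == length(sequences))
  structure(
    list(round_id = round_id, sequences = sequences,
         well_labels = as.character(well_labels), width = widths[1]),
    class = "ch_whitelist"
  )
}

#' @export
print.ch_whitelist <- function(x, ...) {
  cat(sprintf("<ch_whitelist %s: %d sequences of %d nt>\n",
              x$round_id, length(x$sequences), x$width))
  invisible(x)
}

#' Read a barcode whitelist from a TSV file
#'
#' One sequence per line, with an optional second tab-separated column of
#' well labels. Sequences must share one length, use only A/C/G/T and be
#' unique.
#'
#' @param path Path to the whitelist file.
#' @param round_id One of `"bc1"`, `"bc2"`, `"i5"`, `"i7"`.
#' @return A `ch_whitelist` object.
#' @examples
#' wl <- load_whitelist(system.file("extdata",
#'   "example_bc1_whitelist_synthetic.tsv", package = "chseq"), "bc1")
#' wl
#' @export
load_whitelist <- function(path, round_id = c("bc1", "bc2", "i5", "i7")) {
  round_id <- match.arg(round_id)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  seqs <- vapply(parts, `[[`, "", 1L)
  labs <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_, "")
  if (all(is.na(labs))) labs <- NULL
  new_whitelist(trimws(seqs), round_id, labs)
}

#' Write a whitelist to a TSV file
#'
#' @param wl A `ch_whitelist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_whitelist <- function(wl, path) {
  stopifnot(inherits(wl, "ch_whitelist"))
  writeLines(paste(wl$sequences, wl$well_labels, sep = "\t"), path)
  invisible(path)
}

#' Generate a random whitelist with a minimum pairwise Hamming distance
#'
#' Candidate sequences are sampled uniformly over ACGT and accepted greedily
#' when at least `min_dist` mismatches away from every accepted sequence.
#' A minimum distance of `2*m + 1` guarantees unique correction of up to `m`
#' substitution errors; `2*m + 2` additionally guarantees that reads with
#' `m + 1` errors are never assigned to the wrong entry.
#'
#' @param n Number of sequences.
#' @param width Sequence length in nt.
#' @param min_dist Minimum pairwise Hamming distance to enforce.
#' @param round_id Whitelist round identifier.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `ch_whitelist`.
#' @export
random_whitelist <- function(n, width, min_dist = 3L,
                             round_id = c("bc1", "bc2", "i5", "i7"),
                             seed = 1L) {
  round_id <- match.arg(round_id)
  stopifnot(n >= 1L, width >= 1L, min_dist >= 1L)
  rng <- local_rng(seed)
  bases <- c("A", "C", "G", "T")
  accepted <- matrix(NA_integer_, nrow = 0L, ncol = width)
  tries <- 0L
  max_tries <- 2000L * n
  while (nrow(accepted) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "could not place %d sequences of width %d at min distance %d",
        n, width, min_dist), call. = FALSE)
    }
    cand <- sample.int(4L, width, replace = TRUE)
    ok <- nrow(accepted) == 0L ||
      min(rowSums(accepted != matrix(cand, nrow(accepted), width,
                                     byrow = TRUE))) >= min_dist
    if (ok) accepted <- rbind(accepted, cand)
  }
  seqs <- apply(accepted, 1L, function(r) paste(bases[r], collapse = ""))
  new_whitelist(seqs, round_id)
}

#' Build a single-substitution barcode correction index
#'
#' Enumerates every sequence within `max_mismatch` substitutions of a
#' whitelist entry. Sequences reachable from two or more entries are flagged
#' ambiguous and are never assigned. Only `max_mismatch` 0 or 1 is supported:
#' with hundreds of entries per round, two-mismatch neighbourhoods collide
#' heavily and correction would no longer be reliable.
#'
#' @param wl A `ch_whitelist`.
#' @param max_mismatch 0 (exact match only) or 1.
#' @return A `ch_correction_index`: lookup table from observed k-mer to
#'   whitelist position and mismatch count, with an ambiguity flag.
#' @export
build_correction_index <- function(wl, max_mismatch = 1L) {
  stopifnot(inherits(wl, "ch_whitelist"))
  max_mismatch <- as.integer(max_mismatch)
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0", call. = FALSE)
  if (max_mismatch > 1L) {
    stop("max_mismatch > 1 is unsupported: neighbourhood collisions make ",
         "correction unreliable for large whitelists", call. = FALSE)
  }
  seqs <- wl$sequences
  n <- length(seqs)
  kmer <- seqs
  entry <- seq_len(n)
  mm <- rep(0L, n)
  if (max_mismatch == 1L) {
    bases <- c("A", "C", "G", "T")
    for (p in seq_len(wl$width)) {
      orig <- substr(seqs, p, p)
      for (b in bases) {
        keep <- orig != b
        if (!any(keep)) next
        mut <- seqs[keep]
        substr(mut, p, p) <- b
        kmer <- c(kmer, mut)
        entry <- c(entry, which(keep))
        mm <- c(mm, rep(1L, sum(keep)))
      }
    }
  }
  # a k-mer reachable from >1 distinct entries is ambiguous, except that an
  # exact whitelist sequence always maps to itself with 0 mismatches
  ord <- order(kmer, mm)
  kmer <- kmer[ord]; entry <- entry[ord]; mm <- mm[ord]
  first <- !duplicated(kmer)
  grp <- cumsum(first)
  n_entries <- vapply(split(entry, grp), function(e) length(unique(e)), 1L)
  ambiguous <- (n_entries > 1L)[grp][first] & mm[first] > 0L
  structure(
    list(round_id = wl$round_id, width = wl$width,
         max_mismatch = max_mismatch, n_entries = n,
         kmer = kmer[first], entry = entry[first],
         mismatches = mm[first], ambiguous = ambiguous),
    class = "ch_correction_index"
  )
}

#' @export
print.ch_correction_index <- function(x, ...) {
  cat(sprintf(
    "<ch_correction_index %s: %d entries, max_mismatch %d, %d k-mers (%d ambiguous)>\n",
    x$round_id, x$n_entries, x$max_mismatch, length(x$kmer), sum(x$ambiguous)))
  invisible(x)
}

#' Correct observed barcodes against an index
#'
#' Vectorised lookup: each observed sequence resolves to a unique whitelist
#' entry within the index's mismatch budget, or is reported `no_match` /
#' `ambiguous`.
#'
#' @param index A `ch_correction_index`.
#' @param observed Character vector of observed barcode sequences.
#' @return A tibble with one row per observed sequence: `observed`, `entry`
#'   (whitelist position or `NA`), `mismatches`, `status` (one of
#'   `"matched"`, `"no_match"`, `"ambiguous"`).
#' @export
correct_barcodes <- function(index, observed) {
  stopifnot(inherits(index, "ch_correction_index"))
  hit <- match(observed, index$kmer)
  entry <- index$entry[hit]
  mm <- index$mismatches[hit]
  amb <- index$ambiguous[hit]
  status <- ifelse(is.na(hit), "no_match",
                   ifelse(amb, "ambiguous", "matched"))
  entry[status != "matched"] <- NA_integer_
  mm[status != "matched"] <- NA_integer_
  tibble::tibble(observed = observed, entry = entry,
                 mismatches = mm, status = status)
}
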
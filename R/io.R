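#' Write sequences as FASTQ
#'
#' Constant Q37 ('F') qualities; header description lines are preserved
#' verbatim, which is how the simulator carries i5/i7 index reads.
#'
#' @param seqs Character vector of sequences.
#' @param headers Description lines (without the leading `@`).
#' @param path Output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, headers, path) {
  stopifnot(length(seqs) == length(headers))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- headers
  qual <- Biostrings::BStringSet(strrep("F", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (optionally gzipped).
#' @return A list with `seqs` (character) and `headers` (full description
#'   lines).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(seqs = as.character(unname(x)), headers = names(x))
}

#' Write a digital expression matrix as a MatrixMarket trio
#'
#' Writes `matrix.mtx` (integer general coordinate format, rows = cells),
#' `barcodes.tsv` (cell keys) and `features.tsv` (gene id and species tag)
#' into `dir`.
#'
#' @param mat A cells x genes sparse count matrix (`dgCMatrix`) with cell
#'   keys as rownames and gene ids as colnames.
#' @param species Character vector of species tags parallel to the columns;
#'   taken from the `species` attribute of `mat` when `NULL`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_matrix_dir <- function(mat, dir, species = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(species)) species <- attr(mat, "species")
  if (is.null(species)) species <- rep(NA_character_, ncol(mat))
  Matrix::writeMM(methods::as(mat, "dgCMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat), file.path(dir, "barcodes.tsv"))
  writeLines(paste(colnames(mat), species, sep = "\t"),
             file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket trio back into a sparse count matrix
#'
#' @param dir Directory holding `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return A cells x genes `dgCMatrix` with a `species` attribute.
#' @export
read_matrix_dir <- function(dir) {
  mat <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  if (anyDuplicated(barcodes)) stop("duplicate cell keys in barcodes.tsv", call. = FALSE)
  stopifnot(nrow(mat) == length(barcodes), ncol(mat) == nrow(feats))
  dimnames(mat) <- list(barcodes, feats[[1]])
  attr(mat, "species") <- if (ncol(feats) >= 2L) feats[[2]] else rep(NA_character_, ncol(mat))
  mat
}
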
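#' Read and write the package's standard file formats
#'
#' Thin wrappers around Biostrings / readr / jsonlite keeping the package's
#' conventions: FASTA for sequences, BED6 (0-based half-open, tab-separated,
#' no header) for regions on the fictitious contig `chrSYN`, TSV for count /
#' label / expression tables, JSON for ground-truth records.
#'
#' @param x Object to write (see individual functions).
#' @param path File path.
#' @name zonereg_io
NULL

#' @describeIn zonereg_io Write a `seq_set` (or named character vector) as FASTA.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "seq_set")) {
    seqs <- Biostrings::DNAStringSet(x$sequences)
    names(seqs) <- x$ids
  } else {
    seqs <- Biostrings::DNAStringSet(x)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  }
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' @describeIn zonereg_io Read FASTA into a named character vector.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' @describeIn zonereg_io Write regions as BED6 (`chrom start end name score
#'   strand`); missing strand is written as `.`.
#' @export
write_bed6 <- function(x, path) {
  x <- genomic_regions(x)
  if (is.null(x[["strand"]])) x$strand <- "."
  bed <- dplyr::select(x, "chrom", "start", "end", "name", "score", "strand")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @describeIn zonereg_io Read BED6 into a region tibble.
#' @export
read_bed6 <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc"
  )
  genomic_regions(bed)
}

#' @describeIn zonereg_io Write a matrix (with rownames) or data frame as TSV.
#' @param id_column Name for the rowname column when writing a matrix.
#' @export
write_tsv_matrix <- function(x, path, id_column = "id") {
  if (is.matrix(x)) {
    df <- tibble::as_tibble(x, rownames = id_column)
  } else {
    df <- tibble::as_tibble(x)
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' @describeIn zonereg_io Read a TSV written by `write_tsv_matrix()` back into
#'   a matrix keyed by its first column.
#' @export
read_tsv_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' @describeIn zonereg_io Serialise a ground-truth record (list / tibble) as JSON.
#' @export
write_ground_truth <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @describeIn zonereg_io Read a ground-truth JSON file.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
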
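#' Read / write tab-delimited tables
#'
#' All tabular interchange (allele-count tables, gene read-count tables,
#' probe read counts, per-base depth) uses tab-delimited files with a
#' header row; lines starting with `#` are comments.
#'
#' @param path file path
#' @return a `data.table`
#' @export
read_tsv_table <- function(path) {
  stopifnot(file.exists(path))
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}

#' @rdname read_tsv_table
#' @param x a data.frame to write
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write BED3 intervals (0-based half-open, as internal)
#'
#' Out-of-range coordinates (negative start, end <= start) are rejected.
#'
#' @param path file path
#' @return data.frame with `chrom`, `start`, `end`
#' @export
read_bed3 <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end"),
                         select = 1:3, data.table = FALSE)
  if (any(x$start < 0) || any(x$end <= x$start)) {
    bad <- which(x$start < 0 | x$end <= x$start)[1]
    stop("out-of-range BED interval at line ", bad, ": ",
         x$chrom[bad], ":", x$start[bad], "-", x$end[bad])
  }
  x
}

#' @rdname read_bed3
#' @param x data.frame with chrom, start, end
#' @export
write_bed3 <- function(x, path) {
  data.table::fwrite(x[, c("chrom", "start", "end")], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over `Biostrings` returning plain named character
#' vectors, the representation used throughout the package.
#'
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
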
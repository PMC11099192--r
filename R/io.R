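#' Read and write FASTQ/FASTA via Biostrings
#'
#' Thin wrappers keeping the package's internal read representation (a plain
#' data.frame with id, sequence and quality string) in sync with standard
#' formats.
#'
#' @param reads data.frame with columns `id`, `sequence`, `qualities`.
#' @param path file path.
#' @return `read_fastq()` returns a data.frame (id, sequence, qualities);
#'   `read_fasta()` a named character vector.
#' @name io
NULL

#' @rdname io
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qualities))
  invisible(path)
}

#' @rdname io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x),
             sequence = as.character(x),
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname io
#' @param sequences named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read / write bedGraph-like methylation call tables
#'
#' Tab-separated with columns chrom, pos (0-based), strand, meth_count,
#' total_count. `read_meth_calls()` also accepts the Bismark coverage dialect
#' (chrom, start 1-based, end, percent, count_meth, count_unmeth), detected by
#' column count; Bismark coverage files carry no strand, so strand is set to
#' `"*"`.
#'
#' @param calls data.frame of calls.
#' @param path file path.
#' @name meth_io
NULL

#' @rdname meth_io
#' @export
write_meth_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname meth_io
#' @export
read_meth_calls <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, fixed = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 5L) {
    names(df) <- c("chrom", "pos", "strand", "meth_count", "total_count")
  } else if (ncol(df) == 6L) {  # Bismark coverage: chrom start end pct m u
    df <- data.frame(chrom = df[[1]], pos = df[[2]] - 1L, strand = "*",
                     meth_count = df[[5]], total_count = df[[5]] + df[[6]],
                     stringsAsFactors = FALSE)
  } else stop("unrecognised methylation-call table layout (", ncol(df), " columns)")
  df
}
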
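#' Sequence file I/O
#'
#' Thin wrappers around Biostrings readers/writers that move between the
#' package's plain named-character representation and `DNAStringSet`.
#' FASTQ output carries dummy "I" qualities (simulated reads have no real
#' base-quality model).
#'
#' @param path file path.
#' @return [read_fasta()] and [read_fastq()] return a named character
#'   vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              format = "fasta")
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}
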
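# DUST-style triplet-overrepresentation score: sum over distinct 3-mers t
# of c_t (c_t - 1) / 2, normalized by (number of triplets - 1). Low-
# complexity reads score high (a pure homopolymer of length L scores
# (L - 2) / 2); random sequence scores well below 1.
dust_score <- function(read) {
  L <- nchar(read)
  if (L < 4L) return(0)
  tri <- substring(read, 1:(L - 2L), 3:L)
  tab <- table(tri)
  sum(tab * (tab - 1) / 2) / (length(tri) - 1L)
}

#' Pre-assignment read quality control
#'
#' Applies the standard sedaDNA pre-assignment filters to merged reads, in
#' a fixed order so each read is removed for exactly one reason and the
#' report counts are additive: (1) reads shorter than `min_len` bp; (2)
#' exact sequence duplicates (first occurrence kept, input order); (3)
#' homopolymers (a single distinct base over the whole read); (4)
#' low-complexity reads whose DUST-style score exceeds `dust_threshold`.
#' The kept-read count is the denominator for relative sequence abundances
#' downstream.
#'
#' @param reads named character vector of merged read sequences (or a
#'   `DNAStringSet`).
#' @param min_len minimum length in bp (default 30; a 30-bp read is kept).
#' @param dust_threshold complexity score cutoff (default 2.0). The exact
#'   score is a configurable stand-in for an unparameterized external
#'   complexity filter.
#' @return class `qc_result`: list with `reads` (kept, input order
#'   preserved) and `report` (counts: n_input, n_kept, n_short,
#'   n_duplicate, n_homopolymer, n_low_complexity).
#' @export
#' @examples
#' qc <- filter_reads(c(a = strrep("ACGT", 15), b = strrep("A", 50)))
#' qc$report$n_homopolymer
filter_reads <- function(reads, min_len = 30, dust_threshold = 2.0) {
  if (!is.character(reads)) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  n_input <- length(reads)
  if (!n_input) {
    return(structure(list(
      reads = reads,
      report = list(n_input = 0L, n_kept = 0L, n_short = 0L,
                    n_duplicate = 0L, n_homopolymer = 0L,
                    n_low_complexity = 0L)), class = "qc_result"))
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read_%05d", seq_along(reads))
  }
  short <- nchar(reads) < min_len
  pool <- reads[!short]
  dup <- duplicated(pool)
  pool2 <- pool[!dup]
  homo <- grepl("^(.)\\1*$", pool2)
  pool3 <- pool2[!homo]
  lowc <- vapply(pool3, dust_score, numeric(1)) > dust_threshold
  kept <- pool3[!lowc]
  structure(list(
    reads = kept,
    report = list(n_input = n_input, n_kept = length(kept),
                  n_short = sum(short), n_duplicate = sum(dup),
                  n_homopolymer = sum(homo),
                  n_low_complexity = sum(lowc))), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "qc_result: kept %d / %d (short %d, duplicate %d, homopolymer %d, low-complexity %d)\n",
    r$n_kept, r$n_input, r$n_short, r$n_duplicate, r$n_homopolymer,
    r$n_low_complexity))
  invisible(x)
}
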
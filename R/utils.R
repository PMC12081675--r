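DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' @param x character vector of sequences over A/C/G/T (case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  out <- chartr("ACGTacgt", "TGCATGCA", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# complement of a base vector (already split); returns the reversed complement
revcomp_vec <- function(v) {
  rev(chartr("ACGT", "TGCA", v))
}

seq_split <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Deterministic sub-seed derivation: all randomness in a multi-stage
# operation flows from one user seed; stages get distinct offsets.
# Kept below 2^31 so the result is a valid R integer seed.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Convert a calendar year CE to years BP
#'
#' The BP (before present) convention anchors 0 BP at 1950 CE, so years
#' after 1950 have negative BP ages (e.g. a core retrieved in 2021 CE has a
#' surface age of -71 BP).
#'
#' @param ce calendar year(s) in the Common Era.
#' @return numeric age(s) in cal yr BP.
#' @export
#' @examples
#' ce_to_bp(2021) # -71
ce_to_bp <- function(ce) 1950 - ce
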
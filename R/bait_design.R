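#' Prepare a circular mitogenome for bait tiling
#'
#' Uppercases the sequence, replaces every non-ACGT character (IUPAC
#' ambiguity codes, N, gaps — any character that would break bait
#' synthesis) with thymine, and appends the first `bait_length` nucleotides
#' to the end so that baits can tile across the circular origin.
#'
#' @param genome nucleotide sequence (character scalar), length >=
#'   `bait_length`.
#' @param bait_length bait length in nt (default 80).
#' @return the extended, cleaned sequence (length `nchar(genome) +
#'   bait_length`).
#' @export
#' @examples
#' circularize_and_clean(strrep("ACGT", 25))
circularize_and_clean <- function(genome, bait_length = 80) {
  g <- toupper(as.character(genome))
  if (nchar(g) < bait_length) {
    stop("genome shorter than bait length (", bait_length, " nt)")
  }
  g <- gsub("[^ACGT]", "T", g)
  paste0(g, substr(g, 1L, bait_length))
}

#' Tile fixed-step baits over an extended circular genome
#'
#' Bait start offsets are `0, step, 2*step, ...` strictly below the
#' original (uncircularized) genome length; each bait is a contiguous
#' `bait_length`-nt window of the extended sequence. When the genome length
#' is divisible by `step`, every circular position is covered exactly
#' `bait_length / step` times (4x for the 80/20 defaults).
#'
#' @param extended output of [circularize_and_clean()].
#' @param original_length the uncircularized genome length in bp.
#' @param bait_length bait length (default 80 nt).
#' @param step tiling step (default 20 nt; a new bait every 20 nt). If
#'   `bait_length` is not divisible by `step`, circular coverage is uneven
#'   and a warning is issued.
#' @return data.frame with columns `sequence` and `start` (0-based offset).
#' @export
tile_baits <- function(extended, original_length, bait_length = 80,
                       step = 20) {
  stopifnot(original_length >= 1, nchar(extended) >= original_length)
  if (bait_length %% step != 0) {
    warning("bait_length is not divisible by step; circular coverage ",
            "will be uneven")
  }
  starts <- seq.int(0L, original_length - 1L, by = step)
  data.frame(
    sequence = substring(extended, starts + 1L, starts + bait_length),
    start = starts,
    stringsAsFactors = FALSE)
}

#' Deduplicate a pooled bait set into the final panel
#'
#' Exact forward-strand string deduplication: the first occurrence (by
#' genome input order, then start offset) of each sequence is retained.
#' Reverse complements are not collapsed — bait synthesis is
#' strand-specific.
#'
#' @param baits data.frame with columns `sequence`, `genome_id`, `start`
#'   (pooled across genomes, in genome input order).
#' @return class `bait_panel`: list with `baits` (the retained rows),
#'   `n_input`, `n_unique`, and `per_genome` (data.frame: genome_id,
#'   n_baits, n_unique_contributed).
#' @export
dedupe_panel <- function(baits) {
  stopifnot(all(c("sequence", "genome_id", "start") %in% names(baits)))
  keep <- !duplicated(baits$sequence)
  kept <- baits[keep, , drop = FALSE]
  rownames(kept) <- NULL
  per_genome <- data.frame(
    genome_id = unique(baits$genome_id),
    stringsAsFactors = FALSE)
  per_genome$n_baits <- as.integer(
    table(factor(baits$genome_id, per_genome$genome_id)))
  per_genome$n_unique_contributed <- as.integer(
    table(factor(kept$genome_id, per_genome$genome_id)))
  structure(list(baits = kept, n_input = nrow(baits),
                 n_unique = nrow(kept), per_genome = per_genome),
            class = "bait_panel")
}

#' @export
print.bait_panel <- function(x, ...) {
  cat("bait_panel:", x$n_unique, "unique baits from", x$n_input,
      "tiled baits across", nrow(x$per_genome), "genomes\n")
  invisible(x)
}

#' Design a hybridization-capture bait panel over circular mitogenomes
#'
#' Full panel design: each genome is circularized and ambiguity-masked
#' ([circularize_and_clean()]), tiled with fixed-step baits
#' ([tile_baits()]), and the pooled baits are deduplicated panel-wide
#' ([dedupe_panel()]).
#'
#' @param genomes named character vector of genome sequences, or a path to
#'   a multi-FASTA file.
#' @param bait_length bait length in nt (default 80).
#' @param step tiling step in nt (default 20).
#' @return a `bait_panel` (see [dedupe_panel()]).
#' @export
#' @examples
#' design_baits(c(g1 = strrep("ACGT", 50)))
design_baits <- function(genomes, bait_length = 80, step = 20) {
  if (is.character(genomes) && length(genomes) == 1L && is.null(names(genomes))
      && file.exists(genomes)) {
    genomes <- read_fasta(genomes)
  }
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    stop("genomes must be named")
  }
  tiled <- lapply(names(genomes), function(id) {
    ext <- circularize_and_clean(genomes[[id]], bait_length)
    b <- tile_baits(ext, nchar(genomes[[id]]), bait_length, step)
    b$genome_id <- id
    b
  })
  pooled <- do.call(rbind, tiled)[, c("sequence", "genome_id", "start")]
  dedupe_panel(pooled)
}

#' Write a bait panel to FASTA plus a TSV summary
#'
#' Bait headers are `{genome_id}:{start}`.
#'
#' @param panel a `bait_panel`.
#' @param fasta_path output FASTA path.
#' @param summary_path optional TSV path for the per-genome summary.
#' @return `fasta_path`, invisibly.
#' @export
write_bait_panel <- function(panel, fasta_path, summary_path = NULL) {
  stopifnot(inherits(panel, "bait_panel"))
  seqs <- stats::setNames(
    panel$baits$sequence,
    sprintf("%s:%d", panel$baits$genome_id, panel$baits$start))
  write_fasta(seqs, fasta_path)
  if (!is.null(summary_path)) {
    utils::write.table(panel$per_genome, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
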
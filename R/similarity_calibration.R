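#' Globally align two genome sequences
#'
#' Simple global pairwise alignment (match 1 / mismatch -1 / linear gap -2)
#' used to put synthetic genome pairs on a common coordinate system before
#' 50-mer fragmentation. Real-data use ingests a pre-made multiple
#' alignment instead; building MSAs is out of scope.
#'
#' @param a,b nucleotide sequences (character scalars).
#' @return list with `a` and `b`: equal-length aligned sequences with `-`
#'   gap characters.
#' @export
align_pair <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

#' Fragment an aligned genome pair into k-mer identity comparisons
#'
#' Each fragment is `k` consecutive alignment columns containing no gap in
#' either sequence; its identity is the fraction of matching columns. The
#' default sliding mode takes every eligible window (deterministic, no
#' sampling noise); random mode samples `n` eligible windows with
#' replacement under a seed.
#'
#' @param aligned list with equal-length aligned sequences `a` and `b`
#'   (e.g. from [align_pair()]), or two aligned rows of an MSA.
#' @param k fragment length in alignment columns (default 50).
#' @param mode `"sliding"` (all gap-free windows) or `"random"`.
#' @param n number of fragments in random mode.
#' @param seed seed for random mode.
#' @param relation optional label: `"within-species"` or
#'   `"between-species"`.
#' @param genome_a,genome_b optional genome identifiers.
#' @return class `pair_comparison`: list with `identities` (fractions
#'   between 0 and 1), `n_mismatch` (per-fragment mismatch counts), `k`, `relation`,
#'   `genome_a`, `genome_b`.
#' @export
fragment_pair <- function(aligned, k = 50, mode = c("sliding", "random"),
                          n = 10000, seed = NULL, relation = NA_character_,
                          genome_a = NA_character_,
                          genome_b = NA_character_) {
  mode <- match.arg(mode)
  va <- toupper(seq_split(aligned$a))
  vb <- toupper(seq_split(aligned$b))
  if (length(va) != length(vb)) stop("aligned sequences differ in length")
  gapfree <- va != "-" & vb != "-"
  match_col <- gapfree & va == vb
  L <- length(va)
  if (L < k) stop("no gap-free window of length k (alignment too short)")
  # windows of k columns, all gap-free
  cg <- cumsum(as.integer(gapfree))
  cm <- cumsum(as.integer(match_col))
  starts <- seq_len(L - k + 1L)
  win_gapfree <- cg[starts + k - 1L] - c(0L, cg)[starts]
  eligible <- starts[win_gapfree == k]
  if (!length(eligible)) {
    stop("no gap-free window of length k (empty comparison)")
  }
  if (mode == "random") {
    set_seed_if(seed)
    eligible <- sample(eligible, n, replace = TRUE)
  }
  matches <- cm[eligible + k - 1L] - c(0L, cm)[eligible]
  structure(list(identities = matches / k,
                 n_mismatch = as.integer(k - matches),
                 k = as.integer(k), relation = relation,
                 genome_a = genome_a, genome_b = genome_b),
            class = "pair_comparison")
}

# mismatch cutoff for "identity >= 1 - t": at most floor(t * k) mismatches
mismatch_cutoff <- function(t, k) floor(t * k + 1e-9)

#' Summarize fragment identities into the standard similarity bins
#'
#' Pools fragments (from one comparison or a list of comparisons with the
#' same `k`) into three half-open identity bins: >= 98%, [95%, 98%), and
#' < 95%. Bin membership is decided on integer mismatch counts, so for
#' k = 50 the bins hold fragments with <= 1, exactly 2, and >= 3
#' mismatches respectively.
#'
#' @param comparisons a `pair_comparison` or list of them.
#' @return class `similarity_bins`: list with `frac_ge98`, `frac_95_98`,
#'   `frac_lt95` (summing to 1), `n` fragments, and `k`.
#' @export
summarize_bins <- function(comparisons) {
  if (inherits(comparisons, "pair_comparison")) {
    comparisons <- list(comparisons)
  }
  if (!length(comparisons)) stop("empty comparison group")
  k <- unique(vapply(comparisons, `[[`, integer(1), "k"))
  if (length(k) != 1L) stop("comparisons use different fragment lengths")
  mism <- unlist(lapply(comparisons, `[[`, "n_mismatch"))
  n <- length(mism)
  if (!n) stop("empty comparison group")
  c98 <- mismatch_cutoff(0.02, k)
  c95 <- mismatch_cutoff(0.05, k)
  structure(list(
    frac_ge98 = sum(mism <= c98) / n,
    frac_95_98 = sum(mism > c98 & mism <= c95) / n,
    frac_lt95 = sum(mism > c95) / n,
    n = n, k = k), class = "similarity_bins")
}

#' @export
print.similarity_bins <- function(x, ...) {
  cat(sprintf(
    "similarity_bins (n = %d, k = %d): >=98%%: %.1f%%; 95-98%%: %.1f%%; <95%%: %.1f%%\n",
    x$n, x$k, 100 * x$frac_ge98, 100 * x$frac_95_98, 100 * x$frac_lt95))
  invisible(x)
}

#' Recommend an LCA identity threshold from fragment distributions
#'
#' Scans a grid of candidate divergence thresholds (a threshold `t` keeps
#' fragments with identity >= 1 - t, i.e. at most `floor(t*k)` mismatches)
#' and returns the most stringent (smallest) threshold whose within-species
#' fragment retention meets the target, reporting the between-species
#' leakage (fraction of between-species fragments that would survive) at
#' that threshold. A stringent threshold that still retains nearly all
#' within-species fragments maximizes species-level resolution while
#' keeping cross-species misassignment low; if no candidate meets the
#' target, the best achievable is returned and flagged.
#'
#' @param within a `pair_comparison`/list: within-species fragments.
#' @param between a `pair_comparison`/list: between-species fragments
#'   (same subfamily).
#' @param candidates candidate divergence thresholds (fractions), default
#'   `c(0.05, 0.02, 0.01, 0)`.
#' @param retention_target minimum within-species retention (default 0.95).
#' @return class `threshold_recommendation`: list with `threshold`
#'   (divergence fraction), `min_identity` (`1 - threshold`), `retention`,
#'   `leakage`, `attained` (logical: target met), and `grid` (per-candidate
#'   retention/leakage table).
#' @export
recommend_threshold <- function(within, between,
                                candidates = c(0.05, 0.02, 0.01, 0),
                                retention_target = 0.95) {
  pool <- function(x) {
    if (inherits(x, "pair_comparison")) x <- list(x)
    list(mism = unlist(lapply(x, `[[`, "n_mismatch")),
         k = unique(vapply(x, `[[`, integer(1), "k")))
  }
  w <- pool(within); b <- pool(between)
  if (length(w$k) != 1L || length(b$k) != 1L || w$k != b$k) {
    stop("within and between comparisons must share one fragment length")
  }
  k <- w$k
  grid <- data.frame(threshold = sort(candidates))
  grid$min_identity <- 1 - grid$threshold
  grid$retention <- vapply(grid$threshold, function(t) {
    mean(w$mism <= mismatch_cutoff(t, k))
  }, numeric(1))
  grid$leakage <- vapply(grid$threshold, function(t) {
    mean(b$mism <= mismatch_cutoff(t, k))
  }, numeric(1))
  ok <- which(grid$retention >= retention_target)
  if (length(ok)) {
    pick <- ok[1]  # smallest qualifying divergence threshold
    attained <- TRUE
  } else {
    pick <- which.max(grid$retention)
    attained <- FALSE
    warning("no candidate threshold reaches the retention target; ",
            "reporting best achievable")
  }
  structure(list(threshold = grid$threshold[pick],
                 min_identity = grid$min_identity[pick],
                 retention = grid$retention[pick],
                 leakage = grid$leakage[pick],
                 attained = attained, grid = grid,
                 retention_target = retention_target),
            class = "threshold_recommendation")
}

#' @export
print.threshold_recommendation <- function(x, ...) {
  cat(sprintf(
    "recommended divergence threshold: %.0f%% (identity >= %.0f%%)\n",
    100 * x$threshold, 100 * x$min_identity))
  cat(sprintf("  within-species retention: %.1f%% (target %.0f%%%s)\n",
              100 * x$retention, 100 * x$retention_target,
              if (x$attained) "" else ", NOT attained"))
  cat(sprintf("  between-species leakage: %.1f%%\n", 100 * x$leakage))
  invisible(x)
}
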
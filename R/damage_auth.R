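#' Position-specific deamination profile
#'
#' Counts C->T substitutions by position from the 5' end and G->A by
#' position from the 3' end over deduplicated, ungapped alignments.
#' Minus-strand alignments are put back in original-molecule orientation
#' (the reference span is reverse-complemented) before counting, so the
#' profile is strand-invariant. Rates condition on the reference base
#' (positions with a reference C at the 5' end / G at the 3' end form the
#' denominator), the standard deamination-rate convention. Positions with
#' fewer than `min_obs` observations are masked (NA): sparse cells say
#' nothing reliable about damage.
#'
#' @param records ungapped alignment records (after positional dedup).
#' @param reads named character vector of read sequences in original
#'   molecule orientation.
#' @param references named character vector of reference sequences.
#' @param P number of positions profiled from each end (default 25).
#' @param min_obs minimum observations per cell before a rate is reported
#'   (default 100).
#' @param circular interpret reference coordinates modulo the reference
#'   length (default TRUE).
#' @return class `damage_profile`: list with `ct5`/`ga3` (masked rates,
#'   length P), `ct5_count`/`n5`/`ga3_count`/`n3` (raw counts), `P`,
#'   `min_obs`, `n_reads` and `mean_terminal` (mean of the last three
#'   positions of both ends).
#' @export
substitution_profile <- function(records, reads, references, P = 25,
                                 min_obs = 100, circular = TRUE) {
  ct5 <- n5 <- ga3 <- n3 <- integer(P)
  refvec <- lapply(references, function(s) seq_split(toupper(s)))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    read <- reads[[r$query_id]]
    if (is.null(read) || is.na(read)) next
    rv <- seq_split(toupper(read))
    len <- length(rv)
    rf <- refvec[[r$ref_id]]
    L <- length(rf)
    idx <- (r$ref_start):(r$ref_end - 1L)
    if (circular) idx <- idx %% L
    span <- rf[idx + 1L]
    if (length(span) != len) next  # gapped record; profile needs ungapped
    if (r$strand == "-") span <- revcomp_vec(span)
    m <- min(P, len)
    # 5' end
    isC <- span[1:m] == "C"
    n5[1:m] <- n5[1:m] + isC
    ct5[1:m] <- ct5[1:m] + (isC & rv[1:m] == "T")
    # 3' end, position 1 = terminal base
    tail_idx <- len - 0:(m - 1L)
    isG <- span[tail_idx] == "G"
    n3[1:m] <- n3[1:m] + isG
    ga3[1:m] <- ga3[1:m] + (isG & rv[tail_idx] == "A")
  }
  new_damage_profile(ct5, n5, ga3, n3, P, min_obs, nrow(records))
}

new_damage_profile <- function(ct5, n5, ga3, n3, P, min_obs, n_reads) {
  rate <- function(num, den) {
    r <- ifelse(den > 0, num / den, NA_real_)
    r[den < min_obs] <- NA_real_
    r
  }
  prof <- structure(list(
    ct5 = rate(ct5, n5), ga3 = rate(ga3, n3),
    ct5_count = ct5, n5 = n5, ga3_count = ga3, n3 = n3,
    P = as.integer(P), min_obs = min_obs, n_reads = n_reads),
    class = "damage_profile")
  prof$mean_terminal <- mean_terminal_damage(prof)
  prof
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf(
    "damage_profile: %d reads; 5' C->T pos1 = %s; 3' G->A pos1 = %s; mean terminal = %s\n",
    x$n_reads, format(x$ct5[1], digits = 3), format(x$ga3[1], digits = 3),
    format(x$mean_terminal, digits = 3)))
  invisible(x)
}

#' Mean terminal deamination
#'
#' Arithmetic mean of the deamination rates at the last `k` positions of
#' both ends (2k cells; masked cells are dropped). The single-number
#' damage summary used to authenticate detections across samples.
#'
#' @param profile a [substitution_profile()] result.
#' @param k terminal positions per end (default 3).
#' @return scalar rate (NA when every terminal cell is masked).
#' @export
mean_terminal_damage <- function(profile, k = 3) {
  stopifnot(profile$P >= k)
  vals <- c(profile$ct5[1:k], profile$ga3[1:k])
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Pool damage profiles by summing counts
#'
#' Rates are recomputed from the summed numerators and denominators, so
#' the pooled rate equals the count-weighted mean of the member rates.
#'
#' @param profiles list of `damage_profile`s with equal `P`.
#' @param min_obs masking threshold for the pooled profile (defaults to
#'   the first member's).
#' @return a pooled `damage_profile`.
#' @export
pool_damage_profiles <- function(profiles, min_obs = NULL) {
  stopifnot(length(profiles) >= 1)
  P <- unique(vapply(profiles, `[[`, integer(1), "P"))
  if (length(P) != 1L) stop("profiles have differing window sizes")
  if (is.null(min_obs)) min_obs <- profiles[[1]]$min_obs
  sum_of <- function(f) Reduce(`+`, lapply(profiles, `[[`, f))
  new_damage_profile(sum_of("ct5_count"), sum_of("n5"),
                     sum_of("ga3_count"), sum_of("n3"),
                     P, min_obs, sum_of("n_reads"))
}

#' Fragment-length histogram and reference coverage
#'
#' @param records alignment records (after positional dedup).
#' @param references named character vector of reference sequences.
#' @param circular wrap coverage positions modulo the reference length.
#' @return list with `length_hist` (data.frame `length`, `count`) and
#'   `coverage` (named list of per-position integer coverage vectors).
#' @export
summarize_fragments <- function(records, references, circular = TRUE) {
  lh <- as.data.frame(table(records$aligned_len), stringsAsFactors = FALSE)
  names(lh) <- c("length", "count")
  lh$length <- as.integer(lh$length)
  coverage <- lapply(names(references), function(rid) {
    L <- nchar(references[[rid]])
    rec <- records[records$ref_id == rid, , drop = FALSE]
    if (!nrow(rec)) return(integer(L))
    pos <- unlist(Map(seq.int, rec$ref_start, rec$ref_end - 1L),
                  use.names = FALSE)
    if (circular) pos <- pos %% L
    tabulate(pos + 1L, nbins = L)
  })
  names(coverage) <- names(references)
  list(length_hist = lh, coverage = coverage)
}

#' Bin samples into fixed-width age windows
#'
#' Bins are anchored at 0 cal yr BP and half-open: `[0, width)`,
#' `[width, 2*width)`, ... — a sample dated exactly at a boundary falls in
#' the older bin. Pooling per-bin damage is done by summing substitution
#' counts before computing rates (see [pool_damage_profiles()]).
#'
#' @param samples data.frame with `sample_id` and `age_median` (cal yr
#'   BP).
#' @param width bin width in years (default 3000).
#' @return data.frame `sample_id`, `age_median`, `bin_start`, `bin_end`.
#' @export
bin_by_age <- function(samples, width = 3000) {
  stopifnot(all(c("sample_id", "age_median") %in% names(samples)))
  b <- floor(samples$age_median / width)
  data.frame(sample_id = samples$sample_id,
             age_median = samples$age_median,
             bin_start = b * width, bin_end = (b + 1) * width,
             stringsAsFactors = FALSE)
}

#' Pooled damage profiles per age bin
#'
#' @param samples data.frame with `sample_id`, `age_median`.
#' @param profiles named list of per-sample `damage_profile`s.
#' @param width bin width in years (default 3000).
#' @return data.frame of bins (`bin_start`, `bin_end`, `n_samples`,
#'   `mean_terminal`) with the pooled profiles in attribute `profiles`.
#' @export
bin_damage_profiles <- function(samples, profiles, width = 3000) {
  bins <- bin_by_age(samples, width)
  starts <- sort(unique(bins$bin_start))
  pooled <- lapply(starts, function(s) {
    ids <- bins$sample_id[bins$bin_start == s]
    pool_damage_profiles(profiles[ids])
  })
  names(pooled) <- as.character(starts)
  out <- data.frame(
    bin_start = starts, bin_end = starts + width,
    n_samples = vapply(starts, function(s) sum(bins$bin_start == s),
                       integer(1)),
    mean_terminal = vapply(pooled, `[[`, numeric(1), "mean_terminal"))
  rownames(out) <- NULL
  attr(out, "profiles") <- pooled
  out
}
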
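#' Align reads to a reference panel with exact k-mer seeds
#'
#' Minimal seed-and-extend aligner for short merged reads against small
#' mitogenome panels. References are indexed on both strands via exact
#' k-mer seeds; every candidate diagonal is evaluated by an ungapped
#' full-read comparison, and every reference hit with identity at or above
#' the floor is reported (all hits, not best-only) — the downstream LCA
#' needs the complete hit set. Coordinates are 0-based half-open. For
#' circular references, reads spanning the origin align into an extended
#' copy and `ref_end` may exceed the reference length; positions are
#' interpreted modulo the length.
#'
#' @param reads named character vector of read sequences (original
#'   molecule orientation).
#' @param references named character vector of reference sequences.
#' @param seed_k exact seed length (default 16). Reads shorter than
#'   `seed_k` are skipped (reported via a message).
#' @param min_identity_floor minimum identity for a hit to be reported
#'   (default 0.80); the LCA applies its own, stricter threshold.
#' @param circular treat references as circular (default TRUE, the
#'   mitogenome case).
#' @return data.frame of alignment records, ordered by query input order
#'   then `ref_id` then `ref_start`: `query_id`, `ref_id`, `ref_start`,
#'   `ref_end` (0-based half-open), `strand`, `n_mismatch`, `aligned_len`,
#'   `identity`.
#' @export
align_reads <- function(reads, references, seed_k = 16,
                        min_identity_floor = 0.80, circular = TRUE) {
  stopifnot(length(references) >= 1)
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read_%05d", seq_along(reads))
  }
  if (is.null(names(references))) stop("references must be named")
  max_rl <- max(nchar(reads), 0L)
  # per-reference extended char vectors + k-mer index
  ref_data <- lapply(names(references), function(rid) {
    s <- toupper(references[[rid]])
    L <- nchar(s)
    ext <- if (circular) paste0(s, substr(s, 1L, min(max_rl - 1L, L))) else s
    v <- seq_split(ext)
    nk <- nchar(ext) - seed_k + 1L
    if (nk < 1L) return(NULL)
    kmers <- substring(ext, 1:nk, seed_k:nchar(ext))
    list(id = rid, L = L, vec = v, index = split(seq_len(nk), kmers))
  })
  names(ref_data) <- names(references)

  out <- vector("list", length(reads))
  skipped <- 0L
  for (qi in seq_along(reads)) {
    read_fwd <- toupper(reads[[qi]])
    rl <- nchar(read_fwd)
    if (rl < seed_k) { skipped <- skipped + 1L; next }
    hits <- list()
    for (orient in c("+", "-")) {
      rs <- if (orient == "+") read_fwd else revcomp(read_fwd)
      rv <- seq_split(rs)
      kpos <- 1:(rl - seed_k + 1L)
      kms <- substring(rs, kpos, kpos + seed_k - 1L)
      for (rd in ref_data) {
        if (is.null(rd)) next
        m <- rd$index[kms]
        found <- !vapply(m, is.null, logical(1))
        if (!any(found)) next
        offs <- unlist(m[found], use.names = FALSE) -
          rep(kpos[found], times = lengths(m[found]))
        offs <- unique(offs[offs >= 0L & offs < rd$L &
                              (offs + rl) <= length(rd$vec)])
        for (off in offs) {
          mism <- sum(rd$vec[(off + 1L):(off + rl)] != rv)
          ident <- (rl - mism) / rl
          if (ident >= min_identity_floor) {
            hits[[length(hits) + 1L]] <- data.frame(
              query_id = names(reads)[qi], ref_id = rd$id,
              ref_start = as.integer(off), ref_end = as.integer(off + rl),
              strand = orient, n_mismatch = as.integer(mism),
              aligned_len = as.integer(rl), identity = ident,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(hits)) {
      h <- do.call(rbind, hits)
      out[[qi]] <- h[order(h$ref_id, h$ref_start, h$strand), , drop = FALSE]
    }
  }
  if (skipped) {
    message(skipped, " read(s) shorter than the seed length were skipped")
  }
  res <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- data.frame(query_id = character(), ref_id = character(),
                      ref_start = integer(), ref_end = integer(),
                      strand = character(), n_mismatch = integer(),
                      aligned_len = integer(), identity = numeric(),
                      stringsAsFactors = FALSE)
  }
  res
}

#' Ingest alignments from a SAM file
#'
#' Reads a SAM file (with `@SQ` header lines and `NM` tags) into the
#' package's alignment-record data.frame. Identity treats indels as
#' mismatches over alignment columns: `identity = (columns - NM) /
#' columns` with columns = M + I + D cigar operations. SAM stores
#' minus-strand reads reference-oriented; the returned `reads` vector is
#' flipped back to the original molecule orientation for damage profiling.
#'
#' @param path SAM file path.
#' @return list with `records` (data.frame as from [align_reads()]) and
#'   `reads` (named character, molecule orientation).
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ".bam"),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "seq"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (!length(x$qname)) {
    stop("SAM file contains no mapped records")
  }
  nm <- x$tag$NM
  if (is.null(nm) || anyNA(nm)) {
    stop("SAM records lack NM tags; identity cannot be computed ",
         "(provide NM-tagged input)")
  }
  cols <- GenomicAlignments::cigarWidthAlongPairwiseSpace(x$cigar)
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar)
  minus <- as.character(x$strand) == "-"
  seqs <- as.character(x$seq)
  seqs[minus] <- revcomp(seqs[minus])
  records <- data.frame(
    query_id = x$qname, ref_id = as.character(x$rname),
    ref_start = x$pos - 1L, ref_end = x$pos - 1L + ref_w,
    strand = as.character(x$strand), n_mismatch = as.integer(nm),
    aligned_len = as.integer(cols),
    identity = (cols - nm) / cols, stringsAsFactors = FALSE)
  reads <- seqs[!duplicated(x$qname)]
  names(reads) <- x$qname[!duplicated(x$qname)]
  list(records = records, reads = reads)
}

#' Remove positional duplicate alignments
#'
#' Within one sample, alignments sharing the same reference and the same
#' start and end position are collapsed to the first record in query input
#' order (strand-insensitive: the same span on opposite strands
#' collapses). This removes amplification duplicates before unique
#' sequences are counted.
#'
#' @param records alignment data.frame (one representative record per
#'   read), rows in query input order.
#' @return the surviving rows.
#' @export
dedupe_alignments <- function(records) {
  if (!nrow(records)) return(records)
  key <- paste(records$ref_id, records$ref_start, records$ref_end,
               sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Assign one read to a taxon by threshold-filtered LCA
#'
#' Hits below the identity threshold are discarded; if none survive the
#' read is unassigned, otherwise the read is assigned to the lowest common
#' ancestor of the surviving hits' taxa. All hits passing the threshold
#' enter the LCA (no best-hit window).
#'
#' @param hits alignment records for one read.
#' @param tax a [taxonomy_tree()].
#' @param genome_taxid named integer: reference id -> taxid.
#' @param min_identity identity threshold in (0, 1]; 0.95 is the shotgun
#'   default and 0.98 the capture default (see
#'   [recommend_threshold()]).
#' @return the assigned taxid, or `NA_integer_` if unassigned.
#' @export
lca_assign <- function(hits, tax, genome_taxid, min_identity = 0.95) {
  stopifnot(min_identity > 0, min_identity <= 1)
  keep <- hits[hits$identity >= min_identity, , drop = FALSE]
  if (!nrow(keep)) return(NA_integer_)
  taxids <- genome_taxid[keep$ref_id]
  if (anyNA(taxids)) {
    stop("hit references a genome absent from the taxonomy: ",
         paste(unique(keep$ref_id[is.na(taxids)]), collapse = ", "))
  }
  tax_lca(tax, taxids)
}

# one representative alignment per read: highest identity, ties broken by
# ref_id then ref_start (records within a read are already so ordered)
best_records <- function(records) {
  if (!nrow(records)) return(records)
  sp <- split(seq_len(nrow(records)), records$query_id)
  # preserve query input order
  sp <- sp[unique(records$query_id)]
  idx <- vapply(sp, function(i) {
    i[which.max(records$identity[i])]
  }, integer(1))
  records[idx, , drop = FALSE]
}

#' Taxonomic profile of one sample
#'
#' Counts unique sequences per assigned taxon after positional duplicate
#' removal, and derives relative sequence abundances (unique sequences
#' divided by the sample's quality-filtered read count).
#'
#' @param assignments data.frame with `query_id` and `taxid` (NA =
#'   unassigned), one row per read.
#' @param records alignment records; each assigned read's representative
#'   (best) alignment is used for positional dedup.
#' @param n_qc_reads number of quality-filtered reads in the sample (the
#'   relative-abundance denominator).
#' @param tax a [taxonomy_tree()] (adds rank and name columns).
#' @return class `taxon_profile`: data.frame `taxid`, `rank`, `name`,
#'   `unique_sequences`, `relative_abundance`; attribute `n_qc_reads`.
#' @export
profile_sample <- function(assignments, records, n_qc_reads, tax) {
  stopifnot(n_qc_reads > 0)
  assigned <- assignments[!is.na(assignments$taxid), , drop = FALSE]
  if (nrow(assigned)) {
    rec <- records[records$query_id %in% assigned$query_id, , drop = FALSE]
    rep_rec <- best_records(rec)
    surv <- dedupe_alignments(rep_rec)
    surv_tax <- assigned$taxid[match(surv$query_id, assigned$query_id)]
    counts <- table(surv_tax)
    prof <- data.frame(taxid = as.integer(names(counts)),
                       unique_sequences = as.integer(counts),
                       stringsAsFactors = FALSE)
  } else {
    prof <- data.frame(taxid = integer(), unique_sequences = integer())
  }
  prof$rank <- tax$rank[match(prof$taxid, tax$taxid)]
  prof$name <- tax$name[match(prof$taxid, tax$taxid)]
  prof$relative_abundance <- prof$unique_sequences / n_qc_reads
  prof <- prof[order(-prof$unique_sequences, prof$taxid),
               c("taxid", "rank", "name", "unique_sequences",
                 "relative_abundance")]
  rownames(prof) <- NULL
  structure(prof, class = c("taxon_profile", "data.frame"),
            n_qc_reads = n_qc_reads)
}

#' Aggregate a profile to a fixed rank
#'
#' Rolls species/genus counts up to the chosen rank (e.g. the family-level
#' view used for shotgun data). Assignments above that rank (whose lineage
#' has no node of the rank) are dropped.
#'
#' @param profile a [profile_sample()] result.
#' @param tax a [taxonomy_tree()].
#' @param rank target rank (default `"family"`).
#' @return a `taxon_profile` at the target rank.
#' @export
profile_at_rank <- function(profile, tax, rank = "family") {
  n_qc <- attr(profile, "n_qc_reads")
  if (!nrow(profile)) return(profile)
  up <- vapply(profile$taxid, tax_ancestor_at_rank, integer(1),
               tax = tax, rank = rank)
  keep <- !is.na(up)
  agg <- stats::aggregate(
    list(unique_sequences = profile$unique_sequences[keep]),
    by = list(taxid = up[keep]), FUN = sum)
  agg$rank <- tax$rank[match(agg$taxid, tax$taxid)]
  agg$name <- tax$name[match(agg$taxid, tax$taxid)]
  agg$relative_abundance <- agg$unique_sequences / n_qc
  agg <- agg[order(-agg$unique_sequences, agg$taxid),
             c("taxid", "rank", "name", "unique_sequences",
               "relative_abundance")]
  rownames(agg) <- NULL
  structure(agg, class = c("taxon_profile", "data.frame"),
            n_qc_reads = n_qc)
}

#' Align, assign and profile one sample
#'
#' Convenience wrapper chaining [align_reads()], per-read [lca_assign()]
#' and [profile_sample()].
#'
#' @param reads quality-filtered reads of one sample.
#' @param references reference panel (named character).
#' @param tax a [taxonomy_tree()].
#' @param genome_taxid named integer: reference id -> taxid.
#' @param min_identity LCA identity threshold (0.98 capture default).
#' @param n_qc_reads relative-abundance denominator; defaults to
#'   `length(reads)`.
#' @param ... passed to [align_reads()].
#' @return list with `profile`, `assignments`, `records`.
#' @export
assign_sample <- function(reads, references, tax, genome_taxid,
                          min_identity = 0.98,
                          n_qc_reads = length(reads), ...) {
  records <- align_reads(reads, references, ...)
  qids <- unique(records$query_id)
  taxids <- vapply(qids, function(q) {
    lca_assign(records[records$query_id == q, , drop = FALSE],
               tax, genome_taxid, min_identity)
  }, integer(1))
  assignments <- data.frame(query_id = qids, taxid = taxids,
                            stringsAsFactors = FALSE)
  list(profile = profile_sample(assignments, records, n_qc_reads, tax),
       assignments = assignments, records = records)
}

#' Filter per-sample profiles into a detection table
#'
#' Applies the detection filters: capture mode keeps species-rank
#' detections with at least 3 unique sequences; shotgun mode aggregates to
#' family rank, excludes prokaryotes, and keeps families with at least 10
#' unique sequences. An optional report filter flags taxa present in at
#' least `min_samples` samples (taxa below it stay in the table with
#' `in_report = FALSE`, mirroring a visualization-only rule).
#'
#' @param profiles named list of `taxon_profile`s (names = sample ids).
#' @param tax a [taxonomy_tree()].
#' @param mode `"capture"` or `"shotgun"`.
#' @param min_unique minimum unique sequences per taxon; defaults to 3
#'   (capture) or 10 (shotgun). Boundary inclusive.
#' @param min_samples if non-NULL, taxa detected in fewer than this many
#'   samples get `in_report = FALSE`.
#' @return class `detection_table`: long data.frame `sample_id`, `taxid`,
#'   `rank`, `name`, `unique_sequences`, `relative_abundance`,
#'   `in_report`.
#' @export
filter_detections <- function(profiles, tax, mode = c("capture", "shotgun"),
                              min_unique = NULL, min_samples = NULL) {
  mode <- match.arg(mode)
  if (is.null(min_unique)) {
    min_unique <- if (mode == "capture") 3L else 10L
  }
  rows <- lapply(names(profiles), function(sid) {
    p <- profiles[[sid]]
    if (mode == "capture") {
      p <- p[p$rank == "species", , drop = FALSE]
    } else {
      p <- profile_at_rank(p, tax, "family")
    }
    p <- as.data.frame(p)
    if (nrow(p)) {
      p <- p[!tax_is_prokaryote(tax, p$taxid), , drop = FALSE]
    }
    p <- p[p$unique_sequences >= min_unique, , drop = FALSE]
    if (nrow(p)) cbind(sample_id = sid, p) else NULL
  })
  det <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(det)) {
    det <- data.frame(sample_id = character(), taxid = integer(),
                      rank = character(), name = character(),
                      unique_sequences = integer(),
                      relative_abundance = numeric())
  }
  det$in_report <- TRUE
  if (!is.null(min_samples) && nrow(det)) {
    n_samp <- table(det$taxid)
    det$in_report <- as.integer(n_samp[as.character(det$taxid)]) >=
      min_samples
  }
  structure(det, class = c("detection_table", "data.frame"), mode = mode)
}

#' Detection table as a samples-by-taxa matrix
#'
#' @param det a [filter_detections()] result.
#' @param value `"unique_sequences"` or `"relative_abundance"`.
#' @param report_only drop rows flagged out of the report filter.
#' @return numeric matrix, rownames = sample ids, colnames = taxon names.
#' @export
detection_matrix <- function(det, value = c("unique_sequences",
                                            "relative_abundance"),
                             report_only = FALSE) {
  value <- match.arg(value)
  d <- as.data.frame(det)
  if (report_only) d <- d[d$in_report, , drop = FALSE]
  samples <- unique(d$sample_id)
  taxa <- unique(d$name)
  m <- matrix(0, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  if (nrow(d)) {
    m[cbind(match(d$sample_id, samples), match(d$name, taxa))] <- d[[value]]
  }
  m
}
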
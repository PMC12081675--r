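test_that("exact substrings align with identity 1 at the right span", {
  g <- random_genome(800, seed = 1)
  read <- substr(g, 101, 160)
  rec <- align_reads(c(q = read), c(ref = g), circular = FALSE)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$ref_start, 100L)
  expect_equal(rec$ref_end, 160L)
  expect_equal(rec$strand, "+")
  expect_equal(rec$identity, 1)
  expect_equal(rec$ref_end - rec$ref_start, rec$aligned_len)
})

test_that("mismatches reduce identity by the direct count", {
  g <- random_genome(500, seed = 2)
  read <- substr(g, 51, 100) # 50 bp
  v <- strsplit(read, "")[[1]]
  v[25] <- setdiff(c("A", "C", "G", "T"), v[25])[1]
  rec <- align_reads(c(q = paste(v, collapse = "")), c(ref = g),
                     circular = FALSE)
  expect_equal(rec$n_mismatch, 1L)
  expect_equal(rec$identity, 0.98)
})

test_that("reverse-strand and origin-spanning reads are recovered", {
  g <- random_genome(600, seed = 3)
  rcv <- function(x) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  minus <- rcv(substr(g, 201, 260))
  rec <- align_reads(c(q = minus), c(ref = g), circular = FALSE)
  expect_equal(rec$strand, "-")
  expect_equal(rec$ref_start, 200L)
  # read crossing the circular origin
  wrap <- paste0(substr(g, 571, 600), substr(g, 1, 30))
  rec2 <- align_reads(c(q = wrap), c(ref = g), circular = TRUE)
  expect_equal(rec2$ref_start, 570L)
  expect_equal(rec2$identity, 1)
})

test_that("all references above the identity floor are reported", {
  g <- random_genome(2000, seed = 4)
  set.seed(5)
  sister <- mutate_genome(g, 0.01) # ~1% divergent sister species
  far <- mutate_genome(g, 0.4)
  read <- substr(g, 301, 400)
  rec <- align_reads(c(q = read), c(a = g, b = sister, c = far))
  expect_true(all(c("a", "b") %in% rec$ref_id))
  expect_false("c" %in% rec$ref_id)
  expect_true(all(rec$identity >= 0.80))
})

test_that("positional dedup keeps one record per reference span", {
  rec <- data.frame(
    query_id = c("q1", "q2", "q3", "q4"),
    ref_id = c("r", "r", "r", "s"),
    ref_start = c(10L, 10L, 10L, 10L),
    ref_end = c(60L, 60L, 70L, 60L),
    strand = c("+", "-", "+", "+"),
    n_mismatch = 0L, aligned_len = 50L, identity = 1,
    stringsAsFactors = FALSE)
  out <- dedupe_alignments(rec)
  # same span collapses (strand-insensitively); other spans/refs survive
  expect_equal(out$query_id, c("q1", "q3", "q4"))
})

test_that("dedup recovers the distinct-span count under injected duplication", {
  g <- random_genome(1000, seed = 6)
  sim <- simulate_reads(g, read_sim_spec(120, seed = 7))
  rec <- align_reads(sim$reads, c(ref = g))
  rep_rec <- rec[!duplicated(rec$query_id), ]
  # duplicate a third of the reads exactly
  dup <- rep_rec[seq_len(40), ]
  dup$query_id <- paste0(dup$query_id, "_dup")
  all_rec <- rbind(rep_rec, dup)
  surv <- dedupe_alignments(all_rec)
  key <- unique(paste(all_rec$ref_id, all_rec$ref_start, all_rec$ref_end))
  expect_equal(nrow(surv), length(key)) # set-based oracle
})

test_that("LCA assignment follows the identity threshold", {
  tax <- toy_taxonomy()
  g2t <- c(gA = 32L, gB = 34L, gC = 42L)
  hit <- function(ref, id) data.frame(
    query_id = "q", ref_id = ref, ref_start = 0L, ref_end = 50L,
    strand = "+", n_mismatch = as.integer(round(50 * (1 - id))),
    aligned_len = 50L, identity = id, stringsAsFactors = FALSE)
  # single surviving hit -> that species
  expect_equal(lca_assign(hit("gA", 1), tax, g2t, 0.95), 32L)
  # two confamilial seals -> family
  expect_equal(lca_assign(rbind(hit("gA", 1), hit("gB", 0.99)),
                          tax, g2t, 0.95), 30L)
  # the weaker hit drops out at a stricter threshold -> species again
  expect_equal(lca_assign(rbind(hit("gA", 1), hit("gB", 0.96)),
                          tax, g2t, 0.98), 32L)
  # nothing survives -> unassigned
  expect_true(is.na(lca_assign(hit("gA", 0.90), tax, g2t, 0.95)))
  # unknown reference is a data-integrity error
  expect_error(lca_assign(hit("gX", 1), tax, g2t, 0.95), "absent")
})

test_that("LCA agrees with the path-intersection oracle on random cases", {
  set.seed(8)
  for (i in 1:200) {
    tax <- random_taxonomy(sample(5:25, 1))
    taxids <- sample(tax$taxid, sample(1:4, 1), replace = TRUE)
    expect_identical(tax_lca(tax, taxids),
                     lca_oracle(tax, taxids))
  }
})

test_that("raising the threshold moves assignments toward the leaves", {
  set.seed(9)
  tax <- toy_taxonomy()
  g2t <- c(gA = 32L, gB = 34L, gC = 42L, gD = 11L)
  for (i in 1:100) {
    n <- sample(1:4, 1)
    hits <- data.frame(
      query_id = "q", ref_id = sample(names(g2t), n, replace = TRUE),
      ref_start = 0L, ref_end = 50L, strand = "+", n_mismatch = 0L,
      aligned_len = 50L, identity = runif(n, 0.9, 1),
      stringsAsFactors = FALSE)
    lo <- lca_assign(hits, tax, g2t, 0.92)
    hi <- lca_assign(hits, tax, g2t, 0.98)
    if (is.na(lo)) {
      expect_true(is.na(hi)) # fewer hits can only lose the assignment
    } else if (!is.na(hi)) {
      # the stricter assignment sits on or below the looser one
      expect_true(lo %in% tax_lineage(tax, hi))
    }
  }
})

test_that("profiles count unique sequences against the QC denominator", {
  tax <- toy_taxonomy()
  asg <- data.frame(query_id = paste0("q", 1:6),
                    taxid = c(32L, 32L, 32L, 32L, 32L, NA),
                    stringsAsFactors = FALSE)
  rec <- data.frame(
    query_id = paste0("q", 1:6), ref_id = "gA",
    ref_start = c(0L, 10L, 20L, 30L, 30L, 50L),
    ref_end = c(50L, 60L, 70L, 80L, 80L, 100L),
    strand = "+", n_mismatch = 0L, aligned_len = 50L, identity = 1,
    stringsAsFactors = FALSE)
  prof <- profile_sample(asg, rec, n_qc_reads = 100, tax)
  # q4/q5 share a span: 4 unique sequences out of 100 QC reads
  expect_equal(prof$unique_sequences, 4L)
  expect_equal(prof$relative_abundance, 0.04)
  expect_lte(sum(prof$unique_sequences), 100)
  # all unassigned -> empty profile
  asg$taxid <- NA_integer_
  empty <- profile_sample(asg, rec, 100, tax)
  expect_equal(nrow(empty), 0L)
})

test_that("detection filters apply mode-specific boundaries", {
  tax <- toy_taxonomy()
  mk_prof <- function(taxid, n) {
    structure(data.frame(
      taxid = taxid, rank = tax$rank[match(taxid, tax$taxid)],
      name = tax$name[match(taxid, tax$taxid)],
      unique_sequences = n, relative_abundance = n / 1000,
      stringsAsFactors = FALSE),
      class = c("taxon_profile", "data.frame"), n_qc_reads = 1000)
  }
  # capture: 3 unique sequences kept, 2 dropped (species rank)
  det <- filter_detections(list(S1 = mk_prof(c(32L, 34L), c(3L, 2L))),
                           tax, "capture")
  expect_equal(det$taxid, 32L)
  # shotgun: families at >= 10 kept, 9 dropped, prokaryotes excluded
  det2 <- filter_detections(
    list(S1 = mk_prof(c(32L, 42L, 11L), c(10L, 9L, 500L))),
    tax, "shotgun")
  expect_equal(det2$taxid, 30L) # Phocidae via roll-up; narwhal at 9 lost
  # report filter: taxa in a single sample flagged but retained
  det3 <- filter_detections(
    list(S1 = mk_prof(32L, 5L), S2 = mk_prof(c(32L, 42L), c(4L, 6L))),
    tax, "capture", min_samples = 2)
  expect_true(all(det3$in_report[det3$taxid == 32]))
  expect_false(any(det3$in_report[det3$taxid == 42]))
  expect_true(42L %in% det3$taxid)
  expect_error(filter_detections(list(), tax, "nonsense"))
})

test_that("SAM ingest reproduces the built-in aligner's records", {
  g <- random_genome(400, seed = 10)
  read <- substr(g, 101, 160)
  v <- strsplit(read, "")[[1]]
  v[10] <- setdiff(c("A", "C", "G", "T"), v[10])[1]
  mread <- paste(v, collapse = "")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:ref\tLN:400",
    paste("q1", 0, "ref", 101, 60, "60M", "*", 0, 0, mread,
          strrep("I", 60), "NM:i:1", sep = "\t"),
    paste("q2", 16, "ref", 201, 60, "60M", "*", 0, 0,
          substr(g, 201, 260), strrep("I", 60), "NM:i:0", sep = "\t")),
    sam)
  res <- read_sam(sam)
  expect_equal(nrow(res$records), 2L)
  r1 <- res$records[res$records$query_id == "q1", ]
  expect_equal(r1$ref_start, 100L)
  expect_equal(r1$ref_end, 160L)
  expect_equal(r1$identity, (60 - 1) / 60)
  # minus-strand SEQ is flipped back to molecule orientation
  r2 <- res$records[res$records$query_id == "q2", ]
  expect_equal(r2$strand, "-")
  rcv <- function(x) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  expect_equal(res$reads[["q2"]], rcv(substr(g, 201, 260)))
})

test_that("species truth is recovered end-to-end without false detections", {
  panel <- simulate_panel(2, 2, 2000, n_genera_per_family = 1,
                          divergence = c(order = 0.16, family = 0.10,
                                         genus = 0.06, species = 0.005),
                          seed = 11)
  core <- simulate_core(panel, n_samples = 4, reads_per_taxon = 25,
                        background_reads = 10, occupancy_intercept = 0,
                        d5_range = c(0.01, 0.1), seed = 12)
  profiles <- lapply(core$samples$sample_id, function(sid) {
    qc <- filter_reads(core$reads[[sid]])
    assign_sample(qc$reads, panel$genomes, panel$taxonomy,
                  panel$genome_taxid, min_identity = 0.98,
                  n_qc_reads = qc$report$n_kept)$profile
  })
  names(profiles) <- core$samples$sample_id
  det <- filter_detections(profiles, panel$taxonomy, "capture")
  truth <- core$truth_counts
  for (k in seq_len(nrow(det))) {
    occ <- truth$occupied[truth$sample_id == det$sample_id[k] &
                            truth$taxid == det$taxid[k]]
    expect_true(occ) # no species detected that truth says was absent
  }
})
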
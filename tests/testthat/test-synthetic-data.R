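pair_divergence <- function(a, b) {
  mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

test_that("zero divergence yields identical genomes", {
  p <- simulate_panel(2, 2, 1000,
                      divergence = c(order = 0, family = 0, genus = 0,
                                     species = 0), seed = 1)
  expect_length(unique(p$genomes), 1L)
})

test_that("realized pairwise divergence tracks the rank specification", {
  p <- simulate_panel(2, 2, 16500,
                      divergence = c(order = 0.16, family = 0.08,
                                     genus = 0.04, species = 0.01),
                      n_genomes_per_species = 2, seed = 7)
  g <- p$genomes
  tol <- function(d) 3 * sqrt(d * (1 - d) / 16500)
  # within one species (binomial sampling oracle, 3 SD band)
  expect_lt(abs(pair_divergence(g[["F1G1S1_1"]], g[["F1G1S1_2"]]) - 0.01),
            tol(0.01))
  # congeneric species
  expect_lt(abs(pair_divergence(g[["F1G1S1_1"]], g[["F1G1S2_1"]]) - 0.04),
            tol(0.04) + 0.002)  # small double-hit collision bias
  # confamilial genera: mean 50-mer identity ~ 1 - 0.08
  aln <- list(a = g[["F1G1S1_1"]], b = g[["F1G2S1_1"]])
  fp <- fragment_pair(aln, k = 50)
  expect_lt(abs(mean(fp$identities) - 0.92), 0.01)
  # every genome maps to exactly one species leaf
  expect_true(all(p$genome_taxid %in%
                    p$taxonomy$taxid[p$taxonomy$rank == "species"]))
  expect_true(all(grepl("^[ACGT]+$", g)))
})

test_that("invalid divergence ordering is a configuration error", {
  expect_error(
    simulate_panel(2, 2, 1000,
                   divergence = c(order = 0.01, family = 0.02,
                                  genus = 0.04, species = 0.08)),
    "invalid divergence ordering")
})

test_that("undamaged error-free reads are exact circular substrings", {
  g <- random_genome(1500, seed = 3)
  sim <- simulate_reads(g, read_sim_spec(200, seed = 11))
  doubled <- paste0(g, g)
  # a read must occur in the doubled genome, forward or reverse-complement
  rc <- function(x) chartr("ACGT", "TGCA",
                           vapply(strsplit(x, ""), function(v)
                             paste(rev(v), collapse = ""), character(1)))
  ok <- vapply(sim$reads, function(r) {
    grepl(r, doubled, fixed = TRUE) || grepl(rc(r), doubled, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
  expect_true(all(nchar(sim$reads) <= 125))
  expect_true(all(nchar(sim$reads) >= 30))
})

test_that("terminal deamination frequency matches the injected rate", {
  g <- random_genome(2000, seed = 5)
  gv <- strsplit(g, "")[[1]]
  n <- 8000
  sim <- simulate_reads(g, read_sim_spec(n, d5 = 0.3, decay = 0.3,
                                         seed = 13))
  # counting oracle on simulator truth: the molecule's first base is
  # genome[start] on + reads and the complement of the fragment's last
  # base on - reads
  t <- sim$truth
  L <- nchar(g)
  first_ref <- ifelse(
    t$strand == "+", gv[t$start],
    chartr("ACGT", "TGCA", gv[((t$start - 1 + t$length - 1) %% L) + 1]))
  is_c <- first_ref == "C"
  obs_t <- substr(sim$reads, 1, 1) == "T" & is_c
  phat <- sum(obs_t) / sum(is_c)
  se <- sqrt(0.3 * 0.7 / sum(is_c))
  expect_lt(abs(phat - 0.3), 1.96 * se + 1e-9)
})

test_that("read-spec validation rejects bad probabilities and lengths", {
  expect_error(read_sim_spec(10, d5 = 1.2), "probabilities")
  expect_error(read_sim_spec(10, length_min = 0))
  expect_error(simulate_reads(random_genome(100, seed = 1),
                              read_sim_spec(5, length_max = 125)),
               "exceeds genome length")
})

test_that("simulated cores have coherent samples, truth and proxies", {
  panel <- simulate_panel(1, 2, 1000, n_genera_per_family = 1, seed = 2)
  core <- simulate_core(panel, n_samples = 6, age_range = c(0, 9000),
                        reads_per_taxon = 10, background_reads = 5,
                        seed = 21)
  s <- core$samples
  expect_true(all(diff(s$age_median) > 0))
  expect_true(all(diff(s$depth_cm) > 0))
  # conservation of counts: truth accounts for every emitted read
  for (sid in s$sample_id) {
    org <- core$read_origin[[sid]]
    expect_equal(nrow(org), length(core$reads[[sid]]))
    tc <- core$truth_counts[core$truth_counts$sample_id == sid, ]
    sp_genome <- table(org$source[org$source != "background"])
    for (k in seq_len(nrow(tc))) {
      gid <- names(panel$genome_taxid)[match(tc$taxid[k],
                                             panel$genome_taxid)]
      expect_equal(tc$true_reads[k],
                   if (gid %in% names(sp_genome))
                     as.integer(sp_genome[[gid]]) else 0L)
    }
  }
  expect_error(simulate_core(panel, 6, age_range = c(9000, 0)),
               "increasing")
})

test_that("a null covariate effect leaves occupancy uncorrelated", {
  panel <- simulate_panel(1, 1, 1000, n_genera_per_family = 1, seed = 4)
  rs <- vapply(1:20, function(i) {
    core <- simulate_core(panel, n_samples = 12, reads_per_taxon = 3,
                          background_reads = 0, seed = 100 + i)
    cnt <- core$truth_counts$true_reads
    suppressWarnings(cor(cnt, core$covariates$temperature,
                         method = "spearman"))
  }, numeric(1))
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.2)
})

test_that("simulation output files round-trip through standard formats", {
  panel <- simulate_panel(1, 2, 1000, n_genera_per_family = 1, seed = 6)
  core <- simulate_core(panel, n_samples = 3, reads_per_taxon = 5,
                        background_reads = 2, seed = 31)
  dir <- withr::local_tempdir()
  write_simulation(core, dir)
  expect_equal(read_fasta(file.path(dir, "panel.fasta")),
               panel$genomes)
  rt <- read_fastq(file.path(dir, "S01.fastq"))
  expect_equal(unname(rt), unname(core$reads[["S01"]]))
  expect_s3_class(read_taxonomy(file.path(dir, "taxonomy.tsv")),
                  "taxonomy_tree")
  expect_true(file.exists(file.path(dir, "proxy_temperature.tsv")))
})
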
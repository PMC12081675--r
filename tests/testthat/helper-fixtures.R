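# Shared fixtures, built in code at test time.

# Small mammal-like taxonomy with a prokaryote branch:
# root(1) -> Bacteria(10) -> BacSp(11)
#         -> Eukaryota(20) -> Phocidae(30) -> Pusa(31) -> P.hispida(32)
#                                          -> Phoca(33) -> P.groenlandica(34)
#                          -> Monodontidae(40) -> Monodon(41) -> M.monoceros(42)
toy_taxonomy <- function() {
  taxonomy_tree(data.frame(
    taxid        = c(1, 10, 11, 20, 30, 31, 32, 33, 34, 40, 41, 42),
    parent_taxid = c(1,  1, 10,  1, 20, 30, 31, 30, 33, 20, 40, 41),
    rank = c("root", "superkingdom", "species", "superkingdom",
             "family", "genus", "species", "genus", "species",
             "family", "genus", "species"),
    name = c("root", "Bacteria", "BacSp", "Eukaryota",
             "Phocidae", "Pusa", "Pusa hispida", "Phoca",
             "Phoca groenlandica", "Monodontidae", "Monodon",
             "Monodon monoceros"),
    stringsAsFactors = FALSE))
}

# idealized calibration curve mu(t) = slope * t with constant curve error
toy_curve <- function(max_cal = 12000, slope = 1, curve_sigma = 0,
                      by = 1) {
  grid <- seq(0, max_cal, by = by)
  cal_curve(grid, slope * grid, rep(curve_sigma, length(grid)))
}

random_genome <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# mutate a sequence at exactly per-site probability p (independent sites)
mutate_genome <- function(g, p) {
  v <- strsplit(g, "")[[1]]
  hit <- which(runif(length(v)) < p)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(v, collapse = "")
}

# binomial closed-form oracle for 50-mer identity bins at per-site
# divergence p: P(<=1 mismatch), P(=2), P(>=3)
binom_bins <- function(p, k = 50) {
  ge98 <- dbinom(0, k, p) + dbinom(1, k, p)
  mid <- dbinom(2, k, p)
  c(ge98 = ge98, mid = mid, lt95 = 1 - ge98 - mid)
}

# brute-force LCA oracle: intersect full root-to-leaf paths, take the
# deepest common node (independent of the pairwise-climb implementation)
lca_oracle <- function(tax, taxids) {
  paths <- lapply(taxids, function(t) tax_lineage(tax, t))
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# random taxonomy: n_nodes nodes, each node's parent drawn among earlier
# nodes, arbitrary ranks
random_taxonomy <- function(n_nodes) {
  parent <- c(1L, vapply(2:n_nodes, function(i) {
    sample.int(i - 1L, 1L)
  }, integer(1)))
  taxonomy_tree(data.frame(
    taxid = 1:n_nodes, parent_taxid = parent,
    rank = sample(c("species", "genus", "family", "order"),
                  n_nodes, replace = TRUE),
    name = paste0("n", 1:n_nodes), stringsAsFactors = FALSE))
}

# alignment records reconstructed from simulator provenance (exact truth,
# no aligner involvement) -- for damage-recovery checks
records_from_truth <- function(sim, ref_id, L) {
  t <- sim$truth
  data.frame(query_id = t$read_id, ref_id = ref_id,
             ref_start = t$start - 1L,
             ref_end = t$start - 1L + t$length,
             strand = t$strand, n_mismatch = 0L,
             aligned_len = t$length, identity = 1,
             stringsAsFactors = FALSE)
}
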
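#' Simulate a mitogenome reference panel with a known taxonomy
#'
#' Generates circular genomes by evolving a random root sequence down a
#' four-level hierarchy (order > family > genus > species), applying
#' independent per-site substitutions along each branch. Branch rates are
#' chosen so that the expected pairwise divergence between two genomes
#' equals the spec value for the rank of their most recent common ancestor:
#' two genomes splitting at rank r differ at a fraction ~`divergence[r]` of
#' sites. This stands in for a curated set of complete vertebrate
#' mitochondrial genomes with controlled intra- and inter-specific
#' divergence.
#'
#' @param n_families number of families under the single order-level root.
#' @param n_species_per_genus species per genus.
#' @param genome_length genome length in bp (>= 1000).
#' @param divergence named numeric: expected per-site divergence between two
#'   genomes whose most recent common ancestor has that rank; names
#'   `order`, `family`, `genus`, `species` (the `species` entry is the
#'   intra-species divergence between individuals of one species). Must be
#'   strictly decreasing from `order` down to `species`.
#' @param n_genera_per_family genera per family.
#' @param n_genomes_per_species individual genomes (leaves of the panel, not
#'   of the taxonomy) per species; pairs within one species realize the
#'   `species` divergence.
#' @param seed integer seed; all randomness in the panel flows from it.
#' @return an object of class `sim_panel`: list with `genomes` (named
#'   character vector of sequences), `taxonomy` (a [taxonomy_tree()]),
#'   `genome_taxid` (named integer mapping genome id to its species taxid)
#'   and `divergence`.
#' @export
#' @examples
#' p <- simulate_panel(2, 2, 2000, seed = 1)
#' length(p$genomes)
simulate_panel <- function(n_families, n_species_per_genus,
                           genome_length,
                           divergence = c(order = 0.16, family = 0.08,
                                          genus = 0.04, species = 0.01),
                           n_genera_per_family = 2,
                           n_genomes_per_species = 1,
                           seed = NULL) {
  stopifnot(genome_length >= 1000, n_families >= 1,
            n_species_per_genus >= 1, n_genera_per_family >= 1,
            n_genomes_per_species >= 1)
  req <- c("order", "family", "genus", "species")
  if (!all(req %in% names(divergence))) {
    stop("divergence must be named with ranks: ", paste(req, collapse = ", "))
  }
  d <- divergence[req]
  if (any(d < 0) || any(d > 1)) stop("divergence values must be in [0, 1]")
  if (any(d > 0) && any(diff(d) > 0)) {
    stop("divergence must decrease from order to species rank ",
         "(invalid divergence ordering)")
  }
  # Branch substitution rates: pairwise divergence between lineages that
  # split at rank r is twice the summed branch rates below r.
  b_fam <- (d[["order"]] - d[["family"]]) / 2
  b_gen <- (d[["family"]] - d[["genus"]]) / 2
  b_sp  <- (d[["genus"]] - d[["species"]]) / 2
  b_ind <- d[["species"]] / 2

  set_seed_if(seed)
  mutate_seq <- function(v, p) {
    if (p <= 0) return(v)
    hit <- which(stats::runif(length(v)) < p)
    if (length(hit)) {
      v[hit] <- vapply(v[hit], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    v
  }

  root <- sample(DNA_BASES, genome_length, replace = TRUE)
  nodes <- data.frame(taxid = 1L, parent_taxid = 1L,
                      rank = "order", name = "SimOrder",
                      stringsAsFactors = FALSE)
  next_id <- 2L
  genomes <- list()
  genome_taxid <- integer()
  for (f in seq_len(n_families)) {
    fam_id <- next_id; next_id <- next_id + 1L
    nodes <- rbind(nodes, data.frame(
      taxid = fam_id, parent_taxid = 1L, rank = "family",
      name = sprintf("Family%d", f)))
    fam_seq <- mutate_seq(root, b_fam)
    for (g in seq_len(n_genera_per_family)) {
      gen_id <- next_id; next_id <- next_id + 1L
      nodes <- rbind(nodes, data.frame(
        taxid = gen_id, parent_taxid = fam_id, rank = "genus",
        name = sprintf("Genus%d.%d", f, g)))
      gen_seq <- mutate_seq(fam_seq, b_gen)
      for (s in seq_len(n_species_per_genus)) {
        sp_id <- next_id; next_id <- next_id + 1L
        nodes <- rbind(nodes, data.frame(
          taxid = sp_id, parent_taxid = gen_id, rank = "species",
          name = sprintf("Species%d.%d.%d", f, g, s)))
        sp_seq <- mutate_seq(gen_seq, b_sp)
        for (i in seq_len(n_genomes_per_species)) {
          gid <- sprintf("F%dG%dS%d_%d", f, g, s, i)
          genomes[[gid]] <- paste(mutate_seq(sp_seq, b_ind), collapse = "")
          genome_taxid[gid] <- sp_id
        }
      }
    }
  }
  structure(list(
    genomes = unlist(genomes),
    taxonomy = taxonomy_tree(nodes),
    genome_taxid = genome_taxid,
    divergence = d
  ), class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("sim_panel:", length(x$genomes), "genomes of",
      nchar(x$genomes[[1]]), "bp;",
      sum(x$taxonomy$rank == "species"), "species\n")
  invisible(x)
}

#' Read-simulation settings
#'
#' Fragment lengths are drawn from a truncated normal (a stand-in for the
#' unreported empirical fragment-length law of degraded sedaDNA; the <=125
#' bp cap reflects the short-fragment regime of sediment cores). Terminal
#' deamination follows a geometric decay from each fragment end: C->T at 5'
#' position i with probability `d5 * (1 - decay)^(i - 1)`, and G->A at 3'
#' position j (counted from the 3' end) analogously — the double-stranded
#' library damage pattern. An optional single-stranded mode applies C->T at
#' both ends instead.
#'
#' @param n_reads number of fragments.
#' @param length_mean,length_sd,length_min,length_max fragment-length law
#'   (bp); lengths are truncated to `[length_min, length_max]`.
#' @param d5,d3 terminal deamination probability at position 1 of the 5'
#'   (C->T) and 3' (G->A) ends.
#' @param decay per-position geometric decay rate of the deamination
#'   probability, between 0 and 1.
#' @param seq_error independent per-base sequencing error probability,
#'   applied after damage.
#' @param single_stranded if TRUE, C->T is applied at both ends (single-
#'   stranded library profile) instead of C->T 5' / G->A 3'.
#' @param seed integer seed.
#' @return validated list of class `read_sim_spec`.
#' @export
read_sim_spec <- function(n_reads, length_mean = 70, length_sd = 15,
                          length_min = 30, length_max = 125,
                          d5 = 0, d3 = 0, decay = 0.3, seq_error = 0,
                          single_stranded = FALSE, seed = NULL) {
  stopifnot(n_reads >= 1, length_min >= 1, length_max >= length_min)
  for (p in c(d5 = d5, d3 = d3, decay = decay, seq_error = seq_error)) {
    if (p < 0 || p > 1) stop("damage/error probabilities must be in [0, 1]")
  }
  structure(list(n_reads = as.integer(n_reads), length_mean = length_mean,
                 length_sd = length_sd, length_min = as.integer(length_min),
                 length_max = as.integer(length_max), d5 = d5, d3 = d3,
                 decay = decay, seq_error = seq_error,
                 single_stranded = isTRUE(single_stranded), seed = seed),
            class = "read_sim_spec")
}

#' Simulate damaged ancient reads from a circular genome
#'
#' Fragment start positions are uniform on the circle and strands uniform.
#' Damage is applied in the original-molecule orientation (the merged read
#' as sequenced, 5' to 3'), then independent sequencing errors. Full
#' provenance (true source position, strand, substitution counts) is
#' returned so downstream recovery can be checked against truth.
#'
#' @param genome a single nucleotide sequence (character).
#' @param spec a [read_sim_spec()].
#' @param read_prefix prefix for read identifiers.
#' @return class `sim_reads`: list with `reads` (named character vector, the
#'   sequenced molecules) and `truth` (data.frame: `read_id`, `start`
#'   1-based position of the molecule's first genome base on the forward
#'   strand layout, `strand`, `length`, `n_deam5`, `n_deam3`, `n_error`).
#' @export
simulate_reads <- function(genome, spec, read_prefix = "read") {
  stopifnot(inherits(spec, "read_sim_spec"))
  L <- nchar(genome)
  if (spec$length_max > L) stop("length_max exceeds genome length")
  set_seed_if(spec$seed)
  g <- seq_split(genome)
  n <- spec$n_reads
  lens <- as.integer(round(stats::rnorm(n, spec$length_mean, spec$length_sd)))
  lens <- pmin(pmax(lens, spec$length_min), spec$length_max)
  starts <- sample.int(L, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  reads <- character(n)
  nd5 <- nd3 <- nerr <- integer(n)
  for (i in seq_len(n)) {
    len <- lens[i]
    idx <- ((starts[i] - 1L + 0:(len - 1L)) %% L) + 1L
    frag <- g[idx]
    if (strands[i] == "-") frag <- revcomp_vec(frag)
    # 5' C->T with geometric positional decay
    p5 <- spec$d5 * (1 - spec$decay)^(0:(len - 1L))
    hit5 <- frag == "C" & stats::runif(len) < p5
    frag[hit5] <- "T"
    # 3' end: G->A by default; C->T in single-stranded mode
    p3 <- rev(spec$d3 * (1 - spec$decay)^(0:(len - 1L)))
    if (spec$single_stranded) {
      hit3 <- frag == "C" & stats::runif(len) < p3
      frag[hit3] <- "T"
    } else {
      hit3 <- frag == "G" & stats::runif(len) < p3
      frag[hit3] <- "A"
    }
    err <- which(stats::runif(len) < spec$seq_error)
    if (length(err)) {
      frag[err] <- vapply(frag[err], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    reads[i] <- paste(frag, collapse = "")
    nd5[i] <- sum(hit5); nd3[i] <- sum(hit3); nerr[i] <- length(err)
  }
  ids <- sprintf("%s_%05d", read_prefix, seq_len(n))
  structure(list(
    reads = stats::setNames(reads, ids),
    truth = data.frame(read_id = ids, start = starts, strand = strands,
                       length = lens, n_deam5 = nd5, n_deam3 = nd3,
                       n_error = nerr, stringsAsFactors = FALSE)
  ), class = "sim_reads")
}

#' Simulate a dated sediment-core sample series with proxy records
#'
#' Emulates a downcore sedaDNA sampling campaign: samples at increasing
#' depth and age, per-sample taxon occupancy drawn from a logistic model on
#' standardized environmental covariates (temperature and sea-ice proxies on
#' irregular age grids), read counts for occupied taxa, terminal damage
#' increasing linearly with age, and a uniform-random background read
#' fraction. Ground truth (occupancy, counts, damage parameters) is
#' returned for parameter-recovery tests.
#'
#' @param panel a [simulate_panel()] result.
#' @param n_samples number of samples (>= 3).
#' @param age_range `c(youngest, oldest)` in cal yr BP; must be increasing.
#' @param covariate_effects data.frame with columns `species` (species name
#'   in the panel taxonomy), `temperature`, `sea_ice`: log-odds of occupancy
#'   per SD of the standardized covariate. Species not listed get effect 0.
#' @param occupancy_intercept baseline log-odds of occupancy per sample.
#' @param reads_per_taxon mean reads for an occupied taxon (Poisson,
#'   shifted by +1 so occupied taxa emit at least one read).
#' @param background_reads mean number of uniform-random background reads
#'   per sample (Poisson).
#' @param d5_range terminal C->T probability at the youngest and oldest
#'   sample age; interpolated linearly in age (damage grows with age).
#' @param decay geometric decay of the damage profile.
#' @param seq_error per-base sequencing error rate.
#' @param depth_range sample depths in cm, equally spaced over this range.
#' @param n_proxy_points knots per proxy series (irregular age grid).
#' @param seed integer seed.
#' @return class `sim_core`: list with `samples` (sample table: sample_id,
#'   depth_cm, age_median, age_lo, age_hi), `reads` (per-sample named list
#'   of read vectors), `read_origin` (per-sample data.frame mapping read_id
#'   to source genome or "background"), `truth_counts` (sample x species
#'   true read counts, long), `truth_damage` (per-sample d5/d3/decay),
#'   `proxies` (named list of data.frames age_calBP/value), `covariates`
#'   (standardized covariate values at sample ages) and `panel`.
#' @export
simulate_core <- function(panel, n_samples = 20,
                          age_range = c(0, 11000),
                          covariate_effects = NULL,
                          occupancy_intercept = 0,
                          reads_per_taxon = 120,
                          background_reads = 30,
                          d5_range = c(0.02, 0.3),
                          decay = 0.3,
                          seq_error = 0.001,
                          depth_range = c(0, 300),
                          n_proxy_points = 40,
                          seed = NULL) {
  stopifnot(inherits(panel, "sim_panel"), n_samples >= 3)
  if (age_range[1] >= age_range[2]) {
    stop("age_range must be increasing: c(youngest, oldest)")
  }
  set_seed_if(seed)
  depths <- seq(depth_range[1], depth_range[2], length.out = n_samples)
  ages <- seq(age_range[1], age_range[2], length.out = n_samples)
  age_half <- pmax(50, 0.05 * ages)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    depth_cm = depths, age_median = ages,
    age_lo = ages - age_half, age_hi = ages + age_half,
    stringsAsFactors = FALSE)

  smooth_series <- function(n) {
    knots <- sort(stats::runif(n, age_range[1] - 500, age_range[2] + 500))
    knots <- knots[c(TRUE, diff(knots) > 1e-6)]
    v <- as.numeric(stats::filter(stats::rnorm(length(knots)),
                                  rep(1 / 3, 3), sides = 2))
    v[is.na(v)] <- stats::rnorm(sum(is.na(v)))
    data.frame(age_calBP = knots, value = v)
  }
  proxies <- list(temperature = smooth_series(n_proxy_points),
                  sea_ice = smooth_series(n_proxy_points))

  cov_at <- function(series) {
    standardize(stats::approx(series$age_calBP, series$value,
                              xout = ages, rule = 2)$y)
  }
  Z <- data.frame(temperature = cov_at(proxies$temperature),
                  sea_ice = cov_at(proxies$sea_ice))

  species <- panel$taxonomy[panel$taxonomy$rank == "species", ]
  beta <- matrix(0, nrow(species), 2,
                 dimnames = list(species$name, c("temperature", "sea_ice")))
  if (!is.null(covariate_effects)) {
    stopifnot(all(c("species") %in% names(covariate_effects)))
    for (k in seq_len(nrow(covariate_effects))) {
      sp <- covariate_effects$species[k]
      if (!sp %in% rownames(beta)) stop("unknown species in effects: ", sp)
      for (cv in c("temperature", "sea_ice")) {
        if (cv %in% names(covariate_effects)) {
          beta[sp, cv] <- covariate_effects[[cv]][k]
        }
      }
    }
  }
  # one representative genome per species
  sp_genome <- vapply(species$taxid, function(t) {
    names(panel$genome_taxid)[match(t, panel$genome_taxid)]
  }, character(1))
  names(sp_genome) <- species$name

  age_frac <- (ages - age_range[1]) / diff(age_range)
  d5s <- d5_range[1] + (d5_range[2] - d5_range[1]) * age_frac

  reads <- list(); origin <- list(); truth <- list()
  for (i in seq_len(n_samples)) {
    sid <- samples$sample_id[i]
    eta <- occupancy_intercept +
      beta[, "temperature"] * Z$temperature[i] +
      beta[, "sea_ice"] * Z$sea_ice[i]
    occupied <- stats::runif(nrow(species)) < stats::plogis(eta)
    srec <- character(0); orec <- character(0)
    cnt <- integer(nrow(species))
    for (s in which(occupied)) {
      nr <- 1L + stats::rpois(1, reads_per_taxon - 1)
      spec <- read_sim_spec(nr, d5 = d5s[i], d3 = d5s[i], decay = decay,
                            seq_error = seq_error,
                            seed = derive_seed(seed, i * 1000L + s))
      sim <- simulate_reads(panel$genomes[[sp_genome[species$name[s]]]],
                            spec,
                            read_prefix = sprintf("%s_%s", sid,
                                                  sp_genome[species$name[s]]))
      srec <- c(srec, sim$reads)
      orec <- c(orec, rep(sp_genome[species$name[s]], nr))
      cnt[s] <- nr
    }
    nbg <- stats::rpois(1, background_reads)
    if (nbg > 0) {
      bg_len <- pmin(pmax(as.integer(round(stats::rnorm(nbg, 70, 15))),
                          30L), 125L)
      bg <- vapply(bg_len, function(l) {
        paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
      }, character(1))
      names(bg) <- sprintf("%s_bg_%04d", sid, seq_len(nbg))
      srec <- c(srec, bg)
      orec <- c(orec, rep("background", nbg))
    }
    reads[[sid]] <- srec
    origin[[sid]] <- data.frame(read_id = names(srec), source = orec,
                                stringsAsFactors = FALSE)
    truth[[sid]] <- data.frame(sample_id = sid, species = species$name,
                               taxid = species$taxid, true_reads = cnt,
                               occupied = occupied, stringsAsFactors = FALSE)
  }
  structure(list(
    samples = samples,
    reads = reads,
    read_origin = origin,
    truth_counts = do.call(rbind, c(truth, list(make.row.names = FALSE))),
    truth_damage = data.frame(sample_id = samples$sample_id,
                              d5 = d5s, d3 = d5s, decay = decay),
    proxies = proxies,
    covariates = Z,
    effects = beta,
    panel = panel
  ), class = "sim_core")
}

#' @export
print.sim_core <- function(x, ...) {
  cat("sim_core:", nrow(x$samples), "samples,",
      sum(lengths(x$reads)), "reads,",
      length(x$proxies), "proxy series\n")
  invisible(x)
}

#' Write a simulated core to the pipeline's standard on-disk formats
#'
#' Writes the reference panel (FASTA), per-sample reads (FASTQ, dummy "I"
#' qualities), taxonomy TSV, per-proxy TSVs (`age_calBP`, `value`), the
#' sample table TSV and the truth TSV.
#'
#' @param core a [simulate_core()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(core, outdir) {
  stopifnot(inherits(core, "sim_core"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(core$panel$genomes, file.path(outdir, "panel.fasta"))
  write_taxonomy(core$panel$taxonomy, file.path(outdir, "taxonomy.tsv"))
  for (sid in names(core$reads)) {
    write_fastq(core$reads[[sid]],
                file.path(outdir, paste0(sid, ".fastq")))
  }
  for (p in names(core$proxies)) {
    utils::write.table(core$proxies[[p]],
                       file.path(outdir, paste0("proxy_", p, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(core$samples, file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(core$truth_counts, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
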
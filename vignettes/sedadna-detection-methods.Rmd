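---
title: "Detecting marine mammals in sediment cores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting marine mammals in sediment cores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedadetect)
```

# The problem

Sedimentary ancient DNA (sedaDNA) preserved in dated marine sediment cores
records which organisms lived in the overlying water column through time,
including large vertebrates that are nearly invisible in the fossil record.
Turning raw sediment sequencing reads into credible, dated species
detections requires a chain of decisions — how the capture baits were
designed, at what sequence identity a read may be assigned to a species,
which reads are discarded, how detections are authenticated as ancient
rather than modern contamination, and how sample ages and environmental
covariates are attached. `sedadetect` implements that chain as a set of
composable, separately testable modules, plus a synthetic-data generator
that provides ground truth for every stage.

This vignette documents the models, the defaults and their rationale, the
numerical conventions, and what the synthetic tests do and do not
demonstrate about real data.

# Synthetic data: what it emulates

`simulate_panel()` builds a circular mitogenome panel over a four-rank
taxonomy (order > family > genus > species). Branch substitution rates are
derived from a per-rank divergence specification: two genomes whose most
recent common ancestor sits at rank $r$ differ at an expected fraction
$d_r$ of sites. The defaults ($d_\mathrm{order}=0.16$,
$d_\mathrm{family}=0.08$, $d_\mathrm{genus}=0.04$,
$d_\mathrm{species}=0.01$) bracket the structure typical of mammal
mitogenomes: sub-percent to ~1% intraspecific divergence, a few percent
between congeners, more between families. Substitutions are independent
per site; double hits cause a small (<0.3% absolute) shortfall between
specified and realized divergence, well inside the binomial sampling band
the tests assert.

`simulate_reads()` draws fragments uniformly on the circle with uniform
strand. Fragment lengths follow a truncated normal (mean 70 bp, sd 15,
truncated to 30–125 bp). The 125 bp cap reflects the short-fragment regime
of degraded sedaDNA; the shape of the length law within that range is a
placeholder — the empirical law of real cores is not modeled, only its
support. Terminal deamination follows the canonical ancient-DNA pattern:
C→T at 5′ position $i$ with probability $d_5(1-\lambda)^{i-1}$ and G→A at
3′ position $j$ analogously, with geometric decay $\lambda$ (default 0.3).
This is the double-stranded-library profile; a `single_stranded` flag
applies C→T at both ends instead. Both library chemistries occur in
practice; the default matches the profile that double-stranded protocols
visualize. Independent per-base sequencing errors are applied after
damage.

`simulate_core()` assembles a dated sample series: equally spaced depths,
ages increasing linearly across the requested range, per-sample taxon
occupancy drawn from a logistic model on standardized temperature and
sea-ice covariates (log-odds per SD), read counts for occupied taxa,
terminal damage increasing linearly with age (default 0.02 at the
youngest to 0.30 at the oldest sample — sub-percent damage for recent
material up to the strong damage expected for early-Holocene ages), and a
uniform-random background read fraction standing in for the non-target
community. Proxy series live on irregular age grids, as real published
records do.

What the generator does *not* emulate: realistic gene architecture,
coalescent within-species variation, compositional biases, mapping biases
from conserved regions shared beyond the panel, taphonomic loss, or a
realistic prokaryote-dominated background. Passing the end-to-end tests
therefore demonstrates that the *computational chain* is correct and
internally consistent under controlled conditions — not that any
particular real-world detection is right.

All randomness flows from explicit seeds; multi-stage operations derive
per-stage sub-seeds deterministically, so every simulated dataset is
exactly reproducible.

# Bait design

Capture panels tile 80-nt baits every 20 nt (4× coverage) around each
circular mitogenome. To handle circularity, the first 80 nt are appended
to the end before tiling; bait starts run from 0 in steps of 20 strictly
below the original length. Every non-ACGT character is replaced by
thymine — any ambiguity code breaks synthesis, so masking applies to
single characters as well as runs. Deduplication is exact,
forward-strand-only string identity (synthesis is strand-specific), first
occurrence retained; both the pre- and post-dedup counts are reported
because published panel sizes do not always state which side of
cross-genome dedup they count. When a genome length is not divisible by
the step, the final starts simply stop below the length and terminal
coverage is uneven; this is accepted and visible in the per-genome
summary.

# Identity-threshold calibration

The LCA threshold determines taxonomic resolution: too low and reads that
could be species-diagnostic are pushed to genus or family; too high and
sequencing errors or damage create spurious species splits. The
calibration fragments an aligned genome pair into all gap-free 50-column
windows (sliding mode; deterministic) or a random sample of them, scores
per-fragment identity, and summarizes into three half-open bins chosen to
be exhaustive on integer mismatch counts at $k=50$: identity ≥ 0.98 (≤ 1
mismatch), [0.95, 0.98) (exactly 2), < 0.95 (≥ 3). Sliding mode is the
default because it removes sampling noise from the reproduction; random
mode exists for very long alignments.

`recommend_threshold()` scans the candidate grid {5%, 2%, 1%, 0%} and
returns the *most stringent* divergence threshold whose within-species
fragment retention meets the target (default 95%), reporting
between-species leakage alongside. Stringency is preferred because every
extra percent of allowed divergence admits a rapidly growing share of
cross-species fragments (the binomial tail), while within-species
retention saturates. For mammal mitogenome panels with sub-percent
intraspecific divergence this lands on 2% (98% identity), the conventional
choice for this taxonomic regime. If no candidate meets the target, the
best achievable is returned and flagged rather than silently accepted.

# Read QC

Filters run in a fixed order — length (< 30 bp), exact duplicates,
homopolymers, DUST-style low complexity — so each read is removed for
exactly one reason and report counts are additive. The 30 bp boundary is
inclusive (a 30 bp read is kept). "Homopolymer" is strict (one distinct
base over the whole read); near-homopolymers are left to the complexity
score, defined as $\sum_t c_t(c_t-1)/2$ over 3-mer counts normalized by
(number of triplets − 1), threshold 2.0. The external tools this step
mirrors do not publish their exact score, so the score is configurable
and documented rather than hidden. The kept-read count is the denominator
of relative sequence abundance downstream, and the filter is idempotent.

# Alignment and LCA assignment

The built-in aligner is a minimal exact-k-mer (default $k=16$)
seed-and-extend ungapped aligner over both strands, reporting *every*
reference hit with identity ≥ 0.80 — deliberately not best-hit-only,
because the LCA needs the full hit set. Coordinates are 0-based half-open
internally; SAM input (1-based, reference-oriented) is converted at the
boundary, requires `NM` tags, and minus-strand sequences are flipped back
to molecule orientation on ingest. Identity counts indels as mismatches
over alignment columns, one definition shared by the built-in aligner and
SAM ingest. Reads crossing the circular origin align into an extended
reference copy and keep `ref_end − ref_start = aligned_len`, interpreted
modulo the reference length.

Assignment discards hits below the mode's identity threshold (0.95
shotgun, 0.98 capture) and takes the lowest common ancestor of the
survivors. Raising the threshold can only remove hits, so assignments
move toward the leaves or to unassigned — a monotonicity the tests check
against a brute-force path-intersection oracle. Positional duplicate
removal collapses records sharing (reference, start, end) —
strand-insensitively, since an amplification duplicate can be sequenced
in either orientation — keeping the first read in input order; it is
applied to each read's best representative alignment before unique
sequences are counted.

Detection filters: capture mode keeps species-rank detections with ≥ 3
unique sequences; shotgun mode aggregates to family rank, excludes
prokaryotes, and keeps families with ≥ 10 unique sequences (both
boundaries inclusive). A separate report filter can flag taxa seen in
fewer than 2 samples; such taxa remain in the full table with
`in_report = FALSE` because the rule is presentational, not evidential.

# Damage authentication

Deamination rates condition on the reference base: rate at 5′ position
$i$ = (#C→T at $i$) / (#reference C at $i$), analogously G→A from the 3′
end, after restoring molecule orientation for minus-strand alignments.
Cells with fewer than 100 observations are masked by default — damage
signals are only interpretable with adequate counts, and sparse cells
otherwise dominate summaries. The headline statistic is the mean over the
last three positions of both ends (six cells). Terminal positions 1–3
from each end are used; with a 25-position window per end the "last
three bases" could in principle be read as window positions 23–25, but
the terminal reading is the one that tracks the damage gradient.

Samples are pooled into 3000-year bins anchored at 0 cal yr BP with
half-open intervals (a sample at exactly 3000 falls in the older bin);
anchoring is a convention the data cannot determine. Pooling sums
substitution counts before recomputing rates, so the pooled rate is
exactly the count-weighted mean of member rates — an identity the tests
assert. Fragment-length histograms and circular per-position coverage
complete the authentication triplet.

# Chronology

Calibration subtracts the reservoir offset ΔR before the curve lookup and
adds its uncertainty in quadrature, then evaluates the usual Gaussian
overlap density on the curve grid (linear interpolation between knots,
trapezoidal weights for irregular grids), normalizes, and summarizes by
the cumulative-mass median and the central 95% quantile interval.
Central quantiles rather than HPD: the published "±" form is consistent
with either, and quantiles are deterministic and monotone under grid
refinement (median error below one grid step). Reports round the median
and interval half-width to 0.1 cal ka. BP is anchored at 1950 CE, so a
core retrieved in 2021 CE has a surface age of −71 BP (`ce_to_bp()`).

The age-depth model is a deliberate simplification of full Bayesian
accumulation modeling: each Monte-Carlo draw samples one calendar age per
control point from its calibrated density, rejects non-monotone draws
(age must not decrease with depth), and interpolates linearly between
control depths; per-depth quantiles over accepted draws give the median
and 68%/95% envelopes. Exact constraints (sd = 0) pin their depths in
every draw. If fewer than 1% of draws are monotone the model stops with
an error pointing at outlier review, rather than reporting quantiles from
a conflicted posterior. This sampler has no accumulation-rate prior and
no memory structure, so its envelopes between control points are narrower
than a full accumulation model would give; it is intended for pipeline
integration and testing, not as a replacement for dedicated age-model
software.

# Proxy integration

Proxies are linearly interpolated to sample median ages — exact at knots,
never extrapolated (samples outside a proxy's support go missing for that
proxy) — then z-standardized (sample sd, $n-1$). Constant series are an
error naming the offending proxy.

The Spearman matrix uses average ranks for ties and two-sided p-values
from the t-approximation with $n-2$ df, on pairwise-complete
observations; pairs with fewer than 5 complete observations are flagged
and given no p-value. Correlations are computed on abundances by
default; presence/absence is a caller-side transform of the detection
matrix.

The redundancy analysis regresses the centered response matrix on the
standardized explanatory matrix; constrained variance is the total
variance of the fitted values and its eigenvalues are the constrained
axes. Each term is tested *marginally* (given all others) — matching how
per-proxy F statistics are conventionally reported — with a
Freedman–Lane permutation scheme: residuals of the reduced model are
row-permuted, added back to the reduced-model fit, and the statistic
recomputed; $p = (1 + \#\{F^* \ge F\})/(n_\mathrm{perm}+1)$, so $p$ is
never below $1/(n_\mathrm{perm}+1)$ and is exactly reproducible under a
seed. Marginal sums of squares do not partition total variance when
explanatory terms are correlated, so per-term fractions are reported
separately from the constrained/residual split, which does sum to one.
A rank-deficient explanatory matrix is an error listing the collinear
terms. The test suite checks the eigenvalues against a direct
eigendecomposition oracle and against an independent RDA implementation,
and calibrates the permutation test's type-I error at $\alpha = 0.05$
over 500 null simulations.

# Worked example

```{r example, eval = FALSE}
panel <- simulate_panel(n_families = 2, n_species_per_genus = 2,
                        genome_length = 16500, seed = 1)
baits <- design_baits(panel$genomes)
baits

core <- simulate_core(panel, n_samples = 12, seed = 2)
qc <- filter_reads(core$reads$S01)
asg <- assign_sample(qc$reads, panel$genomes, panel$taxonomy,
                     panel$genome_taxid, min_identity = 0.98,
                     n_qc_reads = qc$report$n_kept)
asg$profile
```

# Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen so
that every stochastic assertion has adequate Monte-Carlo resolution:
10,000 random 50-mer fragments for the identity bins, 1000 random
taxonomies for the LCA oracle, 20,000 reads for damage-rate recovery, 100
replicates for the old-vs-young damage contrast, 500 null simulations
(n = 30, 199 permutations) for the RDA type-I calibration, and a
16-sample core of a 16-genome panel for the end-to-end run. These sizes
are the package's own choices for statistical resolution; all are seeded
and reproducible.

# Known limitations

* The aligner is ungapped; indel-containing reads lose identity linearly
  and gapped records are skipped in damage profiling. Gapped alignment
  belongs to external aligners, whose SAM output the package ingests.
* The age-depth model understates between-control uncertainty relative
  to accumulation-prior models (see above).
* The synthetic background is uniform random sequence; real non-target
  communities can produce near-threshold hits that the specificity tests
  here cannot probe.
* Real calibration curves and real mitogenome sets are external inputs;
  the package reads them but does not ship them, and idealized synthetic
  curves used in tests are labelled as such.
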
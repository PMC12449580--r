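---
title: "Methods: models, thresholds and design choices in phyconet"
author: "phyconet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in phyconet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

phyconet analyses host-associated biofilm microbiomes from amplicon (ASV)
count tables. The pipeline covers five analytical layers — core-microbiome
and host-specific taxon extraction, compositional community statistics,
sparse association network inference, network metric profiling with
topological role classification, and between-network comparison — plus a
synthetic-data generator with known ground truth and a deterministic
end-to-end driver. This vignette records the models, the tunable
parameters and their defaults, the numerical conventions, and the design
choices that were genuinely open, so that a maintainer can see *why* the
code is the way it is. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

# Data model

The central container, `BiofilmExperiment`, extends
`SummarizedExperiment`: a `counts` assay (features × samples), sample
metadata in `colData` (host treatment, substrate, timepoint, and the
panel/bottle block structure of the mesocosm layout), feature taxonomy in
`rowData` (domain class — prokaryote or microalga — lineage string, 16S
gene copy number). Validity demands unique IDs, finite non-negative
counts and a positive total per sample. Counts are integers when read
from files; after gene-copy-number correction the assay becomes
real-valued and flows through downstream operations unchanged — values
are only re-discretised where an operation is defined on reads (the
core detection filter counts reads, not corrected abundances).

Sample groups are labelled `treatment|substrate` and pool the two
timepoints by default. Per-timepoint grouping is available through the
`group_by` argument of the extraction functions; pooling is the default
because persistence across the short temporal scale is part of what a
compositional core is meant to capture.

# Input handling

Tables are read from a features-as-rows TSV dialect (`#ASV_ID` first
header cell) or BIOM v1 JSON (via the Bioconductor **biomformat**
package). Samples whose total is zero are dropped with a warning at read
time. The depth filter keeps samples with total ≥ threshold — the
boundary is inclusive because the filter is phrased as *removing* samples
with *fewer* reads than the threshold (defaults: 2000 reads for
prokaryote tables, 100 for microalgae). 16S gene-copy-number correction
divides each feature by its copy number; features missing from the
reference get copy number 1 and are reported, since no copy-number
database covers all taxa. The sample depth filter is applied before
copy-number correction by default (the order is configurable; corrected
abundances are no longer reads, so filtering on them would conflate the
two scales).

# Core microbiome and host specificity

A feature belongs to a group's compositional core when it is detected
with **more than** `min_reads = 3` reads (strict boundary — "more than 3
reads" is the definition of detection) in **at least** `min_prevalence =
90%` of the group's samples (inclusive boundary — "at least 90%"), and
its group-mean relative abundance is at least `min_abundance_fraction =
1e-5` (0.001%). The abundance floor is deliberately tiny: rare but
persistent taxa are exactly what a prevalence-based core is supposed to
keep. The abundance rule is evaluated on the group-*mean* relative
abundance rather than per sample, because the threshold describes
community-level rarity; both the threshold and the detection rule are
exposed as arguments.

A feature is host-specific when it has a count above `detection = 0` in
*every* sample of the host's biofilm and proxy-biofilm groups at both
timepoints, and at most `detection` in *every* control-filter and
seawater sample. Presence/absence with any read is the default because
host specificity is phrased as presence, not as an abundance property;
the threshold is configurable.

# Community statistics

Shannon diversity uses the natural logarithm (the convention of the
vegan ecosystem this package sits in). Bray–Curtis distances are
computed with `vegan::vegdist`, by default on relative abundances so
that sequencing depth cancels; raw-count mode is retained because the
distance is depth-dependent by definition and some workflows want that.

PERMANOVA is implemented directly from its sums-of-squares definition
(`SS_total = Σ_{i<j} d²/N`, within-group terms weighted by 1/n_g), with
the pseudo-F and `R² = SS_between/SS_total`. Significance uses label
permutations with the observed statistic included in both numerator and
denominator — `p = (1+b)/(1+m)` — so p is never zero. When the number of
distinct label assignments is no larger than the requested permutation
count (and no strata are given), the implementation switches to complete
enumeration of the label multiset and reports the exact p over all
assignments. This makes small-sample p-values reproducible quantities
rather than Monte-Carlo estimates, and is what the test suite checks
against an independently coded enumeration. Blocked permutation
(`strata`, e.g. panel) is supported but off by default — the block
factors enter the study's mixed models, which are out of scope here, not
its PERMANOVAs.

Beta-dispersion follows the centroid variant: PCoA of the distance
matrix, per-sample distance to the group centroid with the
imaginary-axis correction `z² = d²_pos − d²_neg` truncated at zero
(Bray–Curtis is semi-metric, so negative eigenvalues occur), then a
classical one-way F on the `z` values with label-permutation (or exact)
significance. Centroids rather than spatial medians because the centroid
form has a closed geometry in PCoA space and the choice is not otherwise
forced; `vegan::betadisper(type = "centroid")` is the cross-check in the
tests. PCoA itself is implemented by Gower double-centering and
eigen-decomposition, returning negative-eigenvalue axes explicitly —
`stats::cmdscale` discards them, and beta-dispersion needs them.

Pairwise PERMANOVA subsets the distance matrix per group pair and
adjusts p-values with Benjamini–Hochberg by default (no correction is
named in the workflows this mirrors; BH is the field's default;
Bonferroni is available).

# Association networks

Inference follows the neighborhood-selection flavour of compositionally
robust graphical modelling:

1. **Feature filter.** Whole-community (WMC) networks keep features with
   ≥ 3 total reads and mean relative abundance ≥ 0.25% (the abundance
   floor at which the host networks stabilise); a per-sample-maximum
   reading of the abundance rule is available since the phrasing is
   ambiguous. Core-level networks use the core membership instead.
2. **CLR transform** with unit pseudocount on counts (the standard
   convention for integer tables; real-valued tables without zeros may
   use pseudocount 0). Rows (samples) sum to zero by construction.
3. **Neighborhood lasso.** Each feature is regressed on all others with
   an L1 penalty (glmnet; columns standardised with the population-sd
   convention, no intercept, convergence threshold 1e-10). `lambda_max`
   is the largest absolute cross-product between distinct standardised
   columns divided by n — the smallest penalty with an empty graph. The
   default path is 30 log-spaced penalties down to `0.01·lambda_max`.
4. **StARS.** Graphs are re-estimated on 20 subsamples (without
   replacement) of size `min(⌊10√n⌋, ⌊0.8n⌋)` — the standard
   recommendation adapted to the small group sizes this design produces
   (n ≈ 12 gives subsamples of 9). Edge instability is `2θ(1−θ)` with θ
   the cross-subsample selection frequency; total instability D(λ) is
   the mean over all feature pairs, monotonised from the sparsest end;
   the densest penalty with monotonised D ≤ 0.05 is selected. If no
   penalty qualifies, the sparsest is returned with a warning.
5. **Symmetrization.** OR rule by default (an edge exists if either
   regression selects it), AND by flag. The weight is the mean of the
   two coefficients; when the two are non-zero with opposite signs the
   larger-magnitude coefficient wins and the conflict is counted in the
   network's provenance — averaging sign-conflicting coefficients would
   manufacture a near-zero weight with an arbitrary sign.

Networks are inferred separately per sample group on the merged
prokaryote + microalga table, so cross-domain associations are first-class
edges. Whether control samples join a group's network is left to the
caller (group composition is fully configurable) — the source workflows
are ambiguous on this point.

# Network metrics and roles

All topological metrics are computed on the **unweighted** graph; weights
enter only the mean absolute weight and the sign fields. Transitivity is
global (3·triangles / connected triples), with the average-local variant
by flag. Natural connectivity is `ln(mean(exp(λ_i)))` over adjacency
eigenvalues, evaluated with log-sum-exp stabilisation; it is zero for an
edgeless graph and strictly increases with every added edge.

Module detection maximises Newman–Girvan modularity with a
multi-restart greedy scheme: Louvain on randomly permuted vertex orders,
plus deterministic fast-greedy and leading-eigenvector candidates, best
partition kept; the whole procedure is deterministic under its seed. On
graphs of up to 8 nodes the result is checked in the test suite against
a brute-force maximum over all set partitions. An edgeless graph is a
single module with Q = 0 by convention.

Topological roles use the within-module degree z-score `Zi` (0 when the
module's degree spread is zero) and the participation coefficient
`Pi = 1 − Σ_m (k_im/k_i)²` (0 for isolated nodes), with the canonical
thresholds `Zi ≥ 2.5` and `Pi ≥ 0.62` classifying network hubs (both),
module hubs (Zi only), connectors (Pi only) and peripherals; both
thresholds are parameters.

# Comparing networks

Network profiles are fixed-order vectors (node and edge counts, density,
mean degree, mean betweenness, transitivity, modularity, natural
connectivity, fraction of negative edges, mean absolute weight). Profiles
are z-scored per metric across networks before Euclidean distance —
without standardisation the node/edge counts would dominate every other
metric; raw mode is retained for sensitivity analysis, and zero-variance
metrics are dropped with a warning. PCA operates on the same
standardised matrix, so full-rank PCA score distances equal the profile
distances exactly (asserted to 1e-9 in the tests). Both the distance
matrix and the standardised metric table are written by the pipeline, as
either may be the quantity a heatmap reader wants. Shared structure
between two networks counts common nodes and common unordered edges *with
matching sign* — an association that flips sign across networks is not
the same association.

# The synthetic-data generator

The generator is the package's ground-truth instrument, a first-class
module. It emulates the mesocosm design the package targets: three
seaweed hosts × two substrates (host biofilm, proxy-biofilm membrane),
control filters and ambient seawater, two timepoints, six replicates per
group (seawater half that), with stable panel/bottle block labels.

The generative model is logistic-normal-multinomial, matching the
latent-Gaussian compositional assumption of the inference stage without
sharing any code with it:

* `makeGraph` plants a sparse conditional-dependence graph (band,
  cluster, scale-free or hub topology) with partial correlations drawn
  uniformly from ±[0.15, 0.35] — strong enough to be recoverable around
  n ≈ 100, weak enough that recovery is not trivial. The precision
  matrix has unit diagonal and `−value` off-diagonals, so each planted
  partial correlation is realised exactly; if a row would break strict
  diagonal dominance (dense topologies) all off-diagonals are shrunk
  uniformly just enough to restore it. The covariance is the
  corresponding correlation matrix.
* Latent log-abundances are multivariate normal. Treatment effects add
  `effect_size` (default 1, on the log scale) to a random 20% of
  features per treatment. Planted core and host-specific features take a
  fixed elevated group mean (`core_boost = 2.5` log units) inside their
  groups rather than baseline-plus-boost: "planted as core" must
  guarantee detectability, and letting the N(0,1) baseline lottery reach
  into the planted sets would make the ground truth self-contradictory.
  Outside their groups, host-specific features are structurally absent.
* The latent vector is exponentiated and closed to a composition;
  structural zeros are applied to the composition **before** the
  multinomial draw. This departs from zeroing counts after the draw: it
  guarantees absence *and* keeps every sample total exactly equal to its
  drawn depth — both properties the generator promises, and they cannot
  both hold with post-hoc zeroing.
* Structural prevalence uses fixed-count dropout by default: exactly
  `⌊(1−prev)·n_g⌋` samples per pooled group are zeroed per feature
  (core prevalence 0.95, background 0.75), so the realised structural
  prevalence never falls below target and background features sit
  deterministically below the 90% core threshold. A per-sample Bernoulli
  mode exists; the two-group null design (`nullDesign`) uses no dropout
  at all so its samples are iid — the exchangeability a permutation-test
  calibration requires (fixed-count dropout would induce within-group
  dependence).
* Depths are log-normal (`depth_mean = 10000`, `sdlog = 0.3` —
  overdispersed totals of the magnitude a filtered amplicon run
  produces); counts are multinomial per sample. Everything is
  bit-reproducible under the design seed.

What the generator does **not** emulate: taxonomy misassignment,
chimeras, contamination, spatial/temporal autocorrelation beyond the
block labels, overdispersion beyond the logistic-normal (no
Dirichlet-multinomial layer), or substrate-specific compositional shifts
(a host's proxy biofilm shares the host's planted structure). Passing
tests therefore demonstrate correctness of the *methods* under a
compositional latent-Gaussian world, not performance guarantees on real
amplicon data.

# Problem sizes used in the checks

The test suite and acceptance script choose sizes that make each
property sharp at desk scale: exact permutation enumeration at n = 6
(3 vs 3; 20 assignments); type-I-error calibration on 200 null data sets
of 2 × 6 samples with 999 permutations (acceptance band = the 95%
binomial interval around 0.05); planted-core recovery over 20 replicate
studies of 40 features × 4 replicates/group; network recovery on band
graphs of p = 50 at n = 100 (20 replicates against 100 size-matched
random graphs each) with the sample-size trend checked at n = 50 vs 200
(10 replicates each); brute-force modularity on graphs of ≤ 8 nodes.

# Numerical conventions and degenerate inputs

* Permutation p-values: `(1+b)/(1+m)` sampled, `b/m` over the complete
  enumeration (observed assignment included) in exact mode; permutation
  statistic comparisons use a 1e-12 slack so ties count as extreme.
* CLR rows sum to zero within 1e-9; a zero pseudocount with zeros
  present is an error, not a silent log(0).
* Eigen-based quantities (PCoA, natural connectivity) symmetrise their
  input and use a relative tolerance of about 1e-9 for rank decisions.
* Degenerate cases are defined, not accidental: edgeless graphs have
  density, mean degree, transitivity, modularity and natural
  connectivity 0; identical profiles have distance 0 even when every
  metric is constant; an isolated node is peripheral with Zi = Pi = 0;
  a sample with an all-zero composition aborts the simulation with an
  explicit error.
* Pipeline stage seeds are derived from the master seed by hashing the
  stage name, so inserting a stage never perturbs the randomness of the
  stages before it. The run manifest records wall-clock runtimes and is
  therefore the one output file excluded from byte-identity comparisons.

# Known limitations

* The lasso neighborhoods use a fixed penalty path; no cross-validated
  or extended-BIC alternative is offered, since StARS is the selection
  procedure the pipeline is built around.
* The glasso (inverse-covariance) variant of compositional network
  inference, bootstrapped edge p-values and time-resolved networks are
  out of scope, as are mixed models, differential-abundance testing and
  environmental redundancy analysis.
* Modularity maximisation is heuristic; optimality is only guaranteed
  (and only checked) for the small graphs where exhaustive search is
  feasible.
* PERMANOVA is one-factor (with optional strata); factorial designs
  should go to `vegan::adonis2` directly.
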
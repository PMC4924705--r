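---
title: "Methods: from developmental co-expression modules to survival and chemoresponse screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from developmental co-expression modules to survival and chemoresponse screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexsurv)
```

# Overview

`coexsurv` chains five analyses: (1) a paired comparison of how well protein
versus mRNA expression profiles reflect protein–protein interactions; (2)
weighted co-expression module discovery over a developmental time series,
with an interaction-based module filter; (3) grouping of modules into
early/middle/late developmental stages by their activity profiles; (4) a
two-cohort Cox survival screen over the stage groups with a permutation
group-enrichment test; and (5) a drug-response association screen in a
cell-line panel. This vignette records the models, the tunable parameters,
the numerical choices, and what the synthetic generators do and do not
emulate.

# Interaction co-expression (protein vs mRNA)

For each retained interaction (experimental score > 200 **and** combined
score > 400, strict inequalities; duplicate records collapsed keeping the
per-channel maximum; self-loops dropped), the Pearson correlation of the two
endpoint profiles is computed over the ordered samples, separately in the
protein and mRNA matrices. Edges with an endpoint missing from a matrix are
skipped and counted; edges whose correlation is undefined in either layer
(zero variance, or fewer than 3 shared finite observations) are excluded
pairwise, and the exclusion count is reported — the paired *t*-test requires
complete pairs. The test is two-sided even though the hypothesis is
directional, because the question as posed is whether the two correlation
sets *differ*. When every paired difference is exactly zero we report
*t* = 0, *p* = 1 rather than an error, so that degenerate inputs remain
summarizable.

# Weighted co-expression network

The network core is written from scratch (no external network library):

* **Soft adjacency.** `a_ij = |cor(x_i, x_j)|^β` (unsigned network), β = 10
  by default. Zero-variance genes make the correlation undefined; they
  produce an error naming the offending genes rather than silent NaN
  propagation, since the caller should filter them.
* **Topological overlap.** For `i ≠ j`,
  `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
  `l_ij = Σ_u a_iu a_uj` and `k_i = Σ_u a_iu`; the diagonal is 1. The
  matrix-product implementation is verified against a literal triple loop to
  1e-12; the product is explicitly re-symmetrized because floating-point
  `A %*% A` is symmetric only to one ulp, and downstream tie-breaking
  assumes exact symmetry.
* **Average linkage.** A standard UPGMA agglomeration (Lance–Williams
  update) over `1 − TOM`. Ties in the minimum dissimilarity are broken by
  merging the pair with lexicographically smallest cluster positions, so
  the tree — and everything downstream — is fully deterministic.
* **Dynamic tree cut.** Two phases. A static cut at `cut_height` (default
  0.9 of the tallest merge) first strips the unstructured top of the tree,
  where isolated genes and between-module merges interleave. Each component
  is then refined recursively at its top merge: under average linkage the
  top-merge height *is* the mean cross-branch dissimilarity, so the merge is
  treated as a between-module join when that height exceeds `split_ratio`
  (default 1.12) times the larger of the two branches' internal mean
  dissimilarities. When one branch is smaller than `min_module_size`
  (default 5, matching the smallest module the screen should admit), it is
  peeled off and descent continues into the large branch. Peeled and other
  sub-minimum branches are afterwards merged into the closest module by
  average dissimilarity when that distance is within `cut_height`, and
  otherwise left unassigned (label 0); unassigned genes are excluded from
  all downstream stages. If the static cut leaves no branch of
  `min_module_size` at all — a tree without structure, e.g. all
  dissimilarities equal — the whole tree is reported as a single module
  rather than silently fragmenting. Labels are sorted by decreasing module
  size.

The design of the cut was driven by planted-structure recovery. A cut based
on a high percentile of merge heights fails in two realistic situations:
closely related modules can join *below* that percentile, and background
genes chain onto the top of the tree as singleton merges whose heights
interleave with genuine module joins. The separability-ratio criterion
handles the former (it compares a candidate join against the branches' own
scatter, not against a global height), and the peel-and-reattach rule
handles the latter. Both parameters are exposed (`cut_height`,
`split_ratio`) because no single default suits every dissimilarity scale.

* **Interaction filter.** Within each module only genes with at least one
  interaction to another member of the same module are kept; modules with no
  internally interacting gene are dropped entirely, and labels are
  re-compacted. This mirrors the screen's rationale that a co-expression
  module none of whose members interact is not interpretable as a protein
  complex or pathway.

# Stage grouping

A module's activity at a time point is the arithmetic mean of its members'
expression. Activity rows are z-scored before clustering: modules differ in
absolute abundance, and without standardization magnitude rather than shape
would dominate the Euclidean distances. Modules are clustered by average
linkage and the tree is cut into `n_groups` (default 3) clusters; each
cluster is labelled by the time-axis block (default: consecutive thirds of
the axis, configurable as explicit column blocks) in which its mean
standardized activity is largest. If two clusters claim the same stage the
cluster with the larger block mean keeps it and the other takes its
next-best block; the reassignment is reported via a message rather than
silently. Constant activity profiles make z-scoring undefined and are an
error — no silent arbitrary grouping. Because only z-scored shapes enter the
clustering, stage labels are invariant to positive rescaling of the whole
expression matrix.

# Survival screen

`fit_cox()` maximizes the Cox partial likelihood with **Breslow tie
handling** by Newton–Raphson (score-norm tolerance 1e-8, at most 50
iterations, step halving on likelihood decrease). Breslow was chosen because
ties are rare for continuous expression-driven times and it is the simplest
correct-for-few-ties variant. Covariates are centred before optimization for
numerical stability (the estimate is invariant); categorical covariates are
expanded to reference-level indicators and age enters untransformed. A
constant expression vector yields the degenerate convention β = 0, *p* = 1
with a flag; fits drifting beyond |β| > 20 (complete separation) are flagged
non-converged and never silently reported. The implementation agrees with a
grid search of the log partial likelihood (step 1e-4) to three decimals on
small datasets, and recovers planted log hazard ratios at n = 1000 with
nominal Wald coverage.

The **median split** assigns values equal to the median to the low group —
deterministic on discrete data — and the log-rank statistic is the standard
two-group observed-versus-expected chi-square with 1 df. Only the split
depends on the expression values, so the statistic is invariant to monotone
transformation.

**Two-cohort validation** keeps genes with *p* < α (default 0.05) in the
discovery cohort, *p* < α in the validation cohort, and the same sign of the
log hazard ratio in both — the strictest natural reading of "consistent";
`sign_only = TRUE` relaxes the validation significance requirement.

**Permutation enrichment.** The observed statistic is the overlap between a
stage group's genes and the validated survival genes. The null redraws
`|group|` genes without replacement from the universe, which defaults to all
genes entering the screen across the three groups (configurable; the
alternative — resampling from the genome — dilutes the null with genes that
never had a chance to be screened). The estimator is `(b + 1) / (B + 1)`,
never exactly zero, and the test is seeded and restores the caller's RNG
state. On small problems it agrees with the exact hypergeometric tail within
Monte-Carlo error; under a uniform null its rejection rate at 0.05 is
slightly conservative because of overlap discreteness and the +1 smoothing.

# Chemoresponse screen

Per compound, log10(IC50) values are z-scored across cell lines (compounds
with zero variance are excluded with a report). Classification uses the mean
and the sample (n−1) standard deviation: strictly above μ + SD is resistant,
strictly below μ − SD sensitive, boundary values intermediate. After
z-scoring, μ = 0 and SD = 1, so normalization is redundant for the
classification itself; both steps are implemented faithfully and the
equivalence (affine invariance of the labels) is property-tested. Compounds
need at least 10 sensitive **and** 10 resistant lines (inclusive) to enter
testing. The per-(gene, compound) test is Welch's two-sample *t*-test —
group sizes and variances differ by construction — with intermediate lines
excluded; combinations where either group has fewer than two expression
values are skipped and counted. No multiple-testing correction is applied by
default, matching the screen's per-pair α = 0.05 definition of association;
a Benjamini–Hochberg column is available as an opt-in extra.

# Synthetic data: what is emulated, and what is not

* **Development.** The time axis (default 9 points) splits into consecutive
  early/middle/late thirds. A module's template is 1 inside its stage block
  and −0.5 elsewhere, plus a per-module identity jitter with sd `noise_sd`
  (default 0.4). The jitter is made sample-orthogonal to the block pattern
  and to the jitters of earlier same-stage modules, so planted modules are
  distinguishable *by construction*: the between-template correlation of
  same-stage modules is the deterministic value
  `var_block / (var_block + noise_sd²)` (≈ 0.76 at the defaults) rather than
  a random draw that occasionally approaches 1 and makes recovery
  ill-posed. Member genes add independent noise whose variance is derived
  from the realized template variance so that the expected within-module
  correlation equals the design value ρ; background genes are pure noise.
  The mRNA profile of a gene is its protein profile plus independent noise
  scaled so that the protein–mRNA profile correlation is
  `mrna_agreement` (0 gives an independent profile). This emulates stage-
  peaked co-expression and a degraded mRNA layer; it does not emulate
  reporter-ion chemistry, peptide-level quantification, missingness, or
  mean–variance trends of real proteomics data, so passing recovery tests
  demonstrates correctness of the machinery, not performance on real data.
* **Interactions.** Within-module pairs become edges with probability
  `p_within`, all other pairs with `p_between`; scores are drawn strictly
  above the read filters. Degree heterogeneity and hub structure of real
  interactomes are not modelled.
* **Survival.** Event times are exponential with rate
  `baseline_rate · exp(Σ β_g x_g + covariate terms)` (defaults 0.1, with
  independent exponential censoring at rate 0.05, giving roughly two-thirds
  events); proportional hazards holds by construction, which is exactly what
  makes β recoverable and the Wald coverage interpretable. Real cohorts'
  non-proportionality and informative censoring are out of scope.
* **Drug response.** log10(IC50) values are iid normal per compound; for a
  planted (gene, drug) pair the gene's expression is shifted by ∓δ/2 in the
  lines classified sensitive/resistant for that drug, so the planted group
  difference equals δ. With 60 normal values the expected sensitive and
  resistant counts are ≈ 9.5 each, so the ≥10/≥10 filter retains only a
  fraction of compounds — as in real panels, where most compounds fail the
  criterion. For this reason the generator's power properties are measured
  on the planted pair's *t*-test directly, while the filter's inclusive
  boundary behaviour is tested separately.

# Pipeline defaults and problem sizes

The bundled configuration (`pipeline_config()`) plants six modules of 25–40
genes (two per stage) plus 40 background genes over 9 time points
(ρ = 0.9, mRNA agreement 0.6), interaction probabilities 0.25 within and
0.02 between modules, a discovery cohort of 60 patients and a validation
cohort of 200, eight early-module genes with log hazard ratio 0.8, 2000
permutations, and 40 compounds over 60 cell lines with three planted
gene–drug pairs at δ = 3. These sizes keep a full run in the seconds range
while leaving every stage's statistics non-trivial; the acceptance script
scales the Monte-Carlo studies (200 cohorts of n = 1000 for Cox recovery,
2000 null genes for calibration, 1000 replicates for permutation
calibration) to a few minutes in total. All derived seeds come from the
single configuration seed, outputs carry a version-and-configuration-hash
header, and a repeated run is byte-identical.

# Known limitations

* The dynamic tree cut is the simple "tree" flavour with the refinements
  described above; it does not implement PAM-like per-gene reassignment, so
  borderline genes near module boundaries may stay unassigned where a
  hybrid cutter would place them.
* Modules whose underlying templates are very highly correlated (beyond
  what the orthogonalized generator produces) merge by design — no
  dissimilarity-based method can separate them.
* The Cox fitter targets the univariate-plus-few-covariates screening
  regime; it is not tuned for high-dimensional multivariable fits.
* The permutation test resamples gene labels within the screened universe;
  enrichment against a genome-wide background is a different null and must
  be requested explicitly via the `universe` argument.
* Stage labelling by block argmax operationalizes "early/middle/late"
  automatically; a transition-like module with a flat or bimodal profile is
  assigned to its best block rather than to a separate "mixed" category.
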
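# coexsurv

Linking developmental co-expression structure to cancer prognosis.

`coexsurv` implements, as a tested and reusable R pipeline, an analysis
strategy in which co-expression modules discovered in a developmental
proteome time series are carried forward into cancer cohorts: modules that
are highly expressed at a particular developmental stage are screened for
genes whose expression predicts patient survival, and those genes are then
tested for association with drug response in a cell-line panel. Every stage
is exercisable end to end on synthetic data with planted ground truth, so
the statistical machinery can be validated without any external download.

The pipeline has five analysis stages:

1. **Interaction co-expression.** For every protein–protein interaction
   (STRING-style edge list filtered at experimental score > 200 and combined
   score > 400), the Pearson correlation *r* of the two endpoint profiles is
   computed in the protein layer and in the mRNA layer, and the paired
   difference is tested with a two-sided paired *t*-test — do protein
   profiles reflect the interactome better than mRNA profiles?
2. **Weighted co-expression modules.** An unsigned weighted network is built
   by soft thresholding, `a_ij = |cor(x_i, x_j)|^β` with β = 10; the
   topological overlap measure
   `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   `l_ij = Σ_u a_iu a_uj`, `k_i = Σ_u a_iu`, augments direct adjacency with
   shared-neighbourhood strength; `1 − TOM` feeds average-linkage (UPGMA)
   clustering and modules are extracted by a dynamic tree cut
   (minimum module size 5). Genes without an interaction partner inside
   their own module are removed, and modules with no internal interactions
   are dropped entirely.
3. **Stage grouping.** Each module's activity is the mean member expression
   per time point; modules are clustered on their z-scored activity profiles
   and labelled early / middle / late by the time-axis block in which their
   standardized activity peaks.
4. **Survival screen.** Each stage group's genes are screened by univariate
   Cox proportional-hazards regression (own Newton–Raphson maximizer of the
   Breslow partial likelihood; optional age/gender/race adjustment) in a
   discovery cohort, re-screened in an independent validation cohort
   (validated = p < 0.05 in both, same sign of the log hazard ratio), with
   median-split log-rank tests per gene, and each group is tested for
   enrichment of validated genes by a permutation test (`(b+1)/(B+1)`
   estimator, default 10,000 draws).
5. **Chemoresponse.** Per compound, log10(IC50) values are z-scored across
   cell lines; lines above μ + SD are resistant, below μ − SD sensitive,
   the rest intermediate; compounds with ≥ 10 sensitive and ≥ 10 resistant
   lines are retained; per (gene, compound), Welch's *t*-test compares the
   gene's expression between sensitive and resistant lines.

Synthetic generators (`simulate_development()`, `simulate_ppi()`,
`simulate_survival_cohort()`, `simulate_drug_response()`) plant known module
structure, interaction enrichment, log-hazard effects and gene–drug effects,
and are the basis of the test suite.

## Worked example

The bundled synthetic configuration runs the whole pipeline in a few
seconds:

```r
library(coexsurv)
run <- run_pipeline(pipeline_config(seed = 1, outdir = "coexsurv-out"))
#> simulate: 230 genes x 9 time points, 1204 interactions
#> coexpress: 1204 edges, mean r protein 0.522 vs mRNA 0.159 (p = 5.42e-120)
#> modules: 6 detected (sizes 48/34/31/31/31/27), PPI filter dropped 9 genes, 6 modules kept
#> stages: 1=early 2=middle 3=early 4=late 5=middle 6=late
#> survival (early): 75 screened, 5 significant, 4 validated, enrichment p = 0.01999
#> survival (middle): 62 screened, 6 significant, 0 validated, enrichment p = 1
#> survival (late): 56 screened, 5 significant, 0 validated, enrichment p = 1
#> chemo: 10/40 compounds retained, 8 significant gene-drug pairs
```

Reading the log: the generator planted six co-expressed modules (two per
developmental stage) plus 40 background genes, and an interaction set
enriched within modules. The protein layer reflects those interactions far
better than the degraded mRNA layer (mean per-edge *r* 0.522 vs 0.159). All
six modules are recovered and assigned to their planted stages. Eight genes
of an early-stage module carry a planted log hazard ratio of 0.8: four of
them survive the two-cohort screen (discovery n = 60, validation n = 200),
and only the early group is significantly enriched for validated survival
genes (permutation p = 0.02). In the drug screen, 10 of 40 simulated
compounds have ≥ 10 sensitive and ≥ 10 resistant cell lines; the planted
gene–drug pairs dominate the significant associations.

Each stage writes a TSV artifact (with a provenance header recording the
package version and configuration hash) plus a machine-readable
`summary.tsv` into `outdir`; the run is byte-identical under a fixed seed.
A thin command-line wrapper is included at `inst/scripts/pipeline.R`.

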
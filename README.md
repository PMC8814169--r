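# rdascape

Landscape genomics for geographically structured plant (and other)
populations: how much genome-wide SNP variation tracks environmental
gradients, how much is spatial autocorrelation from restricted dispersal,
and how much is population structure — plus a genome scan for the loci
driving the environmental component.

`rdascape` is aimed at population geneticists analyzing reduced-
representation SNP data (GBS and similar) from collections sampled across
a landscape: a dosage matrix, collection-site coordinates, and a table of
environmental variables. Everything is also exercisable on built-in
synthetic data with known ground truth.

## The method

The core is redundancy analysis (RDA): multivariate least squares of the
centered dosage matrix *Y* on predictors *X*, followed by principal axes
of the fitted values, with R² = ‖Ŷ‖² / ‖Y‖². Partial RDA residualizes *Y*
and *X* on covariates *Z* first. Two-set variance partitioning splits
explained variation into unique and joint adjusted-R² fractions

    a = R²adj(X1 ∪ X2) − R²adj(X2),  c = R²adj(X1 ∪ X2) − R²adj(X1),
    b = R²adj(X1) − a,               d = 1 − R²adj(X1 ∪ X2)

with Ezekiel adjustment and permutation tests (overall and marginal)
for significance. Around this engine the package provides:

* **Spatial predictors** — Gabriel graph over demes, inverse-distance
  (km⁻¹) weights, distance-based Moran's eigenvector maps (dbMEM), and
  forward selection with the double stopping rule, run separately for
  broad-scale (positive-eigenvalue) and fine-scale (negative) MEMs.
* **Environmental processing** — collinear grouping (average linkage on
  1 − |r|), synthetic PC1 variables per group, and iterative VIF < 5
  selection.
* **Population structure** — PCA with out-of-sample projection,
  parallel-analysis estimation of the number of ancestral clusters,
  likelihood-free ancestry factorization by alternating constrained least
  squares, Hudson ratio-of-averages FST (plus windowed genome profiles),
  Nei (1972) distance, and neighbor-joining trees in Newick.
* **Genome scan** — SNP loadings on the leading RDA axes → Mahalanobis
  distances → genomic-inflation-corrected χ² p-values → BH q-values,
  with and without ancestry correction.
* **Gene-flow statistics** — allele-sharing (Dps) distances, unPC scores
  (PC-space distance over km between deme centroids) with a
  Box–Cox/Student-t outlier test, and a Wilcoxon test for lower migration
  rates at mapped barriers.
* **LD decay** — windowed composite r², Hill–Weir curve fitting, loess
  smoothing, half-decay distance.
* **Synthetic data** — selfing populations over a landscape with a
  Gaussian random field on allele-frequency logits (isolation by
  distance), a dispersal barrier as an effective-distance penalty,
  collinear environmental gradients, a minority of environmentally
  selected loci, and a truth record for every simulated quantity.

## Worked example

Simulate a landscape study, partition SNP variation, and scan for the
planted adaptive loci:

```r
library(rdascape)

cfg <- sim_config(n_demes = 20, n_ind = 120, n_snps = 2000,
                  effect_size = 1.5, seed = 42)
dm  <- simulate_demes(cfg)
env <- simulate_env(dm, seed = 42)
sim <- simulate_genotypes(cfg, dm, env, env_column = 6)

G <- filter_sites(sim$geno, maf_min = 0.05, max_missing = 0.2)$geno
X <- impute_mean(G)
#> <geno_matrix> 120 individuals x 1949 sites (3.0% missing)

# spatial basis and forward selection
mems <- compute_dbmem(build_weights(gabriel_graph(dm$demes)),
                      membership = dm$individuals$deme_id)
sel  <- forward_select(X, mems, n_perm = 199, seed = 42)   # 16 of 19 MEMs

# environment vs space
Xenv <- make_synthetic_vars(env, cluster_collinear(env, cut = 0.3))$values
Xenv <- Xenv[match(dm$individuals$deme_id, rownames(Xenv)), ]
varpart_rda(X, Xenv, sel$vectors)
#> <variance_partition> adjusted fractions
#>   a (X1 alone) = 0.0008
#>   b (joint)    = 0.0159
#>   c (X2 alone) = 0.0254
#>   d (residual) = 0.9580
```

Raw percentages for the same fit: environment explains 4.1% of SNP
variation and space 17.0%, of which 1.7% is joint — space dominates, and
almost none of the environmental signal is separable from it once the
shared component is removed (a = 0.0008). That is the expected signature
of environmental gradients confounded with isolation by distance.

```r
anc <- estimate_ancestry(X, 4)
fst <- hudson_fst(G, assign_clusters(anc)$labels)
round(fst$dist$mat, 4)
#>        1      2      3      4
#> 1 0.0000 0.0346 0.0323 0.0421
#> 2 0.0346 0.0000 0.0352 0.0443
#> 3 0.0323 0.0352 0.0000 0.0407
#> 4 0.0421 0.0443 0.0407 0.0000

scan_pipeline(sim$geno, env$values[match(dm$individuals$deme_id,
              rownames(env$values)), ], Q = anc$Q, k = 4)$simple
#> <scan_result> 2000 SNPs, k = 4, lambda = 0.971, 14 candidates (FDR < 0.05)
```

All 14 candidates are among the 40 truly adaptive loci planted by the
generator (the remainder fall below the power of a 120-individual study).
Cluster FST of 0.03–0.04 is the weak-differentiation regime the simulation
is calibrated to.

A reproducible multi-stage pipeline (with YAML configuration, per-stage
provenance and change detection) is available through `pipeline_config()`,
`run_stage()` and `run_pipeline()`, or from a shell via
`inst/cli/rdascape-pipeline.R`.

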
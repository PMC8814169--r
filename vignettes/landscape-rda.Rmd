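---
title: "Partitioning genomic variation over a landscape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning genomic variation over a landscape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdascape)
```

# The problem

Wild relatives of crop plants occupy environmental gradients over small
geographic ranges, and a central question in landscape genomics is how much
of their genome-wide variation tracks the environment (a candidate signal of
local adaptation) versus how much is explained by spatial autocorrelation
and population structure — the signatures of restricted dispersal and
drift. `rdascape` implements the full analysis chain for this question on a
biallelic SNP dosage matrix: constrained ordination (redundancy analysis,
RDA) with environmental predictors, spatial eigenfunctions, and ancestry
covariates; the supporting population-genetic statistics; an RDA-based
genome scan for candidate adaptive loci; and a synthetic-data generator
with a full ground-truth record so every stage is testable without any
external download.

# Redundancy analysis and variance partitioning

RDA of a response matrix $Y$ (here: centered SNP dosages, individuals
$\times$ sites) on predictors $X$ is multivariate least squares followed by
a principal-axis rotation of the fitted values
$\hat Y = X(X^\top X)^- X^\top Y$. The explained fraction is
$R^2 = \|\hat Y\|^2_F / \|Y\|^2_F$. In *partial* RDA with covariates $Z$,
both $Y$ and $X$ are first residualized on $[1, Z]$.

Two design choices matter and are fixed here:

* **Denominator of partial $R^2$.** The default denominator is the *total*
  (pre-residualization) variance of $Y$, so that fractions from simple and
  partial models are additive and can be read as percentages of total SNP
  variation. The residual-variance denominator is available via
  `denominator = "residual"` but is not the default.
* **Adjusted $R^2$.** Ezekiel's correction with covariate degrees,
  $R^2_{adj} = 1 - (1 - R^2)\frac{n - 1 - q}{n - 1 - q - p}$, where $p$ and
  $q$ are the ranks of the (residualized) predictor and covariate blocks.
  Negative adjusted fractions are reported as-is, never truncated.

Two-set variance partitioning (`varpart_rda`) computes
$a = R^2_{adj}(X_1 \cup X_2) - R^2_{adj}(X_2)$ (unique to $X_1$),
$c$ symmetrically, $b = R^2_{adj}(X_1) - a$ (joint) and
$d = 1 - R^2_{adj}(X_1 \cup X_2)$. The identities
$a + b = R^2_{adj}(X_1)$, $b + c = R^2_{adj}(X_2)$ and $a+b+c+d = 1$ hold
to machine precision by construction and are asserted in the test suite.
Raw (unadjusted) analogues are always reported alongside, since observed
percentage decompositions are usually quoted raw.

**Rank detection.** Ranks are determined from singular values at a relative
tolerance of $10^{-10}$ *anchored to the pre-residualization scale* of the
block. This matters: when $Z$ spans $X$ (e.g. testing a term against
itself), the residualized block is numerical noise whose own largest
singular value would pass a self-relative threshold; anchoring to the
original scale detects rank 0 and returns a partial $R^2$ of exactly zero.

**Permutation tests.** The overall test uses pseudo-
$F = (SS_{fit}/p)/(SS_{res}/(n-p-q-1))$ with free row permutation of the
centered response, or — when covariates are present — permutation of the
reduced-model (covariates-only) residuals, re-residualized each draw.
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$. Marginal (type III) tests treat
all other terms as covariates. The default is 5000 permutations for final
models (`pipeline_config`), 999 elsewhere; the acceptance suite verifies
the rejection rate under the null sits inside the 95% binomial band of the
nominal 5% level over 200 replicate datasets.

# Spatial eigenfunctions (dbMEM)

Space enters as distance-based Moran's eigenvector maps: the deme network
is the Gabriel graph (edge $(i,j)$ kept iff
$d_{ij}^2 \le d_{ik}^2 + d_{kj}^2$ for all $k$; boundary ties keep the
edge), edges are weighted $1/d_{km}$ with great-circle (haversine,
$R = 6371.0088$ km) distances, and the doubly centered weight matrix
$HWH$ is eigen-decomposed. Positive-eigenvalue MEMs model broad-scale and
negative-eigenvalue MEMs fine-scale autocorrelation; Moran's I of a MEM is
proportional to its eigenvalue, which the tests verify numerically. MEMs
are computed at deme level and replicated to individuals by membership;
with ~4 individuals per deme this is the only defensible option, and it
keeps the spatial basis orthogonal at the deme level.

Forward selection uses the double stopping rule, run separately within the
positive and negative eigenvalue classes and then unioned: a class enters
only if its global permutation test is significant; MEMs are then added
greedily by $R^2$ increment until the candidate's permutation p-value
exceeds `alpha` (default 0.05) or the cumulative adjusted $R^2$ exceeds
the class's global adjusted $R^2$. Per-class selection follows the
forward-selection literature for eigenvector sets of mixed sign; selection
uses 999 permutations by default (the 5000-permutation convention applies
to final model tests, not to selection).

# Population structure

* **Latent dimension.** `estimate_d` uses parallel analysis: the number of
  covariance eigenvalues of the standardized genotype matrix exceeding the
  maximum eigenvalue over column-permuted replicates, plus one for the mean
  component. Note that this criterion is a null-calibrated test, not a pure
  rank computation — operations that preserve rank but change eigenvalue
  magnitudes (such as duplicating all individuals) can change the estimate.
* **Ancestry coefficients.** `estimate_ancestry` is a likelihood-free
  two-step estimator: the individual-specific frequency matrix is the
  rank-$K$ principal truncation of $X/2$ clipped to $[0,1]$, then factorized
  as $F \approx QP$ by alternating constrained least squares — the $Q$ step
  solves each row's simplex-constrained problem exactly by enumerating
  active sets (exact for the small $K$ used here), the $P$ step runs clipped
  coordinate descent. Both steps are exact or monotone given the other
  block, so the objective is non-increasing; iteration stops at a relative
  change below $10^{-6}$ or 1000 iterations. Initialization is
  deterministic (pivoted anchor rows), so results need no seed.
* **Differentiation.** FST is the Hudson-style ratio of averages: per-site
  numerators $(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$
  and denominators $p_1(1-p_2) + p_2(1-p_1)$ are summed over sites before
  the ratio; sites with zero denominator or fewer than two observed alleles
  in either group are skipped and counted. Negative estimates are reported,
  not truncated. Nei's (1972) standard distance pools allele identities
  over loci; no small-sample correction is applied. The neighbor-joining
  implementation fixes the unstated details: ties in the Q-criterion break
  toward the lexicographically lowest pair, and negative branch lengths are
  clamped to zero with the deficit moved to the sister branch. On additive
  matrices the algorithm is exact, which the tests verify by inverting
  random trees of up to eight taxa.

# Genome scan

The scan follows the Mahalanobis-on-loadings framework: SNP loadings on
the first $k$ (default 4) constrained axes are summarized as
$D^2_i = (\ell_i - \hat\mu)^\top \hat\Sigma^{-1} (\ell_i - \hat\mu)$,
recalibrated by the genomic inflation factor
$\lambda = \mathrm{median}(D^2) / \chi^2_{k,0.5}$, converted to upper-tail
$\chi^2_k$ p-values and Benjamini–Hochberg q-values, with candidates at
$q < 0.05$.

One implementation choice is deliberate and consequential: `scan_pipeline`
standardizes SNP columns (unit variance) before the scan RDA. Raw dosage
columns have MAF-dependent variance, so unscaled loadings mix allele
frequency into the statistic; in calibration simulations the unscaled scan
showed a false-discovery proportion near 0.3 at nominal FDR 0.05, versus
below 0.1 after standardization, with $\lambda$ close to 1. The variance
partitioning RDA, by contrast, keeps the centered unscaled response, so
that percentages refer to dosage variance.

**What recovery simulations show.** The acceptance benchmark plants 2% of
5000 loci with an environmental effect on the spatially *independent*
gradient among the simulated collinear set, at 20 demes and 200
individuals. The choice of gradient matters: effects aligned with latitude
are confounded with isolation by distance to the point of
unidentifiability — in oracle experiments (a univariate test given the true
causal variable), the false-discovery proportion reaches 0.7 under the
latitude gradient, which is precisely the confounding the partial models
exist to expose. The operating effect size is 1.5 logit units per
environmental SD; the scan's measured power curve under the
FST-calibrated field (below) is TPR $\approx$ 0.3 at 0.8, 0.5 at 1.2 and
0.76 at 1.5, with FDP below 0.1 throughout, so the benchmark sits where
power is comfortably diagnostic while error control is tested everywhere.

# Gene-flow statistics

`dps_distance` computes allele-sharing distances $D_{ps} = 1 - \bar p$
with the min-sharing convention per site, missing-aware. `unpc_scores`
forms the ratio of PC-space distance between deme centroids (top 3 axes by
default, matching the number of interpretable structure axes) to
great-circle distance. The outlier rule Box–Cox-transforms the scores
($\hat\lambda$ maximizing the profile likelihood on a $[-2,2]$ grid, step
0.01; non-positive scores shifted by $-\min + \varepsilon$ with the shift
reported), standardizes, and flags pairs beyond the two-sided
$t_{1-\alpha/2,\,N-1}$ critical value — "high" marks isolation over a short
distance, "low" long-distance similarity. An empirical-quantile variant
(top/bottom $\alpha/2$) is available. The barrier association test is a
one-sided Mann–Whitney rank-sum test (normal approximation with tie
correction) that barrier-masked raster cells have lower log migration
rates; a fully tied raster returns $p = 0.5$ since the rank statistic is
degenerate there.

# Linkage disequilibrium

Pairwise $r^2$ is the squared Pearson correlation of mean-imputed dosages
(composite LD — phase is unknown in GBS dosages) within a 250-marker
window. The Hill–Weir expectation
$E[r^2] = \frac{10+C}{(2+C)(11+C)}\Big[1 + \frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\Big]$,
$C = \rho d$, is fitted by bounded scalar least squares over
$\rho \in [10^{-8}, 10]$ per bp on log-spaced bin means; binning is the
default because the raw pair cloud is heteroscedastic and dominated by
short distances (raw-pair fitting via `bins = 0`). Because composite and
gametic $r^2$ differ, fitted $\rho$ values are interpreted comparatively.
Smoothing uses tricube local-linear regression (`loess`, span 0.005 on
study-scale data) evaluated on a 512-point log-spaced grid; the half-decay
distance is the smallest grid point at or below half the curve maximum,
reported as right-censored when the curve never reaches it.

# The synthetic-data generator

`sim_config` defaults encode the study design the package targets: 244
selfing individuals in 58 demes over a 200 km extent, 20,000 SNPs with 3%
MCAR missingness, four spatially arranged ancestry clusters, and a linear
barrier. Parameters chosen where a value had to be fixed:

* `selfing_F = 0.96` — the equilibrium inbreeding coefficient for a
  predominantly selfing grass with roughly 2% outcrossing,
  $F = (1-t)/(1+t)$.
* `gp_sigma2 = 0.25` (logit² units), `gp_range_km = extent/4` — calibrated
  so that cluster-level Hudson FST lands at 0.02–0.04, the differentiation
  scale of the study system; this value was fixed from that calibration
  and not revisited.
* Barrier crossing penalty 3 on effective distances. Because the penalty
  deforms the exponential kernel, the deme covariance can acquire small
  negative eigenvalues (about $-0.1\%$ of the leading eigenvalue at the
  default geometry); these are clipped to zero (standard PSD repair), and
  a covariance more than 5% indefinite is refused.
* Deme frequencies are clipped to $[0.001, 0.999]$ to avoid fixation before
  MAF filtering. Individuals are allocated one per deme, the rest
  multinomially, so no deme is empty.
* The ancestry truth $Q$ softens the spatial k-means cluster assignment
  with a Dirichlet(0.3) perturbation (60/40 mixture), reproducing the
  empirical pattern that a majority of individuals in such collections
  have a maximum ancestry coefficient below 0.9.

What the generator deliberately does **not** emulate: linkage (sites are
independent given deme frequencies, so LD decay fits on simulated data
measure only the sampling floor $1/n$), coalescent genealogies,
recombination maps, genotyping error and allele-depth likelihoods, and
continuous environmental rasters. Passing tests therefore demonstrate the
statistical machinery — estimator algebra, calibration, recovery under the
stated field model — not robustness to those real-data features.

`simulate_admixture` is a separate benchmark generator (Balding–Nichols
cluster frequencies at a target FST, Dirichlet ancestry, binomial
genotypes) used for factorization and projection tests where a discrete
admixture truth is needed.

# Problem sizes and reproducibility

The test suite runs at deliberately small sizes (hundreds of individuals,
$10^2$–$5\times10^3$ sites, 99–199 permutations for selection tests)
chosen so that each property is measured with adequate precision; the
acceptance script analyzes a 244-individual, 58-deme, 3000-SNP study and
three 5000-SNP scan replicates. Every random draw derives from a single
seed through `derive_seed(seed, stage)`, so stages are independently
reproducible; the pipeline records provenance (config slice, input
checksums, derived seed) per stage and skips stages whose provenance is
unchanged.

# Known limitations

* The collinear-grouping index is $1 - |r|$ with average linkage and a 0.3
  cut — a documented, configurable convention; other grouping indices exist
  and can give different synthetic variables.
* Hudson FST assumes binomial allele sampling; under extreme inbreeding the
  effective allele count per individual approaches 1 rather than 2, which
  biases the estimator slightly upward (visible in the panmixia test only
  when selfing is high).
* The unPC score uses unweighted centroid distance over the top axes; the
  original tool's axis weighting is not public, so agreement is
  qualitative.
* `estimate_d`'s permutation null is conservative for strongly admixed
  (continuous) structure; on smooth isolation-by-distance landscapes it
  counts spatial axes rather than discrete clusters.
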
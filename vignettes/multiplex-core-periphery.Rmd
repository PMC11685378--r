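---
title: "Core-periphery disruption in multimodal multiplex brain networks"
author: "multiplexcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-periphery disruption in multimodal multiplex brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiplexcore)
```

## The model

Single-modality brain networks give a partial view of the connectome.
This package integrates three modalities over one parcellation (by default
114 regions: 100 cortical across seven canonical functional systems plus
14 subcortical) into a *multiplex* network — a multilayer network whose
layers share the same node set with one-to-one node correspondence and no
interlayer edges — and quantifies how its core-periphery organization
differs between patients and healthy controls (HC).

The three layers are built as follows.

**Morphological covariance (MC).** Regional gray-matter volumes are
regressed on age, sex and total intracranial volume with coefficients
estimated in HC only, and each subject's residuals are standardized by the
HC residual SD (`zscoreVolumes()`). The edge weight between regions $i$
and $j$ is

$$w_{ij} = e^{-(z_i - z_j)^2} \in (0, 1],$$

a measure of shared deviation from the healthy norm: two regions that
deviate identically get weight 1. The diagonal is forced to zero because
self-edges are meaningless for strength or coreness. The residual SD uses
the sample convention (denominator $n-1$), so the fitting sample has z
mean 0 and SD 1 exactly.

**Structural connectivity (SC).** Streamline-weight matrices are
compressed with $w = \log_{10}(1 + w_{\text{raw}})$. The raw transform
$\log_{10}(w)$ is undefined at zero and negative below 1; adding 1
preserves zeros, nonnegativity and the rank order of edges while still
equalizing magnitudes across edges spanning several orders of magnitude.

**Functional connectivity (FC).** Pearson correlations of regional BOLD
signals are Fisher z-transformed and absolutized, $w = |\operatorname{atanh}(r)|$,
since anticorrelations may carry relevant coupling information.

Before assembly each layer is divided by its largest singular value
(`svdNormalize()`), so all layers enter the multiplex with spectral norm 1.
This corrects for differences in average link weight across modalities;
among the possible spectrum-based normalizations we implement division by
the top singular value only, which preserves within-layer edge rank order.

## Coreness and the disruption index

For every density $d$ in a grid (default $0.01, 0.02, \ldots, 1.00$), each
layer is *independently* filtered by keeping its
$m = \operatorname{round}(d\,N(N-1)/2)$ strongest edges, weights retained
(`thresholdLayer()`). Multiplex richness is then

$$\mu_i = \sum_\alpha c_\alpha\, s_i^\alpha,$$

the linear combination of node strengths across filtered layers; the
coefficients default to $c = (0.5, 0.5, 0.5)$, treating all modalities as
equally informative. Nodes are ranked by decreasing $\mu$, and
$\mu_i^+$ restricts each strength to neighbours ranked above $i$. The
*rich core* is the set of nodes up to the rank where $\mu^+$ peaks
(`richCore()`). **Coreness** is the fraction of explored densities at
which a node belongs to the core — a value in $[0, 1]$ that is an exact
multiple of one over the number of thresholds.

Ties are resolved deterministically: equal richness by ascending node
index, equal boundary $\mu^+$ by the smallest rank (smallest core), and
equal edge weights at the threshold cutoff by ascending $(i, j)$
lexicographic order. An empty filtered graph yields an empty core.

The **coreness disruption index** $\kappa$ is the OLS slope (with
intercept) of $\Delta_i = c_i^{\text{subj}} - c_i^{\text{HC}}$ on the HC
mean coreness $c_i^{\text{HC}}$ (`disruptionIndex()`). A subject
identical to the reference has $\kappa = 0$; losing all coreness gives
$\kappa = -1$. Negative slopes mean hubs lose disproportionately — the
signature of a *targeted attack* on central network elements.
Individual-level $\kappa$ compares each subject to the HC mean; the
group-level index regresses the group-mean coreness
(`groupDisruptionIndex()`). Single-layer $\kappa$ (MC, SC, FC) uses the
same sweep on one layer with unit coefficient.

$\kappa$ is computed on raw coreness and adjusted for confounders
afterwards; the HC reference is likewise the raw HC mean. This is one
consistent ordering of adjustment and reference construction; adjusting
coreness first would be an alternative.

## Harmonization

Multi-site data carry additive and multiplicative scanner effects.
`combatHarmonize()` implements the standard empirical-Bayes location/scale
model: features are standardized by a grand model containing site
indicators and the biological covariates to preserve (age, sex, disease
group), per-site per-feature location and scale are estimated and shrunk
across features with parametric priors (normal/inverse-gamma,
method-of-moments hyperparameters, iterative conditional solution), then
removed. A single site is an identity transform; sites with one subject
and confounded designs are hard errors; zero-variance features pass
through untouched. Harmonization is applied to raw volumes (before
z-scoring, so the MC layer inherits it) and to the *transformed* SC/FC
edge vectors before spectral normalization; harmonized edge weights are
clamped at zero. Whether one harmonizes raw or transformed connectivity
is an open choice; harmonizing on the transformed scale matches where the
location/scale model is most plausible.

## Group statistics

Confounders (age, sex) are removed from $\kappa$ and nodal coreness by
nuisance regression with weights estimated in HC only — fitting in the
pooled sample would absorb disease-related variance. Individual z-scores
are (corrected value − HC mean of corrected values) / HC SD of corrected
values.

Group differences use two-sided permutation t tests (pooled-variance t;
exhaustive enumeration when at most 20,000 label arrangements exist,
otherwise Monte Carlo with the $(b + 1)/(B + 1)$ convention so p-values
are never zero; default $B = 10{,}000$). Nodal comparisons share one
label reshuffle across nodes per permutation, preserving cross-node
dependence, and are corrected with Benjamini-Hochberg FDR within the node
family. Effect sizes are Hedges' g (pooled-SD Cohen's d times
$J = 1 - 3/(4n - 9)$) with percentile bootstrap CIs over per-group
resampling (default 5000 resamples; the bootstrap flavour is a choice,
the resample count is not). Phenotype effects use one-way ANOVA with
Tukey HSD post hoc tests. Clinical dichotomies follow the conventional
cutoffs: EDSS $\ge 4$ (inclusive) for high physical disability and SDMT
z-score $< -1.5$ (strict) for impaired information processing speed;
subjects missing a score are excluded from that comparison only
(complete-case per analysis).

## Prediction

`fitBaggedTrees()` combines decision-tree learners with bootstrap
aggregation (a random-forest ensemble), tuning features-per-split and
minimum node size by a seeded search that minimizes 10-fold
cross-validated classification error. We use a seeded grid/random search
rather than Bayesian optimization: the objective is preserved and the
search is exactly reproducible. Performance is out-of-bag accuracy (each
sample scored only by trees whose bootstrap excluded it), and predictor
relevance is OOB permutation feature importance: a feature's column is
permuted and the mean OOB accuracy drop over repeats reported with its
SD. Permutation is applied to the whole column and evaluated through
each sample's out-of-bag trees — asymptotically equivalent to permuting
within each tree's OOB subset and far cheaper. Features per task: the
four $\kappa$ domains (multiplex, MC, SC, FC), age/sex-adjusted brain
parenchymal fraction z (HC-anchored), and $\log(1+\text{TLV})$ — total
lesion volume is log-transformed because lesion loads are heavily
right-skewed. Controls enter the disease-status task with TLV 0 (they
have no MS lesions); the disability and IPS tasks use patients only,
labeled by the dichotomies above.

## The synthetic cohort generator

No patient-level data can be redistributed, so `simulateCohort()` plants
the structure the analysis assumes and reports the ground truth
(`SyntheticTruth`) for recovery testing:

* a core-periphery multiplex with block mean weights
  $w_{cc} > w_{cp} > w_{pp}$ (defaults 1 / 0.35 / 0.08; SC blocks are
  gamma-distributed around these scaled by 50, FC is generated directly in
  Fisher-z space and mapped through tanh so correlations stay inside
  $(-1, 1)$ — no time series are simulated because nothing downstream
  needs them);
* regional volumes linear in age, sex and TIV (slopes $-0.02$ ml/yr,
  $+0.3$ ml, $+0.004$ ml/ml) plus node noise;
* a targeted hub attack: every edge $(i, j)$ is multiplied by
  $1 - \delta \max(a_i, a_j)$, with core affinities $a_i \in [0.8, 1]$ and
  attack strength $\delta = 0$ for HC and phenotype-graded for patients
  (mean 0.15 CIS, 0.30 RRMS, 0.55 SPMS, 0.45 PPMS, SD 0.08) — the
  multiplicative max-affinity form is one concrete instantiation of
  centrality-targeted damage;
* clinical scores as monotone noisy functions of $\delta$:
  EDSS $= 2 + 5\delta + \mathcal N(0, 0.7)$ clipped to $[0,10]$ and
  rounded to 0.5, SDMT z $= -2.5\delta + \mathcal N(0, 0.8)$, BPF
  decreasing and TLV log-linearly increasing in $\delta$. These links are
  stand-ins; only monotonicity and ordering are asserted anywhere;
* per-site effects applied last: per-node volume location offsets and a
  scale factor, multiplicative SC and Fisher-z FC factors — matching the
  location/scale family that harmonization removes.

The generator does **not** emulate spatial autocorrelation, realistic
modular topology beyond the planted core, lesion geometry, or
scanner-specific noise spectra. Passing tests therefore show that the
machinery recovers planted structure under its own generative
assumptions, not that the pipeline is validated on real MRI. Note also
that regional volumes carry no disease effect, so the MC layer is
essentially intact while SC/FC are attacked — mirroring the observation
that morphological networks are comparatively preserved.

## Numerical choices and degenerate inputs

* Density grid 0.01–1.00 in steps of 0.01 (100 thresholds); the full
  density range is explored and the grid step is configurable.
* Strengths are computed on weighted (not binarized) filtered layers.
* The sweep exploits that ascending densities retain nested edge
  prefixes, updating strengths incrementally; rankings and boundaries are
  recomputed per density. Equivalence with the direct
  filter-then-decompose composition is tested explicitly.
* All-zero layers cannot be normalized (hard error: degenerate subject);
  all-zero filtered graphs yield empty cores; constant reference coreness
  makes $\kappa$ undefined (hard error).
* Matrices are symmetrized as $(M + M^\top)/2$ on input, with asymmetries
  above $10^{-6}$ reported; the diagonal is zeroed.
* Every stochastic stage consumes a seed derived from the single
  configuration seed; rerunning a configuration reproduces all outputs
  exactly.

## Problem sizes used in the shipped analyses

The bundled acceptance analysis simulates 80 HC and 200 patients over 114
nodes with 20 core nodes and two sites, sweeps 100 densities, uses 2000
permutations and 2000 bootstrap resamples, and tunes 8 hyperparameter
configurations per prediction task. The test suite uses smaller cohorts
(20–150 subjects, 20–114 nodes) chosen so each check exercises the full
code path at the smallest size where the planted signal is comfortably
detectable.

## A minimal example

```{r example, eval = FALSE}
library(multiplexcore)

res <- runPipeline(list(
  seed = 1,
  simulate = list(nHC = 30, nMS = 60, nNodes = 60, nCore = 12),
  stats = list(nPerm = 2000, nBoot = 1000),
  predict = list(searchBudget = 4)
), outDir = "results")

res$stats$groupKappaMultiplex        # group-level kappa of the MS group
res$stats$global$multiplex$hedgesG   # effect size of the MS vs HC contrast
head(res$kappaTable)                 # per-subject kappa in all four domains
```

## Known limitations

* The generator's constants are stand-ins; absolute effect sizes from
  synthetic cohorts are not comparable to clinical cohorts and only
  qualitative/ordering properties are meaningful.
* Interlayer-link multilayer models, other multiplex metrics
  (participation, clustering) and longitudinal designs are out of scope.
* The exact variant of spectrum-based layer normalization and of the SC
  log transform in upstream tooling varies; the choices here (spectral
  norm 1; $\log_{10}(1+w)$) are documented above and fixed.
* EDSS and SDMT dichotomies inherit the usual clinimetric weaknesses of
  those instruments; missingness is handled complete-case per comparison.
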
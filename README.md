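# multiplexcore

Core-periphery analysis of multimodal multiplex brain networks, for
network-neuroscience researchers studying how disease reshapes the human
connectome — in particular multiple sclerosis, where damage concentrates
on network hubs.

Three connectivity modalities over one parcellation (default 114 regions)
are merged into a multiplex network with one-to-one node correspondence:

* **MC** — morphological covariance: regional gray-matter volumes are
  z-scored against a healthy-control (HC) norm adjusting for age, sex and
  total intracranial volume, and edges weighted
  `w_ij = exp(-(z_i - z_j)^2)`;
* **SC** — structural connectivity: streamline weights, transformed
  `log10(1 + w)`;
* **FC** — functional connectivity: BOLD correlations, transformed
  `|atanh(r)|`.

Each layer is normalized to unit spectral norm. Over a density sweep
(0.01–1.00), each layer is filtered to its strongest edges, multiplex
richness `mu_i = sum_a c_a s_i^a` (equal coefficients 0.5) feeds a
rich-core decomposition, and **coreness** is the fraction of densities at
which a node sits in the core. The **coreness disruption index**

```
kappa = OLS slope of (coreness_subject - coreness_HC) on coreness_HC
```

summarizes global core-periphery weakening: negative values mean hubs
lose coreness disproportionately — a targeted-attack signature.

Around this core the package provides multi-site empirical-Bayes
(ComBat-style) harmonization, HC-anchored confounder adjustment,
permutation t tests with Benjamini-Hochberg FDR across nodes, Hedges' g
with bootstrap CIs, one-way ANOVA with Tukey post hocs, clinical
dichotomies (EDSS >= 4; SDMT z < -1.5), bagged decision-tree prediction
with out-of-bag accuracy and OOB permutation feature importance, and a
synthetic cohort generator that plants a core-periphery multiplex, a
phenotype-graded targeted hub attack, covariate-dependent volumes and
site effects — with the ground truth returned for recovery testing.

## Worked example

```r
library(multiplexcore)

res <- runPipeline(list(
  seed = 7,
  simulate = list(nHC = 20, nMS = 40, nNodes = 60, nCore = 10),
  stats = list(nPerm = 1000, nBoot = 500),
  predict = list(searchBudget = 4, nRepeats = 3),
  logLevel = "quiet"))

res$stats$groupKappaMultiplex
#> [1] -0.07687996
res$stats$global$multiplex$hedgesG
#> [1] 0.6567172
res$stats$global$multiplex$p
#> [1] 0.01998002
```

The simulated patients carry a targeted hub attack, so the group-level
multiplex kappa is negative (-0.077): nodes with high control-group
coreness lose more coreness in patients than peripheral nodes do. The
positive Hedges' g (0.66) is the standardized HC-minus-MS difference in
confounder-adjusted individual kappa z-scores, significant by a two-sided
permutation t test (p = 0.020). `res$kappaTable` holds per-subject kappa
in the multiplex, MC, SC and FC domains; `res$stats$nodal` the per-node
group comparison with BH-corrected p-values; `res$predictions` the OOB
accuracies and feature importances for the disease-status, disability and
IPS-impairment classifiers.

A command-line entry point for the same pipeline is installed at
`inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --config cfg.yaml --seed 1 --out-dir results`).

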
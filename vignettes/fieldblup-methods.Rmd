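---
title: "Models and methods behind fieldblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fieldblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldblup)
```

fieldblup analyses large inbred breeding panels phenotyped once, in a single
non-replicated field trial with repeated check plots, and genotyped on a
dense SNP array. This vignette sets out the models the package fits, the
statistics it derives from them, the numerical choices in the solver, and
what the bundled synthetic-panel generator does and does not emulate.

## The trial mixed models

All analyses start from a plot-level linear mixed model. With `y` the
phenotypes of an `r` rows by `c` ranges trial:

**Baseline model.** `y = X tau + Z u + Z_g g_t + e`, where `tau` holds the
intercept (and optional linear row/range trend covariates), `u` are iid
block effects with variance `sigma2_u`, `g_t ~ N(0, sigma2_t I)` is a total
genetic effect per line mapped to plots by the indicator `Z_g`, and the plot
error follows a separable first-order autoregressive structure,
`e ~ N(0, sigma2 * AR1(rho_r) (x) AR1(rho_c))`. Because test lines are
unreplicated, the repeated checks are what allow `sigma2_t` to be separated
from the spatial error: `fit_baseline()` refuses trials without any
replication.

**Genomic model.** The total genetic effect is partitioned into an additive
component structured by markers and a residual genetic remainder:
`y = X tau + Z u + Z_g (g_a + g_p) + e` with `g_a ~ N(0, sigma2_a G_s)` and
`g_p ~ N(0, sigma2_p I)`. `G_s = M M' / r` is the scaled genomic
relationship matrix with `r = trace(M M') / n`, so the average
self-relationship is exactly 1. `M` is the allele-code matrix (homozygotes
-1/+1, residual heterozygotes 0) and is deliberately *not* column-centred:
the raw cross-product is the panel's definition, and a VanRaden-style
centred GRM is available as an option (`build_grm(center = TRUE)`). This
genotype-level formulation is the computational twin of a marker-effects
model with `g_m ~ N(0, (sigma2_a / r) I)`; the two give identical restricted
likelihoods and identical additive values (the equivalence is asserted to
`1e-6` in the test suite).

**QTL model.** Selected markers enter the baseline structure as fixed
covariates, `y = Z_g M_j beta_j + X tau + Z u + Z_g g_p + e`, the genetic
term reduced to the residual effect since the markers absorb the QTL-linked
variation. Line genetic values are `M_j beta_j`.

Heritabilities follow the variance-component conventions for these models:
`H2 = sigma2_t / (sigma2_t + sigma2)` with `sigma2_t = sigma2_a + sigma2_p`
for the genomic fit, `h2 = sigma2_a / (sigma2_t + sigma2)`, and the additive
proportion `100 sigma2_a / (sigma2_a + sigma2_p)`. These intentionally
ignore block variance and the spatial correlation, as is conventional for
single-trial plot-basis heritability. Model fit is compared on the REML
log-likelihood; both models carry the same fixed part and the same
constant, so `compare_fits()` reports `delta logL` and the percentage
improvement `100 (logL_g - logL_b) / |logL_b|` on a common scale.

## REML: parameterisation, solver, convergence

The error variance is profiled out analytically, so the optimiser works on
variance *ratios* (`gamma_x = sigma2_x / sigma2`) plus the two AR1
parameters. Evaluation goes through the mixed-model-equation (Woodbury)
identities rather than any dense covariance:

- on a complete grid, `R^-1` is the analytic tridiagonal AR1 inverse,
  assembled as a sparse Kronecker product with an analytic log-determinant;
  incomplete grids (e.g. cross-validation folds, where validation lines'
  plots are removed) fall back to one dense Cholesky of `R` per AR1
  proposal inside the same code path;
- the genetic coefficient block uses the eigendecomposition of `G_s`,
  computed once per GRM and cached, so `gamma_a G_s + gamma_p I` is
  diagonal in rotated coordinates for every candidate point;
- cross-products against `R^-1` are cached per AR1 pair, so the many
  variance-ratio evaluations between spatial updates reuse them.

Maximisation uses bounded quasi-Newton (L-BFGS-B on `log gamma` and
`atanh rho`) followed by a short Nelder-Mead polish, taking the better of
the two; a derivative-free restart covers starts where the quasi-Newton
step fails. We chose this over an average-information update because the
profiled surface is cheap to evaluate at these problem sizes and the
bounded transform handles boundary components (`gamma -> 0`) without
step-halving heuristics; estimates at the lower bound are flagged as
boundary cases in the fit object. Defaults: every variance ratio starts at
1 (equal variance shares), `rho` starts at 0.1, ratios are bounded in
`[1e-8, 1e6]`, `|rho| <= 0.999`, and convergence is judged at `1e-6` on the
log-likelihood. `reml_loglik()` exposes the exact likelihood (same
constant, including the Gaussian normaliser) for external verification;
the test suite holds it equal to a brute-force dense multivariate-normal
computation to `1e-9` on small grids.

BLUPs come from the same solves: `g_a = sigma2_a G_s Z_g' P y` and
`g_p = sigma2_p Z_g' P y`, with the REML projection
`P = H^-1 - H^-1 X (X' H^-1 X)^-1 X' H^-1` never formed densely. (The
variance of `g_a` used below is the variance of the predictor,
`sigma2_a^2 G_s Z_g' P Z_g G_s`.)

## Marker effects, outlier statistics, QTL selection

`backsolve_marker_effects()` converts additive values to per-marker effects
`g_m = M' G_s^-1 g_a` (equivalently `sigma2_a M' Z_g' P y`), with
per-marker variances from the diagonal of `M' G_s^-1 var(g_a) G_s^-1 M`,
and the outlier statistic `t_k = g_m_k^2 / var(g_m_k)`. The algebraic
identity `M g_m = r g_a` holds for every fit and is verified at `1e-6`
relative tolerance. Prediction of unphenotyped lines is the pure product
`M* g_m`; note this reproduces `r` times the additive values of training
lines, a scale that cancels in every correlation-based accuracy.

QTL selection is greedy: repeatedly take the mapped marker with the largest
`t`, then exclude all markers within 25 cM (configurable) on either side on
that chromosome. Ties break to the lowest marker index, making the
selection deterministic; exhaustion can return fewer markers than
requested. The greedy trace is checked against brute-force enumeration on
small instances.

## Cross-validation and the two accuracy definitions

`cross_validate()` partitions lines into five near-equal folds by a seeded
uniform permutation (no stratification). Per fold, the genomic model is
refitted on the training plots only, and validation lines are predicted by
`M g_m`; QTL methods refit `beta_j` on the training fold. Two accuracies
are reported for the pooled validation predictions:

- **additive**: correlation with the full-data genomic model's `g_a` —  a
  pure additive-scale measure;
- **total**: correlation with the full-data baseline model's `g_t`,
  divided by `sqrt(H2)` of the baseline fit — the convention that makes
  results comparable with phenotype-referenced studies.

Whenever the additive proportion is below 1, the total-value accuracy is
systematically the smaller of the two, and across traits it tracks the
additive proportion; both patterns are asserted on synthetic panels.

Two open choices were resolved as follows, both switchable. QTL selection
inside cross-validation defaults to re-selection within each training fold
(`qtl_selection = "fold"`), because fixing the selection from the full data
leaks validation information into the scan; the leaky variant remains
available as `"full"` for comparability with analyses that scanned once.
Spatial parameters are re-estimated in every training fit rather than
frozen from the full-data fit.

## Trait correlations

`genetic_correlations()` correlates BLUP vectors (`g_a` across traits, and
`g_p` across traits) from per-trait genomic fits. These shrinkage-based
estimates are what large-panel studies report; they are not bivariate REML
genetic correlations, which would require joint multi-trait fits the
package deliberately does not attempt. `correlation_summary()` reports the
agreement correlation between the two measures over all trait pairs, mean
absolute correlations, and a same-sign count whose handling of exact zeros
is configurable (`lenient`, the default, counts a zero as agreeing with
anything; `strict` compares `sign()`), since zero entries are genuinely
sign-free.

## Consensus-map scaling, map summaries, LD

Consensus maps merged from multiple bi-parental linkage maps inflate group
lengths. `scale_linkage_group()` minimises the population-size-weighted
squared deviation between scaled consensus positions and component-map
positions of shared markers. The profiled form follows the published
recipe - `R_j = D_bar / D_c` with the target length `D_bar` profiled over a
window "in the vicinity of" the mean component length - which we make
concrete as +/-20% around the weight-averaged mean component-group length
on a 1001-point grid; the closed-form weighted-least-squares minimiser is
computed alongside, and the profiled factor is required (in tests) to land
within one grid step of it. The window and resolution are conservative,
reproducible choices; any optimum outside the window would indicate the
window assumption itself is violated.

`summarize_map()` reports marker counts, unique map positions, markers per
position, genetic length, and the mean interval `length / (positions - 1)`;
aggregates pool lengths and interval counts across chromosomes rather than
averaging the per-chromosome ratios. `ld_r2()` computes `r^2` as the
squared Pearson correlation of allele-code columns over pairwise-complete
lines - the natural LD measure for inbred panels, with no phasing - skipping
pairs with fewer than 30 complete lines; `ld_decay_bins()` summarises decay
in 2 cM bins to 20 cM then 10 cM bins (the decay is fast early and flat
late), with Tukey-style whiskers.

## Marker QC and imputation

Markers with minor allele frequency strictly below 1% are dropped before
imputation (heterozygotes count half an allele copy). Markers without a map
position are assigned to the chromosome of their highest-`r^2` mapped
marker, with a floor of `r^2 >= 0.1` below which they stay unassigned.
Imputation is then per chromosome subset (mapped markers plus their
LD-assigned companions; unassigned markers form a final pool), bounding the
distance computations: each missing call is filled with the
inverse-distance-weighted average of the line's calls at the 10 nearest
markers, distance being the root-mean-square difference of standardized
marker columns over pairwise-complete lines. The distance floor `1e-6`
lets duplicate markers dominate their neighbours' average, as they should.
The distance metric and weight function are recorded in the output
metadata because reasonable alternatives exist; the head-to-head test
requires KNN to beat marker-mean imputation on the same mask. Filtering
precedes imputation in `run_pipeline()` (the order used for the real
array); the operations do not commute in general, which is why the order
is fixed rather than configurable.

## The synthetic panel generator

`sim_panel()` exists so every stage is testable without restricted data.
Its defaults emulate the study conditions of a large single-site wheat
panel: ~10,000 inbred lines, 21 chromosomes at ~820 markers each, a
476 x 24 trial with one check per 11 plots. What it emulates:

- **map-driven LD**: founder inbreds are crossed at random, progeny pass
  through Haldane (no-interference) meioses - crossover counts Poisson in
  the map length in Morgans, positions uniform - and selfing halves
  heterozygosity each generation, so `r^2` decays with cM distance and the
  panel contains family structure;
- **trait architectures**: polygenic effects (iid normal, rescaled so the
  realised additive variance matches the target, optionally correlated
  across traits), optional major QTL, and iid residual genetic values;
- **the trial**: range-major plot order, one designated check line
  repeated every 11 plots (the number of distinct check varieties in the
  motivating trial is unpublished; one is the simplest faithful choice and
  checks are modelled as ordinary replicated lines), contiguous blocks,
  and a plot error field drawn *exactly* from the separable AR1 x AR1
  covariance via its Kronecker-structured Cholesky factor - exactness is
  what makes the REML parameter-recovery tests meaningful.

What it does not emulate: genotype-calling artefacts and allele-frequency
ascertainment of real arrays, selection and pedigree structure across
breeding cycles, genotype-by-environment variation, or non-Gaussian trait
scales (several real traits are 1-9 visual scores). Passing tests on this
generator therefore validate the estimation machinery and the internal
consistency of the pipeline, not robustness to those real-data features.

One scale subtlety matters for interpreting recovery tests: because the
generator fixes the *realised* variance of `g_a` while the model parameter
`sigma2_a` refers to `g_a ~ N(0, sigma2_a G_s)` with positive relatedness
in `G_s`, the model-scale truth is `r * var(effects)`, not the realised
variance. The acceptance test compares the REML estimate against that
model-scale truth, exactly computable from the stored simulation truth.

## Problem sizes used in validation

The bundled checks run at sizes a laptop handles in minutes, chosen to be
large enough for the statistics to stabilise: dense-oracle equalities on
grids of 20-25 plots; parameter recovery on 20 panels of 400 lines by 800
markers; cross-validation orderings on 20 panels of 150 lines by 300
markers under fivefold validation; QTL localisation on 50 panels of 100
lines by 160 markers; the near-noiseless prediction check on 500 lines
with 16 founders (the dense family structure that makes near-perfect
prediction of new lines possible at all). The published-table statistics
involve no simulation and recompute in milliseconds.

## Known limitations

- Spatial structure requires plot coordinates on a (possibly incomplete)
  rectangular grid; irregular layouts are handled by the dense path but
  unequal plot spacing is not modelled.
- Heritability standard errors are not computed (no information-matrix
  machinery is exposed).
- The baseline and genomic models share the fixed part by construction;
  automated covariate selection for layout trends is deliberately out of
  scope - callers opt in via `covariates = c("row", "range")`.
- Multi-environment (GxE) analysis, factor-analytic variance structures
  and Bayesian whole-genome regression are out of scope.
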
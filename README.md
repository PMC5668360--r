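# fieldblup

Spatially adjusted genomic prediction for large inbred breeding panels
phenotyped in non-replicated field trials.

Commercial cereal breeding programmes evaluate thousands of candidate
lines at once. Replicating every line is infeasible, so a panel is sown
once on a large grid with repeated check plots, genotyped on a dense SNP
array, and analysed with mixed models that soak up spatial trend while
separating genetic from environmental variation. fieldblup implements that
analysis end to end for breeders and quantitative geneticists: REML mixed
models with separable AR1xAR1 plot error, GBLUP through a trace-scaled
genomic relationship matrix, SNP-effect back-solving and QTL-style marker
selection, cross-validated prediction accuracy under two definitions,
additive/residual genetic trait correlations, consensus-map scaling, LD
decay, and marker QC/imputation — plus a synthetic panel generator so the
whole pipeline is testable without restricted data.

## The models

For plot phenotypes `y` on an r x c trial grid:

- **Baseline**: `y = X tau + Z u + Z_g g_t + e`, with block effects
  `u ~ N(0, sigma2_u I)`, total genetic effects `g_t ~ N(0, sigma2_t I)`
  per line, and spatial error
  `e ~ N(0, sigma2 * AR1(rho_r) (x) AR1(rho_c))`.
- **Genomic**: `g_t` is partitioned as `g_a + g_p` with
  `g_a ~ N(0, sigma2_a G_s)`, `g_p ~ N(0, sigma2_p I)`, where
  `G_s = M M' / r`, `r = trace(M M') / n`, and `M` is the lines x markers
  allele-code matrix (-1/0/+1).
- **QTL**: selected markers `M_j` enter as fixed effects,
  `y = Z_g M_j beta_j + X tau + Z u + Z_g g_p + e`.

Variance components are estimated by REML (profiled likelihood, structured
solves; see the methods vignette). BLUPs follow
`g_a = sigma2_a G_s Z_g' P y`, marker effects back-solve as
`g_m = M' G_s^-1 g_a` with outlier statistics `t_k = g_m_k^2 / var(g_m_k)`,
new lines are predicted by `M* g_m`, and heritabilities are
`H2 = sigma2_t / (sigma2_t + sigma2)` and
`h2 = sigma2_a / (sigma2_t + sigma2)`.

## Worked example

Simulate a 150-line panel (3 chromosomes x 100 SNPs, fivefold check grid),
fit both trial models, scan for QTL, and cross-validate:

```r
library(fieldblup)

cfg <- sim_config(n_lines = 150, n_founders = 10, n_chromosomes = 3,
                  markers_per_chrom = 100, trial_ranges = 15,
                  selfing_generations = 5,
                  trait_specs = list(trait_spec("yield",
                    polygenic_var = 0.6, residual_genetic_var = 0.4,
                    error_var = 0.43, block_var = 0.1,
                    rho_row = 0.4, rho_col = 0.4)),
                  seed = 2024)
pan <- sim_panel(cfg)
grm <- build_grm(pan$geno)

fb <- fit_baseline(pan$trial, "yield")
fg <- fit_genomic(pan$trial, "yield", grm)
compare_fits(fb, fg)
#>   trait logL_baseline logL_genomic delta_logL pct_improvement H2_baseline
#> 1 yield         -242.        -230.       12.3            5.10       0.768
#>   H2_genomic h2_genomic additive_proportion
#> 1      0.871      0.539                61.9
```

Partitioning the genetic variance with the GRM lifts the log-likelihood by
12.3 (a 5.1% improvement) and puts 62% of the genetic variance on the
additive scale — close to the simulated 60%.

```r
eff <- backsolve_marker_effects(fg, pan$geno, grm)
select_qtl(eff, pan$map, n_select = 5)   # 25 cM exclusion window
#>   marker   chrom   pos     t order
#> 1 C2_M0013 C2     18.2  9.04     1
#> 2 C1_M0010 C1     13.6  5.87     2
#> ...

cross_validate(pan$trial, "yield", pan$geno, pan$map, grm = grm,
               k = 5, seed = 2024)
#> 5-fold cross-validation, trait `yield` (seed 2024)
#>   method accuracy_additive accuracy_total n_lines trait
#>  genomic         0.857          0.471         150 yield
#>     qtl1         0.420          0.307         150 yield
#>     qtl5         0.489          0.267         150 yield
```

Genome-wide prediction clearly beats prediction from one or five selected
QTL, and accuracy against additive genetic values exceeds accuracy against
total values whenever part of the genetic variance is non-additive — the
qualitative pattern expected of a polygenic trait. `autoplot()` methods
visualise fits and accuracy tables; `tidy()`/`glance()` return the numbers.

The package also bundles the published summary tables of a 10,375-line
wheat panel evaluation (`ref_model_fits()`, `ref_cv_accuracy()`,
`ref_trait_correlations()`, `ref_map_summary()`) so its summary statistics
can be validated against reported values, e.g.
`correlation_summary(ref_trait_correlations())`.

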
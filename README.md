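# sibige

Estimating **indirect genetic effects (IGEs) of siblings** from polygenic
score (PGS) associations in samples of unrelated individuals, by comparing
individuals without full siblings (**singletons**) against individuals with
siblings (**non-singletons**).

## The idea

An individual's PGS–phenotype association in a population sample mixes
several sources: the direct effect of their own genotype, indirect effects
of relatives' genotypes acting through the shared environment (the index
PGS is correlated with parental and sibling PGS), and confounding such as
population stratification or assortative mating.  Under the additive family
model

```
Y = k_I·G_I + k_M·G_M + k_P·G_P + k_S·Σ G_sib + ε
```

with standardized PGS `G` and random mating (all parent–offspring and
sibling PGS correlations 0.5), the expected OLS slopes of phenotype on own
PGS are

```
β_S  = k_I + 0.5·k_M + 0.5·k_P + C                    (singletons)
β_NS = k_I + 0.5·k_M + 0.5·k_P + N·0.5·k_S + C        (N siblings)
```

A singleton's association cannot contain a sibling IGE, so — if direct
effects, parental IGEs and confounding are homogeneous across strata —

```
2·(β_NS − β_S) = k_S        (one sibling per non-singleton)
```

and likewise twice the per-additional-sibling interaction coefficient
estimates `k_S`: the effect of a 1 SD increase in one sibling's PGS on the
index individual's phenotype.  The package implements this estimator
algebra together with everything needed to study it without restricted
data:

* **Family simulator** — multivariate-normal family PGS under a random
  (`model1_structure()`) or assortative (`model2_structure()`) mating
  correlation structure, phenotype generation, analytic expectations
  (`expected_slope()`, `expected_bias()`).
* **Synthetic cohort generator** — biobank-style index individuals with
  per-trait PGS/phenotypes, sibship sizes, birth order, adoption flags,
  sibling-question missingness and covariates (`cohort_config()`,
  `simulate_cohort()`, `assign_strata()`).
* **PGS construction** — LD-block genotype simulation, marginal GWAS,
  greedy LD clumping (defaults `P < 1e-5`, `r² < 0.001`, 10000 kb) and
  dosage scoring with weight substitution (`ld_clump()`, `score_pgs()`).
* **Estimators** — covariate-adjusted stratified OLS, delta-method
  differences and percent attenuation, sibling-count interaction models
  (linear, quadratic, 6+-sibling exclusion), the ×2 IGE scaling,
  heterogeneity z-tests and group-difference tables.
* **Pipeline** — `run_replication()` chains every analysis and emits a
  reproducible report; a thin CLI lives at `inst/cli/sibige.R`
  (`simulate-families`, `simulate-cohort`, `clump`, `associate`,
  `difference`, `interaction`, `replicate`).

## Worked example

A 100,000-person cohort with a true per-sibling IGE of `k_S = 0.05` on an
educational-attainment-like trait (direct effect 0.23, parental IGEs 0.05):

```r
library(sibige)

cfg <- cohort_config(
  n_individuals = 100000,
  traits = list(ea = effect_params(k_i = 0.23, k_m = 0.05, k_p = 0.05,
                                   k_s = 0.05)),
  seed = 2026)
report <- run_replication(cfg, seed = 2026)
report
#> Singleton/non-singleton replication report
#>   cohort: 98414 analysed (12765 singleton, 84930 non-singleton, 719 missing)
#>   ea attenuation: 19.0% (95% CI 13.4%, 24.6%), p = 2.23e-11
#> Sibling IGE estimate (sibling-count interaction): 0.0463 (se 0.0051), 95% CI (0.0364, 0.0563)
```

Reading the output: adopted individuals (~1.6%) were removed and the
missingness rule left 719 individuals with undetermined singleton status.
The non-singleton PGS slope exceeds the singleton slope by 19% of the
non-singleton estimate because non-singletons' associations absorb their
siblings' IGEs.  The linear sibling-count interaction (6+-sibling outliers
removed), doubled, recovers the generating `k_S = 0.05` as 0.046 (95% CI
0.036, 0.056).  Individual pieces are available too:

```r
report$firstborn$ea$non_firstborn_vs_firstborn
#> Difference (non_firstborn - firstborn): 0.0265 (se 0.0134), 95% CI (0.0002, 0.0528), p = 0.0485

scale_sibling_ige(0.012, se = 0.003)   # scale any interaction coefficient
#> Sibling IGE estimate (coefficient): 0.0240 (se 0.0060), 95% CI (0.0122, 0.0358)

expected_slope(effect_params(0.23, 0.05, 0.05, 0.05), "non_singleton", 2)
#> [1] 0.33
```

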
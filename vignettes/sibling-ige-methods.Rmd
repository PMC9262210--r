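---
title: "Estimating sibling indirect genetic effects from singleton/non-singleton PGS associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sibling indirect genetic effects from singleton/non-singleton PGS associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibige)
```

## The model

Siblings can shape each other's outcomes — an older sibling who goes to
university may pull a younger one along.  Such *indirect genetic effects*
(IGEs) of siblings leave a fingerprint in ordinary population-sample PGS
associations, because an individual's polygenic score is correlated with
their siblings' scores.  `sibige` implements a framework that exploits
individuals *without* siblings as a natural control group.

The generative model for the index individual's phenotype is additive in
the standardized family PGS:

$$Y \;=\; k_I G_I + k_M G_M + k_P G_P + k_S \sum_{j} G_{S_j} + C\,G_I + \epsilon,
\qquad \epsilon \sim N(0, \sigma_\epsilon^2),$$

where $k_I$ is the direct effect, $k_M, k_P$ are parental IGEs, $k_S$ is
the per-sibling IGE (summed over siblings), and $C$ is a confounding term
that acts as an additive shift of the PGS slope — this representation
absorbs stratification- or assortment-type confounding directly into the
regression expectation rather than as a separate variable, which is what
the difference estimator sees in any case.  All effects are in phenotype
units per SD of PGS; $\sigma_\epsilon$ defaults to 1 so the defaults put
effects roughly on a per-phenotype-SD scale.

Under random mating the within-family PGS correlations are 0.5 for every
parent–offspring and sibling pair (`model1_structure()`), giving the
stratified OLS expectations

$$\beta_S = k_I + 0.5 k_M + 0.5 k_P + C, \qquad
\beta_{NS} = k_I + 0.5 k_M + 0.5 k_P + N \cdot 0.5 k_S + C,$$

with $N$ the number of siblings.  With one sibling,
$2(\beta_{NS} - \beta_S) = k_S$; with varying $N$, the coefficient on
$N \times \mathrm{PGS}$ in an interaction model estimates $0.5 k_S$ and is
doubled by `scale_sibling_ige()`.  `expected_slope()` and
`expected_bias()` return these expectations; every estimator in the
package is validated against them by simulation.

Three identifying assumptions, encoded in `expected_bias()`'s
decomposition, are that singletons and non-singletons share (1) direct
effects, (2) parental IGEs, and (3) confounding.  Violations bias the
unscaled difference by $k_{NS,I}-k_{S,I}$, $0.5(k_{NS,M}-k_{S,M}) +
0.5(k_{NS,P}-k_{S,P})$, and $C_{NS}-C_S$ respectively; stratum-specific
`effect_params()` let all of these be simulated.

Assortative mating (`model2_structure()`: spousal correlation 0.2,
parent–offspring and sibling correlations 0.6) inflates every stratified
slope and — more importantly — inflates the *difference*: the sibling term
enters with weight 0.6 rather than 0.5, so $2(\beta_{NS}-\beta_S) =
1.2\,k_S$ under that structure.  The test suite checks this inflation
directionally over 200 replicates.  The assortative matrix is taken as
given rather than derived from an assortment strength; its internal
consistency (whether 0.6 offspring correlations follow from 0.2 spousal
correlation at equilibrium) is deliberately not modelled.

## What the synthetic cohort emulates

`simulate_cohort()` produces index individuals whose phenotypes were
generated inside full simulated families (parents plus siblings drawn from
the mating structure), after which the relatives are discarded — mirroring
a biobank sample of unrelateds.  The defaults encode the study conditions
the framework was designed around:

* **Sibship-size distribution** — 13.2% singletons and 4.9% with six or
  more siblings, the two margins a UK-biobank-scale cohort exhibits; the
  interior masses (`default_sibship_distribution()`) decay roughly
  geometrically, a realism choice since only the margins are pinned down.
* **Adoption rate 0.016** — matching the ~1.6% of such cohorts excluded
  as adopted; `assign_strata()` removes them.
* **Missingness rule** — with probability 0.02 one of the two
  sibling-count questions is unanswered; an individual reporting zero to
  one question and nothing to the other has singleton status set to
  missing (a reported sibling, by contrast, determines non-singleton
  status).  There is no printed margin for this rate; 2% is a plausible
  questionnaire-nonresponse figure.
* **Birth order** — uniform over sibship positions (nothing stronger is
  known), observed for 29% of the cohort by default.  With
  `older_sib_only_ige = TRUE` only older siblings exert $k_S$, making
  firstborns behave like singletons — the mechanism behind the
  firstborn/non-firstborn contrast.
* **Covariates** — sex, birth year and ten principal components are
  independent of the PGS by default, with small additive phenotype
  effects so covariate adjustment is exercised but unbiased.  An optional
  `pc_confounding` mode mixes a shared family ancestry component into all
  family members' PGS and the phenotype, for studying violations of the
  third assumption; its magnitudes are user choices, not estimates.
* **`sibling_ige_cap`** — an optional per-trait cap on how many siblings'
  IGEs accumulate.  A cap of 5 produces the attenuated-large-family
  pattern: a linear interaction that strengthens once 6+-sibling
  individuals are excluded, and a negative quadratic interaction term.

What the generator does *not* emulate: half-siblings, non-random study
participation, generational drift of PGS effects (off by default, as it is
only a named limitation of the design), sibship size covarying with
parental characteristics, and locus-level transmission — PGS are simulated
directly at the score level as exact multivariate normals.  Passing tests
therefore demonstrate that the estimators recover what this generative
family model implies, not that real-cohort complications are absent.

## Estimator conventions

* OLS throughout with classical (homoskedastic) SEs, complete-case
  handling, and normal 95% intervals ($\pm 1.96\,\mathrm{se}$) — at
  biobank-scale $n$ the $t$/normal distinction is immaterial.
* Stratum differences assume zero covariance (non-overlapping samples):
  $\mathrm{se}_\Delta = \sqrt{\mathrm{se}_A^2 + \mathrm{se}_B^2}$.
* Percent attenuation divides the difference *and its CI bounds* by the
  fixed reference point estimate.  This ignores denominator uncertainty
  and is therefore anti-conservative; it is kept because it is the
  convention the difference-of-two-means workflow uses, and it makes the
  attenuation CI an exact affine map of the difference CI.  Attenuation is
  positive when the reference (non-singleton) estimate is larger.
* The firstborn stratum contains non-singletons with no older siblings;
  singletons, though trivially "firstborn", are excluded from both
  birth-order strata so the contrast isolates birth order among people
  who have siblings.
* `scale_sibling_ige()` doubles whatever it is given; it does not try to
  reproduce roundings that arise when published doublings were applied to
  unrounded inputs.
* Group differences use maximum-likelihood (population) variances in the
  two-means SE so a binary share reduces exactly to the two-proportion
  closed form; adjusted comparisons regress on a group indicator with sex
  and age ($2008 - \text{birth year}$, the approximate assessment
  midpoint).

## Numerical choices

* **Sampling** — family PGS are drawn via the Cholesky factor of the
  correlation matrix applied to iid normals: exact, fast, deterministic
  given a seed.  Non-positive-semidefinite matrices are rejected naming
  the offending eigenvalue (tolerance $-10^{-8}$).
* **Seeds** — every stochastic operation takes an explicit seed and
  restores the caller's RNG state; a run-level seed expands to per-stage
  seeds through a fixed integer recurrence kept below $2^{31}$.
* **Clumping tie-breaks** — equal p-values are ordered by chromosome,
  then position, then id; the window is $\pm$`window_kb` on the same
  chromosome; $r^2$ is the squared sample correlation of dosages (the
  only genotype representation present).  A monomorphic variant
  correlates with nothing and is never removed by LD.
* **Degenerate inputs** — zero-variance variants in the marginal GWAS are
  reported with beta 0 and p 1 under a warning; quadratic interaction
  models are rejected when sibling counts never exceed 1; empty strata
  and collinear designs are errors naming the stratum or column.
* **Monte-Carlo tolerances** — simulation assertions use five standard
  errors of the relevant sampling distribution at the generated size.
  Parameter-sweep recoveries (the 0.5 structural weights) hold the family
  draw and error vector fixed across sweep points (common random
  numbers), so the slope-on-parameter regression cancels shared noise and
  isolates the structural weight; for the stratum-difference weight the
  singleton stratum reuses the quad draw's $(M, P, O_1)$ margin — exactly
  the trio correlation structure — with the sibling column unused.
* **Problem sizes** — expectation-recovery runs use 100,000 families per
  point; calibration uses 200 replicates of 20,000 families per stratum
  and the assortative-inflation check 200 × 40,000, sizes at which the
  Monte-Carlo error of the doubled difference (~0.02) resolves the
  quantities of interest; cohort-level pattern checks use 120,000–200,000
  individuals.  The error-variance equality across strata is assumed (it
  is not separately identified by the design).

## Limitations

The difference estimator inherits the framework's sensitivity to
stratum-level heterogeneity: anything that makes direct effects, parental
IGEs or confounding differ between singletons and non-singletons loads
directly onto the estimate, with the weights given above.  Assortative
mating biases it upward by construction.  Stratifying on sibship size is
conditioning on a non-random variable, so collider paths through parental
characteristics can distort both stratum slopes (they cancel in the
difference only if they affect both strata equally).  The synthetic
cohort offers switches for several of these violations but cannot say how
large they are in any real cohort.
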
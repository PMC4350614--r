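---
title: "Methylation age acceleration: models, adjustments, and heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation age acceleration: models, adjustments, and heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methage)
library(dplyr)
```

## The scientific problem

DNA methylation at a modest number of CpG sites predicts chronological age
remarkably well. An "epigenetic clock" is a linear predictor
$\hat{a}_i = \beta_0 + \sum_j \beta_j x_{ij}$ over beta values
$x_{ij} \in [0,1]$, possibly on a transformed age scale. The interesting
quantity is not the prediction itself but its *failure*: the difference
between methylation age and chronological age,
$\Delta_{\text{age}} = m_{\text{age}} - \text{age}$, interpreted as an
index of accelerated biological aging. This package implements the full
analysis chain around that statistic:

1. **clock scoring** from a probes-by-samples beta matrix;
2. **technical adjustment** of $m_{\text{age}}$ and construction of
   $\Delta_{\text{age}}$ and the residual age-acceleration index;
3. **mortality association** via Cox proportional-hazards models, with the
   hazard ratio expressed per 5 years of $\Delta_{\text{age}}$;
4. **pooling** of per-cohort log hazard ratios by inverse-variance
   fixed-effect meta-analysis with a DerSimonian–Laird heterogeneity
   check;
5. **heritability** of $\Delta_{\text{age}}$ in twin-family pedigrees via
   relationship-class intraclass correlations and a restricted-likelihood
   additive variance-component model.

Cohort-scale methylation data are access-controlled, so the package ships
a synthetic-data generator whose statistical structure matches every
assumption the analysis makes; the whole pipeline is exercised end to end
on data with known truth.

## Clock scoring

`apply_clock()` computes, per sample, the intercept plus the weighted sum
of beta values. Two calibration conventions are supported. Blood-trained
clocks (the Hannum type) predict years directly (`transform = "identity"`).
Multi-tissue clocks (the Horvath type) are trained against a log-linear
transform of age,

$$
f(a) = \begin{cases}
\log(a+1) - \log(a_{\text{adult}}+1), & a \le a_{\text{adult}} \\
(a - a_{\text{adult}})/(a_{\text{adult}}+1), & a > a_{\text{adult}},
\end{cases}
$$

with natural logarithms; `apply_clock()` maps the raw score back to years
through the exact inverse (`inverse_horvath()`). The knot
$a_{\text{adult}}$ defaults to 20 years, the standard adult calibration
point, and the transform pair round-trips to below $10^{-10}$.

**Missing probes.** Published clocks are routinely applied to arrays where
a probe or two failed QC. The default policy, `drop_term`, simply omits
the missing terms — clocks of this kind have been scored with 70 of 71
probes and no imputation, and for near-symmetric clocks a dropped term
perturbs the score far less than imputation error would. `mean_impute`
(substitute the probe's mean beta across samples) is offered when
cross-matrix comparability matters more than per-sample fidelity. Every
result carries a per-sample `coverage` so the choice is auditable.

## Adjustments and the two acceleration indices

Technical structure (plate, array, chip position, hybridisation date) is
removed by `adjust_technical()`: all covariates are entered as
fixed-effect factors in an OLS regression of $m_{\text{age}}$, and the
residuals are added back to the mean predicted age. The construction
preserves the grand mean exactly and is idempotent. Aliased factor levels
raise an error rather than being dropped silently — in a batch-adjustment
context a rank-deficient design almost always means mislabelled metadata.
`adjust_cell_counts()` uses the same construction with measured white
blood cell counts entered as numeric covariates (no transformation is
applied to the counts).

Two acceleration indices serve different purposes:

- $\Delta_{\text{age}}$ (`compute_delta_age()`) is the exact difference in
  years and is the quantity modelled against mortality;
- the residual index (`compute_age_acceleration()`) regresses predicted on
  chronological age and keeps the residuals, which are uncorrelated with
  age by construction. This is the right index to correlate against
  age-dependent covariates such as naive T-cell abundance, where
  $\Delta_{\text{age}}$'s built-in negative age correlation would induce
  spurious associations.

`cohort_summary()` reports the mean/SD of $m_{\text{age}}$ and
$\Delta_{\text{age}}$, the Pearson correlation with chronological age, and
a median error defined as $\mathrm{median}_i |m_{\text{age},i} -
\text{age}_i|$ — the published cohort tables do not define their "median
error" formally, and this definition matches its printed magnitude
relative to the mean $\Delta_{\text{age}}$. Summaries are computed on the
*adjusted* $m_{\text{age}}$, since that is the analysis quantity.

## Survival association

`fit_cox()` maximises the Cox partial likelihood (through the standard
`survival` engine) and re-expresses the first coefficient — the
$\Delta_{\text{age}}$ term, in years — per 5 years:
$HR_5 = e^{5\hat\beta}$ with Wald interval
$e^{5(\hat\beta \pm 1.96\,\mathrm{se})}$. Efron tie handling is the
default (standard practice and more accurate under ties); Breslow is kept
because its partial likelihood has a convenient closed form for oracle
tests, and the two coincide exactly on tie-free data. P-values are Wald;
with hundreds of events the Wald and likelihood-ratio versions are
indistinguishable in practice.

The proportional-hazards assumption is checked via Schoenfeld residuals
(`schoenfeld_check()`): at each event time the residual is the covariate
of the failing subject minus the risk-set-weighted mean under the fit, and
the diagnostic is the Pearson correlation of residuals with the event-time
rank. At the fitted coefficients the residuals sum to zero (the score
equation), which the tests verify to $10^{-6}$.

Sensitivity tooling mirrors standard epidemiological practice:
`exclude_early_deaths()` drops deaths (never censorings) occurring strictly
before a 2-year window, guarding against reverse causation from terminal
illness at blood draw; deaths at exactly the window boundary are retained.
`km_by_quartile()` produces descriptive product-limit curves by
$\Delta_{\text{age}}$ quartile, using linear-interpolation sample
quantiles with boundary ties assigned to the lower group.

## Meta-analysis

`fixed_effect_meta()` pools per-cohort per-5-year log hazard ratios with
weights $w_i = 1/\mathrm{se}_i^2$. Pooling is always on the per-5-year log
scale; per-year estimates must be rescaled before entry (multiplying both
the log hazard ratio and its standard error by 5, which leaves the Wald
statistic unchanged). The DerSimonian–Laird moment estimator
$\tau^2 = \max\{0, (Q - df)/C\}$ is computed for reporting only — the
fixed-effect model is the reported model, and $\tau^2$ never re-weights
the pooling. The implementation is the closed form itself; the test suite
cross-checks it against an independent meta-analysis package to
$10^{-10}$.

## Heritability in twin-family pedigrees

Clocks track chronological age differently in adults and adolescents, so
before pooling a family phenotype across generations
`standardize_within_generation()` residualizes $\Delta_{\text{age}}$ on
age and sex within parents and within offspring — the offspring model adds
an age$^2$ term for the non-linear adolescent trend — and scales each
generation's residuals to unit variance.

Two estimators then look at the same question from different angles:

- `icc_by_class()` computes, per relationship class (MZ twins, DZ twins,
  full siblings, parent–offspring, spouses), the pair-ANOVA intraclass
  correlation $ICC = (MS_B - MS_W)/(MS_B + MS_W)$. Overlapping candidate
  pairs are first reduced to *pseudo-independent* (disjoint) pairs by a
  seeded random greedy selection (`enumerate_pairs()`, default seed 2015
  so published runs are reproducible). Confidence intervals use the
  Fisher z transform with the disjoint pair count — the natural choice
  when the formula behind a published interval is unstated. Under a purely
  additive model the class ICCs should fall near $h^2 \cdot r$ for
  expected relatedness $r$ (1 for MZ, 0.5 for DZ/sib/parent–offspring, 0
  for spouses), and that pattern is what the simulation tests verify.
- `fit_variance_components()` fits
  $\mathbf{y} \sim N(\mu \mathbf{1},\; V_a \mathbf{A} + V_e \mathbf{I})$
  by REML, where $\mathbf{A}$ is the expected additive relationship
  matrix from `build_relationship_matrix()`. The restricted likelihood is
  profiled over $h^2 = V_a/(V_a + V_e)$ on $[0, 0.999]$: a single
  eigendecomposition of $\mathbf{A}$ diagonalises the covariance for every
  candidate $h^2$, and $\mu$ and the total variance are profiled out in
  closed form, so each evaluation is $O(n)$ after the initial $O(n^3)$
  factorisation (reusable across fits on the same pedigree via the `eig`
  argument). REML rather than ML avoids the downward variance bias from
  estimating the mean. The standard error comes from the numeric curvature
  of the profile restricted log-likelihood at the optimum; because a Wald
  test on a bounded variance ratio and a boundary-corrected
  likelihood-ratio test (50:50 $\chi^2_0/\chi^2_1$ mixture against
  $h^2 = 0$) can disagree near the boundary, both p-values are reported
  and labelled.

Spouse relatedness is fixed at 0 (no inbreeding, no assortative-mating
adjustment) and half-siblings are unsupported; dominance and shared-
environment components (ACE/ADE decompositions) are out of scope.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults emulate the
mortality-cohort design the pipeline targets and are not meant to be tuned
per run:

- **Four cohorts** of sizes 446, 920, 2635, 657 with mean ages 79.1, 69.5,
  66.3, 72.9 and age SDs 0.6, 0.8, 8.9, 6.9 years — two narrow birth
  cohorts and two age-heterogeneous cohorts, matching the published
  cohort descriptives (also recorded in `reference_cohort_table()`).
- **Latent biological age**: $b_i = a_i + g_i + u_i$ with additive genetic
  $g_i$ and environmental $u_i$ components; total SD
  `sigma_delta = 5` years (the printed $\Delta_{\text{age}}$ SDs are
  ~5 years) and heritability `h2 = 0.4` (the published estimate is
  ~0.4).
- **Probes**: `n_probes = 64` clock CpGs with slope signs alternating
  ±1, betas $x_{ij} = \mathrm{clamp}_{[0,1]}(0.5 + s_j (b_i - 70)/200 +
  \varepsilon_{ij})$. The returned "true clock" (weights $200 s_j/m$,
  matching intercept) inverts this construction exactly, so scoring it
  recovers $b_i$ up to noise of SD $200\sigma_\varepsilon/\sqrt{m}$ years.
  The default technical noise `beta_noise_sd = 0.01` is the magnitude of
  Illumina-array technical replicate variation and keeps measurement
  attenuation of the hazard ratio negligible (~0.25 years of m_age
  noise). Clamping to $[0,1]$ introduces a slight, documented bias; a
  warning fires if more than 5% of values clamp.
- **Batch structure**: samples alternate over `batch_levels = 2` plates
  and plates beyond the first shift each probe by
  `batch_offset` $\times\, s_j$ — along the clock's slope direction,
  because a uniform shift would cancel in a sign-balanced clock and make
  the adjustment stage untestable. The default offset 0.01 moves
  $m_{\text{age}}$ by about 2 years, a realistic plate effect.
- **Survival**: death times are exponential with rate
  $\lambda_0 e^{\beta \Delta_i}$ (`lambda0 = 0.07`/year at
  $\Delta = 0$, true $\beta$ = log(1.21)/5 per year by default),
  censored at the minimum of a uniform draw and a 12-year horizon —
  event fractions around 35%, comparable to older-adult cohorts. Any
  proportional-hazards baseline would do; exponential is the simplest.
- **Pedigree**: two-generation families — `n_mz = 67` MZ-twin and
  `n_dz = 111` DZ-twin families, the first `n_extra_sib = 119` of them
  with one extra sibling, both parents always present (the twin-cohort
  composition this emulates reports those class counts; its printed
  117-family total is not internally consistent with them, so the
  generator parameterises family counts directly). Genetic transmission is
  the standard additive model: parents draw independent
  $g \sim N(0, \sigma_g^2)$, offspring receive the mid-parent value plus
  an independent Mendelian deviation $N(0, \sigma_g^2/2)$, MZ co-twins
  share one draw. This yields MZ ICC $= h^2$, DZ/sib ICC $= h^2/2$ and
  parent–offspring covariance $\sigma_g^2/2$ by construction.

Every generator is a pure function of the configuration and master seed
(each one derives its stream by a fixed offset), and
`write_fixture_set()` materialises byte-identical plain-text fixtures with
an MD5 manifest.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: genome-wide array content (only clock
probes are simulated), cell-composition confounding of the clock signal,
covariate-dependent mortality (simulated survival depends only on
$\Delta_{\text{age}}$), familial clustering in the survival cohorts
(subjects are independent, so no robust/clustered variance is needed),
assortative mating, dominance, and shared family environment. Recovery of
the simulated truth demonstrates the estimators' correctness under their
own assumptions, not robustness to their violation.

## Numerical choices and degenerate inputs

- Beta values outside $[0,1]$, duplicate probe/sample IDs, unknown
  transforms, and rank-deficient adjustment designs are hard errors that
  name the offending entry.
- A clock with zero probes present in a matrix is an error; a sample with
  zero observed clock probes gets `NA` m_age with coverage 0.
- Constant chronological age makes the residual-acceleration slope
  unidentifiable and errors; an all-identical ICC input and an identity
  relationship matrix (no related pairs) are likewise rejected.
- The REML profile optimum is located by golden-section/parabolic search
  with tolerance $10^{-7}$ and compared against both boundaries; the
  suite checks it against a dense grid scan to $10^{-3}$.
- Quartile boundaries use type-7 (linear interpolation) quantiles with
  ties going to the lower group.

## Problem sizes used in the checks

The simulation-based checks run at sizes chosen to keep Monte-Carlo error
comfortably inside the tolerances they assert: hazard-ratio recovery uses
50 replicates of four 500-sample cohorts (truth $HR_5 = 1.2$; the
replicate mean and 95% CI coverage are checked), null calibration uses
200 single-cohort replicates at $HR_5 = 1$, and heritability recovery
uses 100 replicates of a 300-family panel at $h^2 = 0.4$ (checking the
mean REML estimate and the MZ $\approx h^2$, DZ $\approx h^2/2$ ICC
pattern). `scripts/acceptance.R` recomputes all of these from scratch at
the same sizes.

## A worked miniature

```{r example}
cfg <- sim_config(n_cohorts = 2, n_per_cohort = c(200, 200),
                  n_mz = 30, n_dz = 40, n_extra_sib = 20, seed = 3)
report <- run_study(cfg)
report$meta$basic
glance(report$heritability$vc)
```

## Known limitations

The package applies clocks; it never trains them, and it bundles no
published coefficient tables (clock files are user-supplied CSV + YAML).
Array preprocessing and QC are upstream concerns. The Cox layer has no
time-varying covariates, competing risks, penalisation, or clustered
variance. The heritability model is strictly additive-plus-residual
(AE); exact numeric parity with pedigree software built on different
variance-component engines is not targeted.
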
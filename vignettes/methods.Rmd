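---
title: "Methods: income inequality, household income, and cortical maturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: income inequality, household income, and cortical maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogini)
```

## The scientific question and the analysis design

Cortical thickness decreases through adolescence, and the steepness of that
decrease is a usable index of brain maturation. The "weak" income-inequality
hypothesis holds that neighborhood inequality harms predominantly the poorer
members of a community. neurogini implements an analysis design built around
that hypothesis:

1. **Neighborhood inequality.** Each census tract's Gini coefficient is
   estimated from the 11 binned household-income counts that census agencies
   publish. Because inequality and overall wealth are entangled, tract Gini
   is residualized on tract mean income, and the residuals are median-split
   into high- and low-inequality tracts.
2. **Household income.** Each adolescent's household income is divided by a
   household-size-specific low-income cut-off (LICO), and the resulting
   income-to-needs ratio is median-split into low- and high-income groups.
3. **Cohort models.** Within each sex, mean cortical thickness is modelled
   with the full factorial of age (months), income group and inequality
   group as fixed effects and a family-level random intercept (siblings are
   nested in families). The three-way age-by-income-by-inequality Wald F is
   the headline test; follow-ups test age-by-inequality within each income
   group, per-subgroup thickness-age slopes with Pearson R², and all six
   pairwise slope contrasts with family-clustered robust errors.
4. **Expression profiles.** Within each of the four subgroups, thickness-age
   correlations are computed per cortical region (34 Desikan-Killiany
   regions, hemispheres averaged upstream), Fisher z-transformed
   (`z = 0.5[ln(1+r) − ln(1−r)]`), stacked across subgroups, and regressed
   on the regional expression of the glucocorticoid receptor gene *NR3C1*
   and androgen receptor gene *AR* with expression-by-income-by-inequality
   interactions and per-subgroup simple fits.

Benjamini–Hochberg FDR control at α = 0.05 is applied within each declared
test family: the three interaction tests per sex for thickness, the three
interaction tests per gene and sex for profiles, and the six slope
contrasts per sex.

## Gini estimation from binned, top-coded income

Census income tables give counts over 11 ordered ranges, the last open
("$100,000 and over"). Two estimators are provided:

- **`lognormal_mle`** (default). A lognormal distribution is fitted by
  maximum likelihood directly on the interval-censored counts (the open
  top bin contributes a right-censored term), and the Gini is the closed
  form `2Φ(σ̂/√2) − 1`. The lognormal is the standard parametric model for
  household income; it handles the open bin without ad-hoc imputation and
  gives a smooth, scale-free estimate. The likelihood is optimized over
  `(μ, log σ)` by Nelder–Mead from midpoint log-moment starting values,
  with bin probabilities floored at 1e-300 to keep the objective finite.
- **`midpoint`**. Every household is placed at its bin midpoint (the open
  top bin at 1.5× its lower edge, the conventional top-code multiplier,
  configurable) and the exact discrete Gini of the resulting point-mass
  distribution is computed from the Lorenz polyline. This estimator is
  exactly equal to the microdata Gini whenever incomes truly sit at bin
  midpoints, which makes it the oracle-comparable channel.

Degenerate inputs are handled explicitly: a single occupied bounded bin
returns Gini 0 with a warning (all incomes equal up to binning); all mass
in the open top bin is an error for the MLE (the scale is unidentified).

**Residualization direction.** The grouping variable is inequality adjusted
for wealth, so the default regresses Gini on mean income and keeps the
residuals ("Gini residuals"). The reverse direction is also implemented
(`direction = "income_on_gini"`) because the verbal description of such
adjustments is often ambiguous; with 37 tracts and a weak Gini-income
correlation the two orderings rarely differ. This was a genuinely open
design choice; Gini-on-income is the default because the residuals are
then in Gini units and are the quantity being split.

**Ties-to-low median split.** `median_split()` sends values strictly above
the median to "high" and everything else to "low". With an odd number of
units the median element itself goes low, so 37 tracts split 19 low / 18
high — the behaviour a reader expects from reported group sizes in designs
like this one.

## Degrees of freedom for the interaction F tests

Every reported interaction test is a Wald F (the squared Wald t of a single
coefficient) with 1 numerator df. The denominator df convention is an
explicit argument:

- `df = "residual"` (default): `n` minus the number of fixed-effect
  coefficients — 8 for the factorial thickness and stacked profile models,
  4 for the two-group follow-ups. This is the statistically conventional
  residual df.
- `df = "printed"`: `n − 2`. Published analyses of this design report
  denominators of that form (e.g. F(1, 402) at n = 404 and F(1, 134) at
  136 stacked profile observations), which cannot be the residual df of an
  8-coefficient model. The option reproduces that reporting convention
  without changing the F statistic itself.

At the sample sizes involved (n ≥ 68) the two conventions change p-values
only in the third decimal; the default favours correctness, the option
favours comparability.

The mixed model is fitted by REML via lme4 with a single family random
intercept. When every family contributes one adolescent the random
intercept is unidentified and the fit falls back to OLS (the two agree on
fixed effects when the family variance is zero). Fixed-effect rank
deficiency and design cells with fewer than 2 participants are errors that
name the offending cell.

**Slope contrasts.** The pairwise comparison of thickness-age slopes pools
two subgroups into `thickness ~ age × subgroup` and uses family-clustered
(CR0) sandwich standard errors for the interaction coefficient. A pooled
interaction model with cluster-robust errors is the standard approach when
the original method is unnamed; it respects the family nesting without
re-estimating variance components in small subgroups.

**Covariate adjustment.** `adjust_thickness()` replaces each thickness
column by the residuals of an OLS on parental education and maternal
smoking, plus the grand mean, so adjusted and raw thickness share a scale.
An optional age² term (with its income and income-by-inequality
interactions) can be added to the factorial model as a sensitivity check.

## The stacked profile regression

The profile models treat the 34 regions as independent observations, as
the design implies (4 × 34 = 136 stacked rows for the three-way model,
2 × 34 = 68 within an income group). No spatial-autocorrelation correction
is applied. This is a known simplification: neighbouring cortical regions
are not independent, and the regional z values within a subgroup share
the same participants. The per-subgroup intercepts in the factorial model
absorb the shared (common-shift) component of that dependence, which is
why the null calibration of the interaction tests holds in simulation, but
the p-values of the per-subgroup simple fits should be read as descriptive.

## What the synthetic generator emulates

`sim_config()` defaults describe the study design the analysis assumes:

| Parameter | Default | Meaning |
|---|---|---|
| `n_tracts` | 37 | census tracts, true Ginis evenly spanning `gini_range` |
| `gini_range` | 0.34–0.56 | observed tract Gini span in such data |
| `n_families` | 323/sex | with `sibling_rate` 0.25 → E[n] ≈ 404 per sex |
| `age_range_months` | 144–216 | uniform ages, 12–18 years |
| `baseline_thickness` | 3.10 mm | mean cortical thickness at age midpoint |
| `residual_sd` | 0.12 mm | within-person residual SD |
| `family_sd` | 0.05 mm | shared family intercept SD |
| `expression_correlation` | 0.75 | inter-gene r across regions |

Tract incomes are lognormal with scale set from the target Gini by the
closed form inverted (`σ = √2 Φ⁻¹((G+1)/2)`), so every tract carries an
*exact microdata Gini* as ground truth alongside its binned counts. Tract
populations are uniform on 2,500–8,000 with households ≈ population/2.4.
Census covariates (density, housing types, tenure) are generated with a
realistic dependence on inequality so that group comparisons have signal.

Per-subgroup thinning slopes are not set directly but derived from target
thickness-age R² values: `slope = −√(R²/(1−R²) · Vn/Va)` with `Vn` the
total noise variance and `Va` the age variance. The default targets are
the observed quartet pattern for females (0.255 / 0.050 / 0.017 / 0.14
for low-high / low-low / high-high / high-low income-inequality cells;
slopes ≈ −0.0037 to −0.0009 mm/month, i.e. 0.01–0.044 mm/year of
thinning, well inside the adolescent range) and a uniform 0.31 for males.
Regional thickness adds fixed regional baselines (SD 0.35 mm) and a
region-specific slope `slope + γ·x_region`, where `x_region` is the
standardized *NR3C1* expression and γ is derived analogously from target
profile R² values (0.41 / 0.003 / 0.18 / 0.36 female; 0.45 / 0.38 / 0.30 /
0.33 male) given the per-region sampling noise `1/√(n_subgroup − 3)` of a
Fisher z. These effect-size parameterizations are simulation defaults
calibrated to reproduce observed R² magnitudes, not claims about
mechanism.

The expression generator produces two region profiles whose *sample*
correlation equals the target exactly (an empirically orthogonalized
Cholesky construction); a `"sample"` method with bounded resampling to a
±0.08 window is available when natural sampling scatter is wanted. The
packaged `inst/extdata/synthetic_region_expression.csv` is such a
synthetic table at r = 0.75; it is a stand-in with the right statistical
shape, not atlas data.

True income groups come from the pooled ties-to-low median split of the
generated income-to-needs ratios and true inequality groups from the
residualized exact Ginis — i.e. the generator applies the same grouping
rules as the analysis, so downstream label recovery is exact for income
and near-exact for inequality (estimation error in the binned Gini can
flip tracts adjacent to the median).

What the generator does **not** emulate: measurement error structure of
real MRI (site, motion), non-uniform age distributions, mixed-sex
families, spatially autocorrelated regional noise, income-inequality
correlations at the tract level, and any probe-level expression
processing. Passing recovery tests on synthetic data therefore shows the
pipeline is correct and calibrated, not that real data meet its
assumptions.

**Median split timing.** The income median split is computed on the
analyzed cohort, after exclusions (missing income or household size,
missing tract), pooled across sexes; a per-sex override exists. Exclusions
are logged with machine-readable reason codes.

## Simulation scale and expected operating characteristics

The shipped checks use problem sizes chosen to characterize the method
well while remaining quick to run: null calibration of the three
interaction tests over 500 generated studies (~300 participants each,
equal slopes, zero expression association), and detection/ranking rates
over 100 studies at the full design scale (37 tracts, ≈ 808 adolescents).
Under the default calibration the three-way thickness and profile
interactions are detected in roughly 80–90% of studies, and the
low-income/high-inequality female subgroup shows the steepest fitted
slope in ≈ 90% of studies.

One operating characteristic deserves emphasis. Whether that subgroup
also shows the *strongest* expression-profile R² in a given study is
dominated by sampling noise: with 34 regions, the standardized separation
between subgroup expression slopes calibrated to R² = 0.41 and R² = 0.36
is only ≈ 0.34, independent of the noise scale (both the slope difference
and its standard error scale with the per-region z noise). The
probability that the 0.41-subgroup ranks first is therefore only ≈ 0.6,
and no honest recalibration of the generator can raise it while holding
the R² quartet fixed. Rank-based summaries of profile strength across
subgroups of this size should not be over-interpreted — in simulation or
in real data.

## Known limitations

- The binned-Gini MLE assumes lognormal incomes; strongly bimodal tract
  distributions would bias it (the midpoint method is the robust check).
- Expression values are consumed as-is (adult donor, left-hemisphere
  atlas values applied to bilateral averages); representativeness is an
  external assumption.
- The profile regressions ignore spatial dependence between regions
  beyond the shared-shift component absorbed by subgroup intercepts.
- The design is cross-sectional: "age-related decrease" is a
  between-person slope, not a within-person trajectory.
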
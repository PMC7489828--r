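---
title: "Methods: excess cardiovascular death risk at census-tract scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: excess cardiovascular death risk at census-tract scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractrisk)
```

## The question the package answers

Small areas differ in cardiovascular (CVD) mortality far more than their
age structure explains. `tractrisk` quantifies that gap at census-tract
scale by contrasting two quantities per tract:

* **expected risk** — the sum, over a semisynthetic individual-level
  population of the tract, of each person's model-predicted probability of
  CVD death over a 4-year window, per 100 000 residents;
* **observed risk** — the directly age-standardized CVD death rate over the
  same 4-year window, applied to the tract population, per 100 000.

The headline statistic is the **difference** (expected minus observed) per
100 000. Negative values mean more deaths occurred than individual-level
risk factors predict — *excess* risk — and the package then asks whether
that excess clusters in space (global Moran's I with a permutation test),
which social and biological determinants it tracks (Bonferroni-corrected
univariate screens, backward-stepwise multivariate OLS, a rank composite),
and how many tracts would leave excess under counterfactual improvements of
those determinants.

## The semisynthetic population

Individual-level data at full-county scale are rarely available, so the
population is *semisynthetic*: individuals are synthesized to match real
aggregate inputs.

1. **Expansion.** Tract demographic marginals (counts per tract, five-year
   age band and sex; the 18 bands `0-4` … `85+`) are expanded into persons.
   Ages are drawn uniformly within a band; the open-ended band spans
   85–100 years. Counts are conserved exactly per cell.
2. **Claims assignment.** Insurer claim counts per tract and condition
   (diabetes, hypertension, hyperlipidemia) are distributed over a
   *claims-covered* subset of each tract's adults — a fraction
   `coverage_fraction` (default 0.8) of adults, since claims data cover
   only part of a population. Exactly `min(count, covered)` covered adults
   are flagged; a count exceeding the covered pool is clipped with a
   warning rather than erroring, because inconsistent administrative inputs
   are common. The claims record is authoritative for covered persons.
3. **Hot-deck imputation.** Biomarkers (systolic blood pressure, total and
   HDL cholesterol), smoking, and the condition flags of uncovered adults
   are copied from a survey donor pool, matched on sex and five-year age
   band, widening to the adjacent bands and then to sex only when a stratum
   is empty. Donors are drawn uniformly with replacement within the
   stratum. With a single donor per stratum, imputation is an identity
   map — the strict oracle used in the tests.

"Adult" means age strictly above 18 throughout: the risk model assigns zero
risk at or below 18, so the same cutoff governs claims eligibility and
donor matching.

## The risk model

Individual 5-year CVD death risk uses a proportional-hazards survival form

\[ r_5 = 1 - S_0(\text{sex}, \text{age band})^{\exp\left(\sum_j \beta_j (x_j - c_j)\right)} \]

with sex- and age-band-specific baseline survival \(S_0 \in (0,1]\) and
centered covariates (defaults: smoking and diabetes flags, systolic blood
pressure centered at 122 mm Hg, total cholesterol centered at 189 mg/dL).
Persons aged 18 or younger receive exactly 0. The default coefficients
shipped by `default_risk_model()` are **synthetic**: the baseline hazard
rises log-linearly with age (about 9%/year, scaled so a typical county
population yields an expected surface near 1400–1500 per 100 000 over 4
years, higher for men); they are placeholders with plausible magnitudes,
not the published values of any specific equation. Analyses of real data
should supply their own model as JSON (`read_risk_model()`).

Risks are rescaled from the 5-year model horizon to the 4-year observation
window with the constant-hazard identity \(r_4 = 1-(1-r_5)^{4/5}\). A
proportional rescaling (\(0.8\,r_5\)) is available via
`scaling = "linear"`; the two agree to first order at small risks and we
default to the hazard form because it is probabilistically coherent at any
risk level.

## Observed rates and the difference

Observed rates use direct age standardization,
\(10^5\sum_b w_b d_b / p_b\), defaulting to the US 2000 standard-million
weights collapsed to the 18 bands (`us2000_standard()`; configurable).
Weights are renormalized over the bands a tract actually populates, which
preserves the standardization identity (equal band rates return that common
rate) in tracts with empty bands. Deaths in a zero-population band are a
data error. The rate is a period rate over the whole 4-year window — no
annualization — matching the period over which individual risks are
summed.

Tracts below `min_population` (default 50) are excluded from the difference
table and listed in an attribute: observed rates in near-empty tracts are
dominated by quantization and disclosure-suppression artifacts.

Calibration of the risk model is checked by OLS of observed on expected
rate: a well-calibrated model yields a slope CI covering 1 and an intercept
CI covering 0.

## Spatial clustering

Contiguity weights are row-standardized; rook adjacency is used for
adjacency lists, and queen contiguity is available where lattice geometry
exists. Islands keep zero rows, are flagged, and are excluded from the
statistic. Global Moran's I is

\[ I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}, \]

tested by random permutation of the values across tracts with pseudo-p
\((1 + \#\{I_{perm} \ge I_{obs}\})/(n_{perm}+1)\) and 999 permutations by
default. Constant surfaces raise an error rather than returning 0.

**Sidedness.** The default alternative is `"greater"` — positive spatial
autocorrelation, i.e. clustering of like values, which is the hypothesis of
interest for an excess-risk surface. The folded convention used by some GIS
software (one-sided toward the observed deviation from \(E[I] = -1/(n-1)\))
is available as `alternative = "folded"`, but it rejects about twice the
nominal rate under an exchangeable null, so it is not the default: with
`"greater"`, a nominal 0.05 cut rejects ~5% of i.i.d. surfaces (the test
suite verifies 3–7% over 500 replicates).

## Determinant regressions

The univariate screen regresses the difference on each determinant
separately and flags significance at `alpha / m`, with `m` the number of
determinants actually screened — with the default table of 20 social
determinants this is 0.05/20 = 0.0025. Multivariate models report per-term
95% CIs, adjusted \(R^2 = 1-(1-R^2)(n-1)/(n-k-1)\) and residual SE;
rank-deficient designs error naming the aliased terms. Backward stepwise
elimination drops the highest-p term above `p_remove = 0.05`, refits, and
stops when all retained terms are significant or one term remains; exact
p ties drop the later term in candidate order (deterministic and
documented). Missing determinant values are handled complete-case per
model.

The rank composite ranks tracts 1 (most favorable) to n per determinant,
honoring each determinant's orientation (`favorable_high` for e.g. income,
`favorable_low` for e.g. food-stamp share), with average ranks at ties; the
mean rank across determinants is regressed on the difference. Ranking makes
the composite invariant to monotone transforms of any determinant.

## Counterfactual scenarios

A scenario scales each modified determinant by \(1 \pm \text{magnitude}\)
(relative change, the default — a single fraction applies meaningfully to
both percentages and dollar amounts; a percentage-point mode exists via
`mode = "absolute"`), clamps percentage columns to [0, 100], and applies
special rules last (the shipped improvement scenario lifts high-school
graduation at or above 90% to exactly 100%). Prediction is
residual-preserving (delta method): each tract's baseline difference is
shifted by \(\sum_j \beta_j (x'_j - x_j)\) under the fitted model, so the
unexplained part of each tract's excess persists — scenario counts are
relative to the observed baseline, not to a refit. The scenario summary
counts tracts with strictly negative predicted difference and their
population share.

## The synthetic-data generator and its ground truth

Every input can be generated with a serialized `ground_truth`:

* **Lattice tracts** (`gen_tract_lattice`) — unit squares with rook
  adjacency, a deterministic stand-in for county tract geography.
* **Demographics** (`gen_demographics`) — tract totals Poisson around
  `mean_pop` (default 3414, a typical county mean tract size), allocated
  multinomially over bands × sex. The default band weights follow a large
  US county age pyramid; default male share 47.6%.
* **Survey pool** (`gen_survey_pool`) — adult donors with biomarkers
  drifting mildly in age and sex around means of 122 mm Hg SBP, 189 mg/dL
  total cholesterol, 52 mg/dL HDL-C, and condition prevalences rising with
  age on the logit scale.
* **Claims** (`gen_claims`) — binomial draws over each tract's
  claims-eligible adults (bands 20-24 and older; the 15-19 band straddles
  the eligibility boundary and is left out of the claims denominator).
* **Determinants** (`gen_determinants`) — independent Gaussian fields per
  determinant, smoothed one step over rook neighbors with weight
  `spatial_rho` (default 0.5), rescaled to target means/SDs and clamped to
  plausible ranges. Smoothing correlates a determinant across space but
  not with other determinants.
* **Observed deaths** (`gen_observed_deaths`) — the generator *inverts* the
  analysis: the planted difference is
  `intercept + effects · determinants + N(0, noise_sd)` per 100 000, the
  implied observed rate is `expected - difference` floored at 0, and
  deaths are spread over age bands at a common band rate so direct
  standardization recovers the planted rate exactly.

The default truth plants effects on food-stamp share, joblessness,
high-school graduation and median income with `noise_sd` 300 per 100 000,
giving a difference SD near 420 per 100 000 — comparable to what county
analyses report. The `intercept` (default −1980) centers the planted
difference near −40 per 100 000 over the default determinant means so that
roughly half the tracts land in excess; without a level term the planted
predictor would push observed rates onto the zero floor. When you change
the effects, re-center the intercept accordingly.

**Death-count realization.** Band death counts are integer-rounded by
default (`realization = "rounded"`). Fractional counts
(`realization = "fractional"`) keep the planted structure exact and are the
natural choice for noiseless configurations, where "zero noise" should mean
exactly that; a stochastic binomial realization is also available. At
realistic tract sizes (≈2000+ residents) rounding contributes rate noise
well under the planted noise; at very small `mean_pop` (a few hundred)
band-level quantization dominates and regression inference degrades — real
small-area analyses face the same small-count instability, which is one
reason the pipeline excludes tiny tracts.

**What the generator does not emulate:** household/school/workplace
structure, survey design weights, race/ethnicity covariates, correlation
*between* determinants (real social determinants are strongly
intercorrelated, which is why stepwise selection on real data is far less
stable than on generated data), migration, and secular mortality trends.
Passing recovery tests on generated data therefore demonstrates the
statistical machinery, not that any particular real county behaves this
way.

## Numerical and design choices

* All generators are pure functions of (parameters, seed); a scoped-RNG
  helper restores the caller's random state, and a master seed derives
  per-stage sub-seeds.
* OLS fits are delegated to `stats::lm`; the test suite checks every fit
  against a hand-coded normal-equations + t-inference oracle to 1e-10.
* Moran's I is checked against a brute-force \(O(n^2)\) double sum to
  1e-12; the permutation pseudo-p floors at \(1/(n_{perm}+1)\).
* Degenerate inputs error early with classed conditions
  (`tractrisk_argument_error`, `tractrisk_data_error`,
  `tractrisk_config_error`, `tractrisk_stat_error`); pipeline stages prefix
  errors with the stage name.
* Problem sizes: the test suite exercises lattices from 1×2 up to 10×10
  with tract populations of 150–2000 (200 recovery replicates, 500
  permutation-calibration replicates), and the acceptance script runs a
  full 18×19 = 342-tract county at mean tract population 3414 (~1.2M
  persons), mirroring a mid-size US county.

## Known limitations

* The default risk model is synthetic; conclusions about any real place
  require a published, locally calibrated equation.
* The delta-method counterfactual assumes the fitted associations are
  transportable to the modified determinant levels and ignores coefficient
  uncertainty in the scenario counts.
* Global Moran's I only; local cluster statistics (LISA) are future work.
* Determinant regressions are associational; nothing here identifies
  causal effects of improving a determinant.
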
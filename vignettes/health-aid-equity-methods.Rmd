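---
title: "Wealth-stratified under-5 mortality and health aid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wealth-stratified under-5 mortality and health aid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aidequity)
```

## The question the package addresses

Development assistance for health ("health aid") grew rapidly after 2000,
and under-5 mortality in recipient countries fell over the same period. The
question this package operationalises is distributional: did the mortality
declines associated with health aid accrue *preferentially to the poorest
households*, or did aid mostly benefit the better-off? Answering it requires
three ingredients that the package implements end to end:

1. **Mortality estimation by wealth stratum.** Under-5 mortality rates per
   country, calendar year and wealth quintile, estimated from complete birth
   histories (the month of birth, survival status and age at death in months
   for every live birth reported by surveyed women).
2. **A pooled absolute wealth index.** Household surveys normally rank
   households *within* each survey; comparing the "poorest fifth" across
   countries requires a single asset-based index fitted to all households
   pooled, so that quintile 5 means the same (absolutely) poor stratum
   everywhere.
3. **Two-way fixed-effects interaction regressions.** With country-year-
   quintile mortality cells joined to a country-year panel of aid per capita
   and covariates, the effect of interest is the *interaction* of lagged aid
   with wealth quintile: how much more (or less) a dollar of aid is
   associated with mortality change among the poor than among the
   wealthiest.

Because the microdata that motivate this design are access-controlled, the
package ships a synthetic-data generator with known ground truth; every
stage is tested by parameter recovery rather than by re-downloading data.

## Data model and month arithmetic

Calendar months are integers since January 1900 (`cmc()`, the DHS
century-month-code convention). The recall window is the 120 months
preceding the interview month. Exposure counts *full months lived*: a child
contributes month $m$ when

$$b \le m < \min(b + 60,\; d,\; v), \qquad m \ge v - 120,$$

where $b$ is the birth month, $d = b + \text{age at death}$ the death month
and $v$ the interview month. Two conventions are required where the data are
month-granular and no finer information exists, and the package fixes them
once:

* the interview month itself contributes no exposure (the partial month is
  discarded), and
* the death month contributes no exposure (death at month start); the death
  event is counted in the calendar year containing $d$, provided $d$ lies
  inside the window and before the interview.

Exposure months are bucketed by their own calendar year; no mid-year
allocation rule is needed. The per-cell mortality rate is
$1000 \cdot \text{deaths}/\text{child-years}$ with survey-weighted numerator
and denominator, which makes rates invariant to rescaling all weights. When
two surveys from one country overlap in calendar time the cells pool the
children (weighted union), preserving the deaths/exposure definition; cells
with zero exposure are omitted. Records claiming an age at death of 60
months or more violate the under-5 definition and are rejected (or dropped
with a message under `on_invalid = "drop"`).

The maternal-education covariate $E_{cq}$ is the survey-weighted median of
mothers' schooling years per country and quintile, held constant over that
stratum's years. A time-invariant $E_{cq}$ is the cleanest reading of a
per-stratum education level and avoids ill-defined per-year medians when
overlapping surveys are pooled; at an exact 50/50 weight split the lower
middle value is taken, so medians are deterministic.

## The pooled wealth index

`wealth_index()` fits the first principal component of eleven standardized
asset/service indicators (ten binary: improved water and sanitation,
finished floor, electricity, radio, television, phone, refrigerator,
motorcycle, car; one continuous: rooms per person). Three constructions
distinguish it from a plain PCA:

* **Weighting.** All moments — means, SDs, the covariance matrix, quantile
  cutpoints — use household weights, by default each survey's share of its
  national population, so a single very large survey cannot dominate the
  pooled index. Weighted moments use the sum-of-weights divisor, which makes
  integer weights exactly equivalent to row replication (a property the
  tests exploit).
* **Year effects.** Weighted per-survey-year means of each standardized
  variable are removed before the eigen-decomposition, absorbing common
  drift in asset ownership over the survey period (ownership of phones, for
  instance, rises everywhere over time for reasons unrelated to a
  household's relative wealth). Residualizing before the decomposition is
  the simplest construction with this effect; including year dummies as
  extra PCA columns was the alternative considered, and the choice is
  recorded here as the package's own.
* **Sign and cutpoints.** The leading eigenvector is sign-normalized so the
  score increases with wealth (anchored on the electricity loading), and
  quintile cutpoints are the weighted 20/40/60/80 percentiles of the fitted
  scores under a step-CDF quantile definition: the cutpoint is the smallest
  observed score whose cumulative weight share reaches the target. A score
  exactly at a cutpoint is assigned to the poorer quintile. Both choices
  make assignment deterministic under ties.

Quintile labels follow the reference convention throughout the package:
**1 = wealthiest (reference stratum), 5 = poorest**. Scoring unseen
households standardizes with the stored means/SDs and subtracts the stored
year effect (unseen years receive no adjustment); households missing any
index variable are excluded with a logged count, since the analysis is
defined for complete-information households. Standardization absorbs affine
rescaling of any input, so measuring rooms per person in different units
cannot change anyone's quintile.

## The two-way fixed-effects interaction model

For mortality rate $M_{ctq}$ in country $c$, year $t$, quintile $q$:

$$M_{ctq} = \beta_q + \gamma A_{c,t-\ell} + \delta_q A_{c,t-\ell}
  + \theta E_{cq} + \phi G_{ct} + \psi U_{ct} + \alpha_c + \tau_t
  + \varepsilon_{ctq},$$

with quintile dummies $\beta_q$ (reference $q=1$), aid per capita $A$
lagged $\ell$ years (default 1), government health spending per capita $G$,
urban population share $U$ (percent), and country and year fixed effects.
$\gamma$ is the naïve association of aid with mortality among the
wealthiest; the $\delta_q$ are the quantities of scientific interest.

Implementation choices:

* **Explicit dummies, not demeaning.** At the scales involved (tens of
  countries, about twenty years) absorbing the fixed effects by explicit
  dummy columns is cheap and keeps the full coefficient vector recoverable.
  Equality with the demeaning (within) estimator, and a Frisch–Waugh check
  for the interaction block, are tests rather than options.
* **Cluster-robust covariance.** $V = a\,(X'X)^{-1}\left(\sum_c X_c'\hat
  e_c \hat e_c' X_c\right)(X'X)^{-1}$ with the small-sample factor
  $a = \frac{G}{G-1}\cdot\frac{N-1}{N-K}$ and $t$ inference on $G-1$
  degrees of freedom, where $G$ is the number of country clusters. This is
  the convention of the major econometrics packages for clustered within
  regressions, and it reduces exactly to HC1 when every observation is its
  own cluster — an identity the tests assert against the `sandwich`
  package. Mortality is serially correlated within countries, so clustering
  by country is the appropriate level.
* **The log variant** regresses $\log M_{ctq}$, dropping zero-rate cells
  (no offset shift), so that $100\,\delta_q$ reads as the percent mortality
  difference per aid dollar; `interaction_estimates()` also reports
  $100(e^{\delta_q}-1)$ for the exact reading. The observation count of a
  log fit is therefore the cell count minus the zero-rate cells minus any
  rows lost to lag coverage.
* **Variants.** `variant_sweep()` refits over aid lags 0–3, both outcome
  transforms, both aid series, and an optional lagged-dependent-variable
  term (the previous year's outcome of the same cell, plain OLS); rows
  without a prior-year cell are dropped. Failures are recorded and the
  sweep continues.
* The regression is unweighted by default; survey weights have already been
  consumed at the rate-estimation stage, and exposure weighting of cells is
  available as an option (`exposure_weights = TRUE`) but off by default.
* $R^2$ is the overall coefficient of determination of the dummy-inclusive
  regression.

Rank-deficient designs are an error naming the collinear columns rather
than a silent drop. One practical corollary, which also bit during
development: any covariate that is *additively separable* in country and
year is absorbed exactly by the two-way dummies, so the generator gives
education a country-level multiplier and the covariate series country-
specific trends.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions once; the defaults are the
package's definition of a realistic multi-country survey study and are not
tuned per experiment.

* **Scale.** 30 countries, panel years 1990–2012, two survey waves per
  country (2003 and 2012, interviews in June), 420 households per survey,
  and quintile Poisson fertility means (1.4, 1.7, 2.0, 2.4, 2.6 births per
  household over the window, wealthiest to poorest) giving roughly 51,000
  births. The two waves' 10-year recall windows jointly cover 1993–2012.
  The fertility gradient reproduces the characteristic pattern that
  child-year exposure falls with rising wealth.
* **Wealth and assets.** Latent household wealth is standard normal. Each
  binary asset follows a logistic model in latent wealth with a slope
  constrained non-negative; intercepts and slopes are set so that ownership
  by assigned quintile reproduces the steep gradients seen in pooled survey
  descriptives — electricity near 0% among the poorest and near 100% among
  the wealthiest, cars rare outside the top quintile, radios common
  everywhere. Rooms per person is log-normal with a latent-wealth slope.
* **Mortality.** Baseline monthly hazards per quintile equal the observed
  1993–2000 period rates by quintile (7.9, 13.6, 23.2, 34.3, 36.9 deaths
  per 1,000 child-years, wealthiest to poorest) divided by 12,000 — the
  rate-to-monthly-hazard conversion used throughout. Survival is simulated
  month by month (a Bernoulli draw per lived month), which makes the
  exposure arithmetic exactly testable: with constant monthly hazard $h$
  and no aid effect, the aggregate rate converges to $12{,}000\,h$ per
  1,000 child-years.
* **Aid and its effect.** Each aid series is
  $\max(0, \text{level}_c + \text{slope}_c \cdot \max(0, t - 2000) +
  \text{noise})$: flat through the 1990s, then country-specific growth,
  mirroring the post-2000 scale-up. Total aid reaches roughly \$10–25 per
  capita by 2012 across countries; malaria-specific aid is several-fold
  smaller. Aid enters the hazard with a one-year lag — the same lag the
  default estimator uses, so the generator truth and the estimand align.
  In the linear mode the per-dollar effect $(\gamma + \delta_q)$ adds to
  the rate before conversion; in the log mode it multiplies the hazard.
  Default truths are the published linear and semi-elasticity coefficient
  columns for total and malaria aid.
* **Covariates.** Education medians per quintile (8 down to 1.5 years) with
  a country-level log-normal multiplier; government health spending and
  urbanization follow country-specific linear trends with no noise by
  default, so covariate noise never contaminates recovery experiments.
  Covariate effects on mortality default to the published point estimates.
* **Weights.** Survey weights are i.i.d. log-normal around 1 — the
  within-country cluster sampling design of real surveys is deliberately
  *not* modelled, and the population-share weight is a simulated national
  population share.

Not emulated, hence outside what passing tests demonstrate: HIV-specific
mortality dynamics, recall and survivorship bias in birth histories,
survey non-response, multi-birth correlation beyond the shared household,
and spatial clustering of sampling. The generator's quintile for the hazard
is the *latent-wealth* quintile, while the analysis recomputes quintiles
from assets — deliberately, so that wealth-index misclassification is part
of the exercised pipeline.

## Problem sizes and numerical behaviour of the experiments

Three facts shape the recovery experiments; all are visible in the test
suite and acceptance script rather than asserted here.

* **Linear recovery.** At the default scale (~51k births, ~3,000 cells,
  about 60 child-years per cell) a single replicate estimates
  $\delta_5$ with a Monte-Carlo SD of roughly 0.4 rate units, so
  experiments average replicates: the suite runs 50, the acceptance script
  more, because the precision of a replicate *mean* is what the comparison
  needs.
* **Quintile misclassification attenuates interactions slightly.** Assigned
  quintiles disagree with latent quintiles for a minority of households
  (adjacent-quintile confusion); because adjacent strata have similar true
  interactions in the linear column, the induced attenuation of
  $\delta_5$ is small but non-zero. It is a property of index-based
  stratification itself, not of the estimator, and would affect a real
  analysis the same way.
* **Log rates need well-filled cells.** $\log$ of a small Poisson count is
  biased ($E[\log D \mid D>0] \ne \log E[D]$, strongly so below a handful
  of expected deaths), and the bias varies with the expected count, which
  distorts slopes — concentrated in the wealthiest (reference) cells where
  deaths are rare. The log-outcome experiment therefore runs at a larger
  scale (16,800 households per survey, ~2M births per replicate), where
  reference-quintile cells carry enough deaths that this distortion is
  second-order. In the log mode the experiment also evaluates the
  estimator against the generator's own strata, isolating the
  log-specification recovery from the (separately exercised)
  misclassification channel, which acts multiplicatively on hazards and
  would otherwise confound the reading of the semi-elasticity.

## Trend smoothing

`smoothed_trends()` produces wealth-stratified trend curves by local
polynomial regression of annual cell rates on calendar year: degree 6 with
an Epanechnikov kernel $w(u) = 0.75(1-u^2)$ for $|u|<1$ by default, with
pointwise bands from the linear-smoother variance under a per-quintile
residual variance estimate. The bandwidth is not a quantity with a
canonical value, so the default is chosen by leave-one-year-out
cross-validation over a candidate grid (4–20 years); with only ~20 distinct
years a degree-6 fit needs a wide kernel, and quintiles with fewer than
degree + 2 distinct years are skipped with a warning. The smoother
reproduces polynomials up to its degree exactly and returns zero-width
bands on constant data, both asserted in tests.

## Determinism and orchestration

A `sim_config()` plus its seed fully determines every generated table; the
three generator stages use fixed offsets from the configured seed, and the
pipeline writes all tables as UTF-8 tab-separated text with the
configuration echoed as YAML, so identical runs are byte-identical.
`run_pipeline()` executes generate → index → rates → fit → report with each
stage's row counts logged and a failing stage named in the error; a
fixture-only mode re-emits the packaged reference tables (which verify
md5 checksums at load) with their decline arithmetic recomputed. A thin
command-line wrapper over `run_pipeline()` ships in `inst/scripts/`.

## Known limitations

* The index-based quintiles attenuate interaction estimates slightly
  relative to the latent truth (see above); real analyses face the same
  estimand question and cannot observe the gap.
* Clustered inference with ~30 clusters is mildly anti-conservative;
  nominal 95% intervals are expected to cover somewhat below nominal, and
  the recovery tests require at least 85% empirical coverage rather than
  95%.
* The log specification silently conditions on cells with at least one
  death; at small exposures this is a selection on the outcome, which is
  why the package surfaces the log-model observation count and why the log
  experiments run large.
* `period_summary()` reports a missing percent decline when the early
  period rate is zero; zero-exposure cells are omitted rather than
  imputed.
* The generator's aid series, while shaped like the post-2000 scale-up, is
  a two-parameter ramp with noise; it does not model aid bursts, program
  cycles, or donor-switching dynamics.
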
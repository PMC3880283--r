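# aidequity

Has health aid preferentially reduced under-5 mortality among the poorest
households of aid-recipient countries? `aidequity` implements the full
analysis chain needed to ask that question of household-survey microdata —
and, because the motivating microdata (DHS birth histories joined to
country-year aid panels) are access-controlled, it ships a synthetic-data
generator with known ground truth so the whole pipeline is testable by
parameter recovery. It is aimed at epidemiologists and health economists
working with survey-based mortality estimation and panel regression.

## What it computes

**Mortality cells.** Complete birth histories (birth month, survival
status, age at death in months) are converted into survey-weighted under-5
deaths and child-years of exposure per (country, calendar year, wealth
quintile) cell over the 10-year recall window preceding each survey, with
the rate $M_{ctq} = 1000 \cdot \text{deaths} / \text{child-years}$.

**A pooled absolute wealth index.** The first principal component of eleven
standardized household asset/service indicators, fitted to all households
pooled, weighted by each survey's national population share, with per-year
means removed before the eigen-decomposition. Quintile 1 is the wealthiest,
quintile 5 the poorest, everywhere in the package.

**The interaction model.** A two-way fixed-effects regression

$$M_{ctq} = \beta_q + \gamma A_{c,t-1} + \delta_q A_{c,t-1}
  + \theta E_{cq} + \phi G_{ct} + \psi U_{ct} + \alpha_c + \tau_t
  + \varepsilon_{ctq}$$

with lagged aid per capita $A$, maternal education $E$, government health
spending $G$, urbanization $U$, country and year fixed effects, and
standard errors clustered by country (small-sample factor
$\frac{G}{G-1}\frac{N-1}{N-K}$, $t$ inference on $G-1$ df). The
coefficients of interest are the aid-by-quintile interactions $\delta_q$:
how much more a dollar of aid is associated with mortality decline in
quintile $q$ than among the wealthiest. Variants: log outcome
(semi-elasticities), aid lags 0–3, malaria-specific aid, and a
lagged-dependent-variable check.

## Worked example

```r
library(aidequity)

cfg <- sim_config(seed = 42)          # 30 countries, ~51k births
dat <- simulate_survey_data(cfg)

widx <- wealth_index(dat$households)
print(widx)
#> Pooled wealth index (weighted PC1, 25200 households)
#>   explained variance share: 0.375
#>   loadings:
#>      water_improved sanitation_improved      floor_finished         electricity
#>               0.250               0.353               0.333               0.364
#>               radio          television               phone        refrigerator
#>               0.216               0.357               0.297               0.378
#>          motorcycle                 car    rooms_per_person
#>               0.184               0.234               0.274

scored <- predict(widx, dat$households)
cells  <- mortality_cells(dat$births, dat$households, scored)
fit    <- fe_mortality(cells, dat$panel, fe_spec())
print(fit)
#> Two-way FE spec: outcome = rate, total aid lagged 1 year(s)
#> n = 3000 cells, 30 country clusters, R^2 = 0.103
#> Aid x quintile interactions (reference: q1, wealthiest):
#>        Estimate Std. Error t value Pr(>|t|)
#> aid      0.5546     0.3790  1.4635   0.1541
#> aid:q2   0.0963     0.3078  0.3128   0.7567
#> aid:q3  -0.8608     0.2804 -3.0699   0.0046
#> aid:q4  -0.5053     0.3816 -1.3241   0.1958
#> aid:q5  -0.6676     0.2919 -2.2870   0.0297
```

All loadings are positive — every asset indicates wealth — and the index
explains 37% of the pooled asset variance. The generator's ground truth for
the poorest-quintile interaction is $\delta_5 = -0.57$ deaths per 1,000
child-years per aid dollar; this single replicate estimates $-0.67$ with a
clustered SE of $0.29$, i.e. each additional dollar of health aid per
capita is associated with roughly 0.7 fewer deaths per 1,000 child-years
among the poorest relative to the wealthiest. Individual replicates carry
Monte-Carlo noise of this size by design; recovery experiments average
many replicates (`summary(fit)` shows the full coefficient table with
covariates).

Other entry points: `period_summary()` (period rates and declines by
quintile), `variant_sweep()` (lags, log outcome, malaria aid, LDV),
`smoothed_trends()` (local-polynomial trend curves with bands),
`run_pipeline()` (seeded end-to-end run writing delimited outputs), and
`survey_inventory()` / `wealth_descriptives()` (packaged, checksummed
reference tables). A thin CLI wrapper lives at `inst/scripts/pipeline.R`.

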
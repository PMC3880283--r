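Package: aidequity
Title: Wealth-Stratified Under-5 Mortality and Health Aid Panel Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether health aid preferentially reduces
    under-5 mortality among the poorest households in aid-recipient
    countries. Implements survey-weighted under-5 mortality estimation from
    complete birth histories (deaths and child-years of exposure per
    country-year-wealth-quintile cell), a pooled absolute wealth index built
    from household assets by weighted principal components with year
    effects, and two-way (country and year) fixed-effects interaction
    regressions of mortality on wealth quintile by lagged health aid with
    country-clustered robust standard errors, including log-outcome,
    lag-sweep and lagged-dependent-variable variants. A synthetic
    household-survey generator with known wealth gradients and aid-by-wealth
    effects makes the full pipeline testable end to end, and a local
    polynomial smoother produces wealth-stratified mortality trend curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), sandwich, lmtest, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
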
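Package: ancineq
Title: Socio-Economic Inequality Analysis of Antenatal Care Utilisation
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring and decomposing socio-economic inequality in
    the utilisation of eight or more antenatal care (ANC) visits from
    DHS-style household survey data. Provides survey weight derivation and
    multi-country pooling, weighted prevalence cross-tabulations,
    best-subset covariate selection by AIC with variance-inflation-factor
    screening, survey-weighted logistic regression with average marginal
    effects, weighted fractional ranks, concentration curves and
    concentration indices by wealth and education (pooled and per country),
    and an elasticity-based decomposition of the concentration index into
    per-covariate contributions. A synthetic multi-country survey generator
    with a PCA-scored asset wealth index supplies ground-truth fixtures so
    the full pipeline is testable without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
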
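# ancineq

Socio-economic inequality analysis of antenatal care (ANC) utilisation
from DHS-style household surveys, for epidemiologists and health-equity
analysts. The package measures how attendance of **eight or more ANC
visits** (the WHO recommendation) is distributed across household wealth
and maternal education, and decomposes that inequality into the
contributions of individual covariates.

## What it computes

Records ranked by a socio-economic stratifier receive weighted fractional
mid-ranks `r_i`; the **concentration index** of a binary outcome `y` with
weighted mean `μ` is

    C = 2 cov_w(y, r) / μ,        C ∈ [−1, 1]

positive when eight-or-more-visit attendance is concentrated among the
richer / more educated. Linearizing a weighted logistic fit by average
marginal effects `β^m_k`, the index decomposes additively:

    C = Σ_k η_k C_k + residual,   η_k = β^m_k x̄_k / μ,
    C_k = 2 cov_w(x_k, r) / x̄_k

where `η_k` is the elasticity of the outcome to category `k`, `C_k` that
category's own concentration index on the same ranks, and the residual is
defined by closure. Supporting stages: v005-style weight derivation and
population de-normalization for multi-country pooling, complete-case
eligibility filtering, weighted prevalence cross-tabs (Kish-effective-size
CIs), best-subset AIC selection with VIF screening, and per-country
concentration curves/indices. A synthetic multi-country generator with a
PCA-scored asset wealth index provides ground-truth fixtures; restricted
DHS microdata are never required.

## Worked example

```r
library(ancineq)

spec   <- population_spec(n_total = 5000, seed = 1)   # 15-country stated world
survey <- simulate_survey(spec)
pooled <- pool_surveys(filter_eligible(survey),
                       spec$countries[, c("country", "total_pop")])

weighted_prevalence(pooled$anc8, pooled$pooled_weight)
#>     label estimate lower upper    n n_weighted n_eff
#> 1 overall     9.57  8.73  10.5 5000   12840449  4333

rk <- ranked_outcome(pooled$anc8, pooled$wealth_quintile,
                     pooled$pooled_weight, label = "wealth_quintile")
concentration_index(rk)
#> CIX (wealth_quintile, pooled) = 0.2038 (SE 0.0273, p < 0.0001), mu = 0.0957, n = 5000

fit <- fit_weighted_logit(pooled, c("wealth_quintile", "education", "age_band",
                                    "employed", "parity", "residence"))
dec <- decompose_cix(fit, rk)
aggregate_contributions(dec, digits = 2)
#>        age_band       education        employed          parity       residence
#>           -0.22           41.16           -0.04            0.06           20.48
#> wealth_quintile
#>           25.34
```

Reading the output: 9.57% of women in this synthetic pool attend eight or
more visits; the positive, highly significant wealth index (0.204) says
attendance is concentrated among richer households; and of that
inequality, education explains ~41%, wealth itself ~25% and urban/rural
residence ~20%, with a 13% residual — the qualitative pattern the
generator's positive wealth/education gradients encode. `run_pipeline()`
executes the same stages end to end from a single config and writes CSV/
JSON artifacts with an MD5 manifest; a CLI wrapper lives in
`inst/cli/ancineq.R`.

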
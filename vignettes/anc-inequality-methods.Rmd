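---
title: "Measuring and decomposing socio-economic inequality in antenatal care utilisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing socio-economic inequality in antenatal care utilisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancineq)
```

## The problem

The WHO recommends at least eight antenatal care (ANC) contacts per
pregnancy. In multi-country household surveys of the DHS type, attendance
of eight or more visits is strongly graded by household wealth and by
maternal education. `ancineq` implements the full measurement pipeline for
that kind of analysis: survey weighting and pooling, weighted prevalence
tables, covariate selection, survey-weighted logistic regression, and —
the analytical core — concentration curves, concentration indices, and the
elasticity-based decomposition of the index into per-covariate
contributions.

Because the underlying microdata (woman-level DHS recodes) are restricted,
the package ships a synthetic multi-country generator with known ground
truth. Every stage is therefore testable end to end, and the test suite's
claims are claims about the generator's stated world, not about any real
country.

## Survey weights and pooling

DHS stores the women's sampling weight as `v005`, the actual weight times
one million; the per-woman analysis weight is `v005 / 1e6`. For a pooled
multi-country analysis each country's weights are *de-normalized*:

\[ w_i = \frac{v005_i}{10^6} \times
   \frac{\text{women aged 15–49 in the country}}{\text{eligible sample size}} , \]

so country blocks enter pooled estimates in proportion to their female
populations. The national population totals are a required metadata input
(`country_meta`); the package does not attempt to derive them. Eligibility
is a birth in the five years before the survey plus complete observations
on all analysis variables; `filter_eligible()` applies the complete-case
rule and logs per-variable exclusion counts. Because de-normalization
divides by the *eligible* sample size, filtering must precede pooling;
`run_pipeline()` enforces that order.

Clusters and strata are deliberately out of scope: variance estimation
uses the Kish effective sample size \(n_\mathrm{eff} = (\sum w)^2 / \sum w^2\)
for prevalence intervals, and a heteroskedasticity-robust sandwich for the
concentration index. Both understate design effects from clustering; with
the design variables absent this is the standard fallback, and it is
documented rather than hidden.

## Concentration curves and the concentration index

Records are ranked by the stratifier — wealth quintile (poorest to
richest) or education (no education to higher) — in increasing order.
Grouped stratifiers create large tie blocks, so ranks use the weighted
mid-rank of the block:

\[ r_i = \frac{W_{<b} + \tfrac12 W_b}{W}, \]

with \(W_{<b}\) the weight mass strictly below record *i*'s block, \(W_b\)
the block's own mass. This is deterministic and order-invariant, and the
weighted mean of the ranks is exactly one half. The concentration curve
plots cumulative outcome share against cumulative population share over
the blocks; the concentration index is the convenient-covariance form

\[ C = \frac{2\,\mathrm{cov}_w(y, r)}{\mu}, \]

positive when the outcome is concentrated among the higher-ranked. For a
binary outcome \(C\) cannot exceed \(1-\mu\) (up to finite-sample slack);
no Erreygers or Wagstaff rescaling is applied to the headline index,
because the emulated analysis reports the uncorrected index on the
\([-1, 1]\) scale. Both corrected variants are returned as clearly
labelled fields (`wagstaff`, `erreygers`) for sensitivity use.

The standard error comes from the convenient regression: weighted least
squares of \(2\sigma_r^2\, y_i/\mu\) on \(r_i\) has slope exactly \(C\),
and its HC1 sandwich standard error yields the test of \(C = 0\). The test
suite checks its type-I error empirically (nominal 5%, accepted band 3–7%
over 500 null simulations) and the \(1/\sqrt{n}\) scaling of the standard
error. p-values are reported with a `< 0.0001` floor, matching the
reporting style of the emulated tables.

## Regression and marginal effects

`fit_weighted_logit()` is a weighted maximum-likelihood logistic fit
(IRLS via `stats::glm`) with weights normalized to mean one, so
model-based Wald intervals are on the scale of the real sample size;
coefficients are invariant to the weight scale. Covariate selection
mirrors best-subset search by AIC (\(-2\ell + 2k\), ties toward the
smaller group) over caller-supplied candidate groups, with a guarded
exhaustive enumerator (`all_subsets()`); multicollinearity is screened by
VIF on the dummy-coded design.

Decomposing a binary-outcome concentration index requires a linearization
of the regression. The default is the derivative-based average marginal
effect,

\[ \beta^m_k = \beta_k \cdot \overline{p(1-p)}_w , \]

averaged over the estimation sample — the standard choice in the
concentration-index decomposition literature. A weighted linear
probability model (`fit_weighted_lpm()`) is provided as the sensitivity
alternative; under a truly linear outcome model it makes the decomposition
exact, which the tests exploit as an oracle. Derivative AMEs for category
dummies differ from finite-difference (toggle) effects by second-order
curvature terms; the tests bound that gap at 20% relative for the default
world's effect sizes.

## The decomposition

For each non-reference category \(k\):

* elasticity \(\eta_k = \beta^m_k \bar x_k / \mu\);
* covariate concentration index \(C_k = 2\,\mathrm{cov}_w(x_k, r)/\bar x_k\),
  computed on the *same* ranks as the outcome index;
* absolute contribution \(a_k = \eta_k C_k\) and percentage contribution
  \(100\, a_k / C\).

The residual is defined by closure, \(C - \sum_k a_k\), so the additive
identity holds to machine precision on every run; the generalized
concentration index of the regression error is reported alongside as a
diagnostic (`gc_error`), and the two agree exactly under a linear model.
`aggregate_contributions()` sums percentage contributions per variable and
over named variable sets — the arithmetic behind statements like
"education, wealth and residence jointly contribute about a third of the
inequality". The package bundles the published reference decomposition
tables of the emulated 15-country analysis (`reference_decomposition()`)
as fixed *inputs* for that arithmetic; in the published education-ranked
table the value rows are visibly shifted one label against the category
column in several blocks, and the bundled file follows the accompanying
text's category assignments (with one stray duplicated row dropped). Note
the source text is itself inconsistent for one cell (it claims 8.02% for
incomplete secondary while assigning that row's index elsewhere); the
variable-level sums used everywhere are invariant to the shift.

## The synthetic stated world

The generator's defaults are fixed and are not tuned to test outcomes:

* **Countries.** 15 countries, sample shares mirroring the emulated pooled
  analysis (largest 18%, smallest 3.2%), default total 15,000 women at
  desk scale; national female populations set by country-specific sampling
  fractions spread over roughly 1/1500–1/3500 so de-normalization is
  non-trivial.
* **Wealth.** One household per woman; latent affluence standard normal;
  15 binary assets with probability `plogis(0.9 * affluence + offset)`,
  offsets spread over \([-1.5, 1.5]\). The first principal component of
  the standardized asset table, oriented positively and cut into weighted
  quintiles, recovers the affluence ranking (Spearman > 0.8 at
  n = 10,000).
* **Education.** Proportional-odds on affluence, one log-odds per SD by
  default, cutpoints calibrated numerically so the marginal distribution
  matches the stated category shares (42% no education, …, 4.7% higher).
* **Residence.** Urban probability rising in affluence (0.9 log-odds per
  SD), marginal 39.5% urban. Remaining covariates are drawn independently
  from their stated marginal shares — a simplification: real surveys
  correlate media exposure and barriers with wealth, so the generator
  understates those covariates' contributions in the decomposition.
* **Outcome.** Logistic, with published adjusted odds ratios used as
  generating coefficients where available (richest quintile 1.87, higher
  education 5.30, employed 1.69, insurance 0.48, rural 0.60, …). The
  intercept is calibrated by bisection so the weighted prevalence hits the
  9% target.
* **Weights.** Gamma raw weights, mean 10^6, CV 0.3 (a typical DHS
  dispersion); `weight_dispersion = 0` gives the equal-weight limit.
* **Visit counts.** Back-filled uniformly on 8–12 or 0–7 conditional on
  the binary outcome, since only the dichotomy is analyzed.
* **Reproducibility.** Each stage draws from its own stream derived from
  the master seed by fixed offsets, so fixtures are byte-identical under a
  fixed seed and stages can be re-run independently.

What a green test does *not* establish: the generator has no cluster
geometry, no within-household correlation, no item-specific asset
inventories, and independent nuisance covariates, so it validates the
estimators' algebra and calibration, not any substantive claim about real
ANC inequality. The pooled headline quantities of the emulated analysis
(wealth index 0.30, education index 0.33, prevalence 8.9%) depend on the
restricted microdata and are deliberately not acceptance targets; the
default world lands near them (about 0.26, 0.29 and 9.2% at n = 15,000)
but is not tuned to match.

## Numerical choices and degenerate inputs

* Logistic convergence: IRLS tolerance 1e-10, 100 iterations; separation
  detected up front and named.
* Intercept and cutpoint calibrations: bisection/`uniroot` to 1e-10 or
  better on a 2,000-point normal grid.
* Constant stratifiers, zero outcome totals, non-positive weights, empty
  categories, and all-constant asset tables are errors, not silent NAs;
  per-country index groups that fail are skipped with a named warning.
* Quintile ties are kept contiguous (stable sort on the cumulative weight
  scale); prevalence intervals collapse to the point at 0% or 100%.
* Rounding: rendered decomposition tables use 3 decimals, percentages in
  prevalence tables 1 decimal, p-values 4 decimals with the `< 0.0001`
  floor.

## Known limitations

* No design-based (cluster/strata) variance — by scope.
* Derivative AMEs (not finite-difference) linearize the logit; both routes
  are exposed, and they disagree at second order.
* The AIC selection searches caller-supplied candidate groups; the
  original analysis's candidate list is unknown, so the default is a small
  nested ladder plus an exhaustive enumerator under a size cap.
* The Stata-recode reader is not implemented; input is schema-validated
  CSV.
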
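#' Canonical survey variable schema
#'
#' Closed category lists for the woman-level covariates used throughout the
#' pipeline, in their analysis order. The first level of every variable is
#' the reference category for regression and decomposition; the orders of
#' `wealth_quintile` (poorest to richest) and `education` (no education to
#' higher) are the ranking orders used by the inequality module, so they
#' must not be permuted.
#'
#' @return Named list; each element is a character vector of levels.
#' @export
anc_schema <- function() {
  list(
    age_band = c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49"),
    education = c("no education", "incomplete primary", "complete primary",
                  "incomplete secondary", "complete secondary", "higher"),
    employed = c("no", "yes"),
    marital = c("never in union", "married", "cohabiting", "widowed",
                "divorced", "separated"),
    parity = c("one", "two-four", "five or more"),
    insurance = c("no", "yes"),
    media_tv = c("no", "yes"),
    media_radio = c("no", "yes"),
    media_newspaper = c("no", "yes"),
    internet = c("no", "yes"),
    barrier_permission = c("not a big problem", "big problem"),
    barrier_distance = c("not a big problem", "big problem"),
    barrier_money = c("not a big problem", "big problem"),
    barrier_alone = c("not a big problem", "big problem"),
    head_sex = c("male", "female"),
    residence = c("urban", "rural"),
    wealth_quintile = c("poorest", "poorer", "middle", "richer", "richest")
  )
}

# Default marginal category shares used by the synthetic generator. These
# mirror the pooled distribution of a multi-country sub-Saharan DHS sample
# of women with a recent birth (large no-education and rural shares, modest
# insurance and newspaper exposure).
default_category_shares <- function() {
  list(
    age_band = c(0.076, 0.213, 0.252, 0.205, 0.155, 0.074, 0.025),
    education = c(0.420, 0.174, 0.082, 0.205, 0.072, 0.047),
    employed = c(0.368, 0.632),
    marital = c(0.082, 0.719, 0.140, 0.011, 0.019, 0.029),
    parity = c(0.216, 0.487, 0.297),
    insurance = c(0.890, 0.110),
    media_tv = c(0.551, 0.449),
    media_radio = c(0.475, 0.525),
    media_newspaper = c(0.883, 0.117),
    internet = c(0.810, 0.190),
    barrier_permission = c(0.797, 0.203),
    barrier_distance = c(0.638, 0.362),
    barrier_money = c(0.459, 0.541),
    barrier_alone = c(0.784, 0.216),
    head_sex = c(0.809, 0.191),
    residence = c(0.395, 0.605)
  )
}

# Variables eligible as regression covariates (everything except the
# derived outcome and weights).
covariate_names <- function() {
  setdiff(names(anc_schema()), character(0))
}

#' Apply the canonical schema to a raw survey data frame
#'
#' Coerces the categorical columns present in `data` to factors with the
#' canonical level sets, erroring on values outside the closed lists.
#'
#' @param data data frame with survey columns (character or factor).
#' @return `data` with schema columns as factors in canonical order.
#' @export
apply_schema <- function(data) {
  sch <- anc_schema()
  for (v in intersect(names(sch), names(data))) {
    vals <- as.character(data[[v]])
    bad <- setdiff(stats::na.omit(unique(vals)), sch[[v]])
    if (length(bad)) {
      stop(sprintf("column '%s' has values outside its category list: %s",
                   v, paste(bad, collapse = ", ")), call. = FALSE)
    }
    data[[v]] <- factor(vals, levels = sch[[v]])
  }
  data
}
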
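#' Weighted prevalence with a survey-style confidence interval
#'
#' Point estimate is the weighted proportion (in percent). The 95% CI is a
#' Wald interval on the logit scale using the Kish effective sample size
#' `n_eff = (sum w)^2 / sum(w^2)`, the standard choice when design
#' variables (clusters, strata) are unavailable. Degenerate proportions
#' (0 or 1) collapse the interval onto the estimate by convention.
#'
#' @param y binary 0/1 outcome vector.
#' @param w positive weights.
#' @param label optional stratum label.
#' @param conf confidence level (default 0.95).
#' @return one-row data.frame: `label`, `estimate`, `lower`, `upper`
#'   (percent), `n` (unweighted), `n_weighted`, `n_eff`.
#' @export
weighted_prevalence <- function(y, w = rep(1, length(y)), label = "overall",
                                conf = 0.95) {
  check_positive_weights(w)
  stopifnot(length(y) == length(w))
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("y must be binary 0/1 without NAs")
  p <- weighted_mean(y, w)
  n_eff <- sum(w)^2 / sum(w^2)
  if (p <= 0 || p >= 1) {
    lo <- hi <- p
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    lg <- stats::qlogis(p)
    se <- sqrt(1 / (n_eff * p * (1 - p)))
    lo <- plogis(lg - z * se)
    hi <- plogis(lg + z * se)
  }
  data.frame(label = label, estimate = 100 * p, lower = 100 * lo,
             upper = 100 * hi, n = length(y), n_weighted = sum(w),
             n_eff = n_eff, stringsAsFactors = FALSE)
}

#' Weighted cross-tabulation of a binary outcome by a factor
#'
#' One weighted prevalence estimate per category, plus the weighted
#' category share `n (%)`, mirroring a bivariable survey table. Empty
#' levels are reported with zero counts and missing estimates.
#'
#' @param y binary outcome.
#' @param f factor (>= 2 levels) or vector coercible to factor.
#' @param w positive weights.
#' @return data.frame with one row per level: `level`, `n`, `share_pct`,
#'   `estimate`, `lower`, `upper`; the overall estimate is attached as the
#'   `overall` attribute.
#' @export
crosstab <- function(y, f, w = rep(1, length(y))) {
  f <- as.factor(f)
  if (nlevels(droplevels(f)) < 1L) stop("factor has no observed levels")
  check_positive_weights(w)
  rows <- lapply(levels(f), function(lv) {
    i <- which(f == lv)
    if (!length(i)) {
      return(data.frame(level = lv, n = 0L, share_pct = 0,
                        estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, stringsAsFactors = FALSE))
    }
    est <- weighted_prevalence(y[i], w[i], label = lv)
    data.frame(level = lv, n = length(i),
               share_pct = 100 * sum(w[i]) / sum(w),
               estimate = est$estimate, lower = est$lower, upper = est$upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall") <- weighted_prevalence(y, w)
  out
}

#' Bivariable summary table across several variables
#'
#' Stacks [crosstab()] results for each requested variable into one table
#' shaped like a survey bivariable-analysis table.
#'
#' @param data pooled data frame.
#' @param outcome name of the binary outcome column.
#' @param variables character vector of factor columns.
#' @param weights name of the weight column (default `pooled_weight`).
#' @return data.frame with columns `variable`, `level`, `n`, `share_pct`,
#'   `estimate`, `lower`, `upper`.
#' @export
bivariable_table <- function(data, outcome = "anc8",
                             variables = intersect(names(anc_schema()),
                                                   names(data)),
                             weights = "pooled_weight") {
  w <- data[[weights]]
  out <- do.call(rbind, lapply(variables, function(v) {
    ct <- crosstab(data[[outcome]], data[[v]], w)
    cbind(variable = v, ct, stringsAsFactors = FALSE)
  }))
  attr(out, "overall") <- weighted_prevalence(data[[outcome]], w)
  out
}
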
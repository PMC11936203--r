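#' Weighted multivariable binary logistic regression
#'
#' Maximum-likelihood logistic fit with per-record sampling weights,
#' reported as adjusted odds ratios with Wald 95% confidence intervals.
#' Weights are internally rescaled to mean one so the information matrix
#' reflects the actual sample size rather than a population-scale weight
#' total; coefficients are invariant to that rescaling. Perfect separation
#' (a category observed in only one outcome class) is detected up front and
#' reported with the offending category.
#'
#' @param data complete-case data frame.
#' @param variables character vector of covariate column names; the first
#'   level of each factor is the reference category.
#' @param outcome name of the binary 0/1 outcome column (default `anc8`).
#' @param weights name of the weight column, or a numeric vector; default
#'   `pooled_weight` when present, else equal weights.
#' @param conf confidence level for the Wald intervals.
#' @return object of class `anc_logit`: list with `coef`, `se`, `vcov`,
#'   `aor` table (aOR, CI), `loglik`, `aic`, `n`, `mu` (weighted outcome
#'   mean), `fitted`, `model` (the estimation frame), `variables`,
#'   `weights` (normalized).
#' @export
fit_weighted_logit <- function(data, variables, outcome = "anc8",
                               weights = NULL, conf = 0.95) {
  stopifnot(is.data.frame(data), length(variables) >= 1L)
  miss <- setdiff(c(outcome, variables), names(data))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  y <- data[[outcome]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome must be complete and binary 0/1; run filter_eligible() first")
  }
  w <- resolve_weights(data, weights)
  mf <- data[, variables, drop = FALSE]
  if (anyNA(mf)) stop("covariates contain missing values; run filter_eligible() first")
  mf <- droplevels(mf)
  check_separation(y, mf)
  wn <- normalize_weights(w)
  fml <- stats::reformulate(variables, response = outcome)
  est <- cbind(stats::setNames(data.frame(y), outcome), mf)
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = est, weights = wn,
                                     control = stats::glm.control(
                                       epsilon = 1e-10, maxit = 100)))
  if (!fit$converged) stop("weighted logistic regression did not converge")
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("aliased coefficients (perfect collinearity): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  V <- stats::summary.glm(fit)$cov.unscaled
  se <- sqrt(diag(V))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- fit$fitted.values
  ll <- sum(wn * (y * log(p) + (1 - y) * log(1 - p)))
  aor <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se),
    aor = exp(unname(beta)),
    lower = exp(unname(beta) - z * se), upper = exp(unname(beta) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
    stringsAsFactors = FALSE
  )
  structure(
    list(coef = beta, se = se, vcov = V, aor = aor,
         loglik = ll, aic = -2 * ll + 2 * length(beta),
         n = length(y), mu = weighted_mean(y, wn),
         fitted = as.numeric(p), model = mf, outcome = y,
         variables = variables, weights = wn,
         xlevels = fit$xlevels, glm_fit = fit),
    class = "anc_logit"
  )
}

#' Weighted linear probability model
#'
#' Weighted least squares of the outcome on the dummy-coded covariates.
#' Provided as the sensitivity alternative to the logistic fit for the
#' concentration-index decomposition: under a linear model the average
#' marginal effect of a covariate is its coefficient, which makes the
#' elasticity-based decomposition exact (zero residual) when the outcome
#' truly is linear in the covariates.
#'
#' @inheritParams fit_weighted_logit
#' @return object of class `anc_logit` with `family = "lpm"`; usable by
#'   [average_marginal_effects()] and [decompose_cix()].
#' @export
fit_weighted_lpm <- function(data, variables, outcome = "anc8",
                             weights = NULL) {
  stopifnot(is.data.frame(data), length(variables) >= 1L)
  y <- data[[outcome]]
  if (anyNA(y) || !is.numeric(y)) stop("outcome must be numeric and complete")
  w <- resolve_weights(data, weights)
  wn <- normalize_weights(w)
  mf <- droplevels(data[, variables, drop = FALSE])
  if (anyNA(mf)) stop("covariates contain missing values")
  X <- stats::model.matrix(stats::reformulate(variables), data = mf)
  fit <- stats::lm.wfit(X, y, wn)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    stop("aliased coefficients (perfect collinearity): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  fitted <- as.numeric(X %*% beta)
  s2 <- sum(wn * fit$residuals^2) / (length(y) - length(beta))
  V <- s2 * solve(crossprod(X, X * wn))
  structure(
    list(coef = beta, se = sqrt(diag(V)), vcov = V, aor = NULL,
         loglik = NA_real_, aic = NA_real_,
         n = length(y), mu = weighted_mean(y, wn),
         fitted = fitted, model = mf, outcome = y,
         variables = variables, weights = wn, family = "lpm"),
    class = "anc_logit"
  )
}

resolve_weights <- function(data, weights) {
  if (is.numeric(weights)) {
    stopifnot(length(weights) == nrow(data))
    w <- weights
  } else if (is.character(weights)) {
    w <- data[[weights]]
  } else if ("pooled_weight" %in% names(data)) {
    w <- data$pooled_weight
  } else {
    w <- rep(1, nrow(data))
  }
  check_positive_weights(w)
  w
}

# Error when any factor category perfectly predicts the outcome.
check_separation <- function(y, mf) {
  for (v in names(mf)) {
    col <- as.factor(mf[[v]])
    for (lv in levels(col)) {
      yy <- y[col == lv]
      if (length(yy) > 0L && (all(yy == 0) || all(yy == 1))) {
        stop(sprintf(
          "separation: category '%s' of '%s' perfectly predicts the outcome",
          lv, v))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.anc_logit <- function(x, ...) {
  cat(sprintf("Weighted logistic fit: n = %d, logLik = %.3f, AIC = %.3f\n",
              x$n, x$loglik, x$aic))
  print(x$aor, digits = 3)
  invisible(x)
}

#' Average marginal effects of a weighted logistic fit
#'
#' For each non-reference category dummy, the derivative-based average
#' marginal effect on the probability scale,
#' `AME_k = beta_k * mean_w(p_i (1 - p_i))`, together with the weighted
#' covariate means and the weighted outcome mean on the estimation sample —
#' the three ingredients of the elasticity used by the concentration-index
#' decomposition.
#'
#' @param fit an [fit_weighted_logit()] object.
#' @return object of class `anc_ame`: data.frame with `term`, `variable`,
#'   `category`, `ame`, `xbar`; attribute `mu` is the weighted outcome
#'   mean.
#' @export
average_marginal_effects <- function(fit) {
  stopifnot(inherits(fit, "anc_logit"))
  lpm <- identical(fit$family, "lpm")
  scale <- if (lpm) 1 else
    weighted_mean(fit$fitted * (1 - fit$fitted), fit$weights)
  X <- stats::model.matrix(stats::reformulate(fit$variables), data = fit$model)
  terms <- setdiff(colnames(X), "(Intercept)")
  assign <- attr(X, "assign")[match(terms, colnames(X))]
  var_of_term <- fit$variables[assign]
  category <- mapply(function(tm, v) sub(paste0("^", v), "", tm),
                     terms, var_of_term)
  out <- data.frame(
    term = terms,
    variable = var_of_term,
    category = unname(category),
    ame = unname(fit$coef[terms]) * scale,
    xbar = vapply(terms, function(tm) weighted_mean(X[, tm], fit$weights),
                  numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, mu = fit$mu, class = c("anc_ame", "data.frame"))
}
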
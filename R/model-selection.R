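#' Best-subset covariate selection by AIC
#'
#' Fits a weighted logistic model for every candidate variable group on the
#' same complete-case estimation sample and selects the group attaining the
#' minimum `AIC = -2 logLik + 2k` (k counting all estimated coefficients,
#' intercept included). Ties are broken toward the smaller group (fewer
#' variables, then fewer parameters). Candidates must share one estimation
#' sample: any missingness on the union of candidate variables is an error
#' so selection is not confounded by differing samples.
#'
#' @param data pooled data frame.
#' @param candidates list of character vectors (variable groups), e.g. from
#'   [all_subsets()].
#' @param outcome binary outcome column name.
#' @param weights weight column name or numeric vector (see
#'   [fit_weighted_logit()]).
#' @return object of class `selection_result`: list with `table`
#'   (candidate, k, loglik, aic), `selected` (character vector),
#'   `selected_fit`, `vif` and `vif_summary` for the selected design.
#' @export
best_subset_aic <- function(data, candidates, outcome = "anc8",
                            weights = NULL) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  vars <- unique(unlist(candidates))
  if (anyNA(data[, c(outcome, vars)])) {
    stop("differential missingness across candidates: apply filter_eligible() ",
         "on the union of candidate variables first")
  }
  fits <- lapply(candidates, function(g)
    fit_weighted_logit(data, g, outcome = outcome, weights = weights))
  tab <- data.frame(
    candidate = vapply(candidates, paste, character(1), collapse = "+"),
    n_vars = lengths(candidates),
    k = vapply(fits, function(f) length(f$coef), numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$aic, tab$n_vars, tab$k)
  best <- ord[1L]
  sel_fit <- fits[[best]]
  v <- if (length(candidates[[best]]) >= 2L) {
    vif(data[, candidates[[best]], drop = FALSE],
        w = resolve_weights(data, weights))
  } else NULL
  structure(
    list(table = tab[order(tab$aic), , drop = FALSE],
         selected = candidates[[best]],
         selected_fit = sel_fit,
         vif = v$vif, vif_summary = v$summary),
    class = "selection_result"
  )
}

#' All variable subsets up to a size cap
#'
#' Exhaustive candidate enumeration for [best_subset_aic()], guarded by a
#' cap on the number of candidates.
#'
#' @param vars character vector of variable names.
#' @param max_size largest subset size (default all).
#' @param max_candidates hard cap on the number of generated subsets.
#' @return list of character vectors (the empty set is excluded).
#' @export
all_subsets <- function(vars, max_size = length(vars),
                        max_candidates = 10000L) {
  sizes <- seq_len(min(max_size, length(vars)))
  total <- sum(choose(length(vars), sizes))
  if (total > max_candidates) {
    stop(sprintf("subset enumeration would produce %d candidates (cap %d); ",
                 total, max_candidates),
         "reduce max_size or supply explicit candidates")
  }
  out <- list()
  for (s in sizes) {
    cmb <- utils::combn(vars, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Variance inflation factors of a dummy-coded design
#'
#' Regresses each non-reference dummy column on all others by weighted
#' least squares and reports `VIF = 1 / (1 - R^2)`, with the mean, minimum
#' and maximum across columns. Perfectly collinear columns are reported
#' with infinite VIF and named in a warning.
#'
#' @param design data frame of covariates (factors are dummy-coded with
#'   reference levels dropped) or a numeric matrix.
#' @param w optional positive weights.
#' @return list with `vif` (named numeric) and `summary`
#'   (mean/min/max).
#' @export
vif <- function(design, w = NULL) {
  if (is.data.frame(design)) {
    design <- droplevels(design)
    X <- stats::model.matrix(~ ., data = design)[, -1L, drop = FALSE]
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (ncol(X) < 2L) stop("VIF needs at least 2 covariate columns")
  if (any(apply(X, 2L, function(x) stats::var(x) == 0))) {
    stop("constant covariate column in VIF design")
  }
  if (is.null(w)) w <- rep(1, nrow(X))
  check_positive_weights(w)
  out <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Xj <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.wfit(Xj, yj, w)
    mu <- weighted_mean(yj, w)
    sst <- sum(w * (yj - mu)^2)
    sse <- sum(w * fit$residuals^2)
    r2 <- 1 - sse / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  if (any(!is.finite(out))) {
    warning("perfect collinearity: infinite VIF for ",
            paste(names(out)[!is.finite(out)], collapse = ", "))
  }
  list(vif = out,
       summary = c(mean = mean(out), min = min(out), max = max(out)))
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Best-subset AIC selection\n")
  print(utils::head(x$table, 10), digits = 5)
  cat("selected:", paste(x$selected, collapse = " + "), "\n")
  if (!is.null(x$vif_summary)) {
    cat(sprintf("VIF mean/min/max: %.2f / %.2f / %.2f\n",
                x$vif_summary["mean"], x$vif_summary["min"],
                x$vif_summary["max"]))
  }
  invisible(x)
}
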
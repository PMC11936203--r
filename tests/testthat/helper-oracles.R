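# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: ranks are computed record by record from the
# defining formula, the concentration index by the O(n^2) pairwise double
# sum, and logistic log-likelihoods by direct numerical maximisation.

# weighted mid-rank, straight from the definition, one record at a time
oracle_rank <- function(x, w) {
  x <- if (is.factor(x)) as.integer(x) else as.numeric(x)
  W <- sum(w)
  vapply(seq_along(x), function(i) {
    (sum(w[x < x[i]]) + 0.5 * sum(w[x == x[i]])) / W
  }, numeric(1))
}

# C = sum_ij w_i w_j (y_i - y_j)(r_i - r_j) / (mu W^2), pairwise form
oracle_cix_double_sum <- function(y, strat, w) {
  r <- oracle_rank(strat, w)
  W <- sum(w)
  mu <- sum(w * y) / W
  acc <- 0
  for (i in seq_along(y)) {
    acc <- acc + sum(w[i] * w * (y[i] - y) * (r[i] - r))
  }
  acc / (mu * W^2)
}

# weighted Bernoulli log-likelihood maximised numerically (AIC oracle)
oracle_logit_aic <- function(y, mf, w) {
  X <- stats::model.matrix(~ ., data = mf)
  wn <- w * length(y) / sum(w)
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(wn * (y * eta - log1p(exp(eta))))
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  2 * opt$value + 2 * ncol(X)
}

# small synthetic spec: 3 countries, quick to generate in simulation loops
small_spec <- function(n = 1500L, seed = 1L, ...) {
  k <- 3L
  n_i <- rep(n %/% k, k) + c(n %% k, 0L, 0L)
  population_spec(
    countries = data.frame(country = c("alpha", "bravo", "charlie"),
                           n_women = n_i,
                           total_pop = n_i * c(1800L, 2500L, 3200L)),
    seed = seed, ...)
}

# pooled dataset from a spec, via the standard preparation path
pooled_fixture <- function(spec) {
  survey <- simulate_survey(spec)
  pool_surveys(filter_eligible(survey),
               spec$countries[, c("country", "total_pop")])
}

# memoised large default-spec survey shared across expensive tests
big_pooled <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- population_spec(n_total = 50000L, seed = 42L)
      cache <<- list(spec = spec, pooled = pooled_fixture(spec))
    }
    cache
  }
})
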
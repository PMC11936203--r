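test_that("elasticity is the scaled marginal effect", {
  expect_equal(elasticity(0.02, 0.45, 0.09), 0.1)
  expect_equal(elasticity(0, 0.7, 0.2), 0)
  expect_equal(elasticity(0.02, 2 * 0.45, 0.09), 2 * elasticity(0.02, 0.45, 0.09))
  expect_error(elasticity(0.02, 0.45, 0), "positive")
})

test_that("covariate concentration indices obey the sign conventions", {
  set.seed(404)
  n <- 4000
  q <- sample(1:5, n, replace = TRUE)
  w <- rgamma(n, 5, 5)
  y <- rbinom(n, 1, 0.1); y[1] <- 1L
  rk <- ranked_outcome(y, q, w)

  top <- as.numeric(q == 5)
  bottom <- as.numeric(q == 1)
  C_top <- covariate_cix(top, rk)
  C_bot <- covariate_cix(bottom, rk)
  expect_gt(C_top, 0)
  expect_lt(C_bot, 0)
  # extreme concentration bound: C_k <= 1 - xbar, approached by the top group
  xbar <- sum(w * top) / sum(w)
  expect_lte(C_top, 1 - xbar + 1e-12)
  expect_gt(C_top, 0.9 * (1 - xbar))
  # a category spread uniformly over ranks concentrates nowhere
  set.seed(405)
  unif <- rbinom(n, 1, 0.3)
  expect_lt(abs(covariate_cix(unif, rk)), 0.05)
  expect_error(covariate_cix(rep(0, n), rk), "empty category")
})

test_that("decomposition closes exactly and sums to 100%", {
  spec <- small_spec(n = 3000, seed = 99)
  pooled <- pooled_fixture(spec)
  vars <- c("wealth_quintile", "education", "residence", "parity", "employed")
  fit <- fit_weighted_logit(pooled, vars)
  for (sv in c("wealth_quintile", "education")) {
    rk <- ranked_outcome(pooled$anc8, pooled[[sv]], pooled$pooled_weight,
                         label = sv)
    dec <- decompose_cix(fit, rk)
    expect_equal(sum(dec$abs_contribution) + attr(dec, "residual"),
                 attr(dec, "cix_total"), tolerance = 1e-12)
    expect_equal(sum(dec$pct_contribution) + attr(dec, "residual_pct"), 100,
                 tolerance = 1e-10)
    expect_equal(sign(dec$abs_contribution),
                 sign(dec$elasticity) * sign(dec$cix))
  }
})

test_that("permuting covariate order changes nothing but row order", {
  spec <- small_spec(n = 1500, seed = 45)
  pooled <- pooled_fixture(spec)
  rk <- ranked_outcome(pooled$anc8, pooled$wealth_quintile,
                       pooled$pooled_weight, label = "wealth_quintile")
  d1 <- decompose_cix(fit_weighted_logit(
    pooled, c("wealth_quintile", "education", "residence")), rk)
  d2 <- decompose_cix(fit_weighted_logit(
    pooled, c("residence", "wealth_quintile", "education")), rk)
  key <- function(d) d[order(d$variable, d$category), ]
  expect_equal(key(as.data.frame(d1)), key(as.data.frame(d2)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("linear generating model decomposes exactly onto its covariate", {
  # outcome a deterministic linear function of a rank-like covariate:
  # single contribution equals the total index, residual is numerically zero
  n <- 2000
  x <- (seq_len(n) - 0.5) / n
  d <- data.frame(x = x, y = 0.02 + 0.14 * x)
  lpm <- fit_weighted_lpm(d, "x", outcome = "y")
  rk <- ranked_outcome(d$y, d$x, rep(1, n), label = "x")
  dec <- decompose_cix(lpm, rk)
  expect_equal(dec$abs_contribution, attr(dec, "cix_total"), tolerance = 1e-10)
  expect_equal(attr(dec, "residual"), 0, tolerance = 1e-10)
  expect_equal(attr(dec, "gc_error"), 0, tolerance = 1e-10)
})

test_that("rank-independent covariates contribute nothing", {
  set.seed(606)
  n <- 20000
  q <- sample(1:5, n, replace = TRUE)
  a <- factor(sample(c("no", "yes"), n, TRUE))
  b <- factor(sample(c("lo", "mid", "hi"), n, TRUE), levels = c("lo", "mid", "hi"))
  y <- rbinom(n, 1, plogis(-2.3 + 0.5 * (a == "yes") + 0.3 * (b == "hi")))
  d <- data.frame(q = q, a = a, b = b, y = y)
  fit <- fit_weighted_logit(d, c("a", "b"), outcome = "y")
  rk <- ranked_outcome(d$y, d$q, rep(1, n), label = "q")
  dec <- decompose_cix(fit, rk)
  expect_true(all(abs(dec$abs_contribution) < 0.01))
  expect_equal(attr(dec, "residual"), attr(dec, "cix_total"), tolerance = 0.05)
})

test_that("reversing the ranking order negates the whole table exactly", {
  spec <- small_spec(n = 1500, seed = 46)
  pooled <- pooled_fixture(spec)
  fit <- fit_weighted_logit(pooled, c("wealth_quintile", "residence"))
  fwd <- ranked_outcome(pooled$anc8, pooled$wealth_quintile,
                        pooled$pooled_weight, label = "wealth_quintile")
  rev_strat <- factor(rev(anc_schema()$wealth_quintile)[
    as.integer(pooled$wealth_quintile)],
    levels = anc_schema()$wealth_quintile)
  bwd <- ranked_outcome(pooled$anc8, rev_strat, pooled$pooled_weight,
                        label = "wealth_quintile")
  d_f <- decompose_cix(fit, fwd); d_b <- decompose_cix(fit, bwd)
  expect_equal(d_b$abs_contribution, -d_f$abs_contribution, tolerance = 1e-12)
  expect_equal(attr(d_b, "cix_total"), -attr(d_f, "cix_total"),
               tolerance = 1e-12)
})

test_that("aggregation sums percentage contributions per variable group", {
  tab <- data.frame(
    variable = c("wealth", "wealth", "edu", "edu", "res"),
    category = c("q2", "q3", "primary", "higher", "rural"),
    pct_contribution = c(1.5, -0.5, 4, 6, 2.25)
  )
  agg <- aggregate_contributions(tab)
  expect_equal(unname(agg[c("wealth", "edu", "res")]), c(1, 10, 2.25))
  # a group of one is its own percentage
  expect_equal(unname(agg["res"]), 2.25)
  combo <- aggregate_contributions(tab, groups = list(joint = c("wealth", "edu")))
  expect_equal(unname(combo["joint"]), 11)
  expect_error(aggregate_contributions(rbind(tab, tab[1, ])), "twice")
  expect_error(aggregate_contributions(tab, groups = list(g = "ghost")),
               "unknown variables")
})
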
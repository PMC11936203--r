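test_that("fractional ranks follow the weighted mid-rank formula", {
  expect_equal(fractional_rank(c(10, 20, 30, 40)),
               c(0.125, 0.375, 0.625, 0.875))
  expect_equal(fractional_rank(5, w = 3), 0.5)

  # permuting the input leaves ranks attached to their records
  x <- c(2, 1, 3, 2, 5); w <- c(1, 2, 1, 3, 1)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(fractional_rank(x, w)[perm], fractional_rank(x[perm], w[perm]))

  expect_error(fractional_rank(rep(3, 4)), "constant stratifier")
  expect_error(fractional_rank(c(1, NA)), "missing")
})

test_that("rank properties hold over random tied/weighted cases", {
  set.seed(5150)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    x <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2) next
    w <- rgamma(n, 4, 4)
    r <- fractional_rank(x, w)
    expect_equal(sum(w * r) / sum(w), 0.5, tolerance = 1e-10)
    expect_true(all(r > 0 & r < 1))
    expect_true(all(diff(r[order(x)]) >= 0))
    expect_equal(r, oracle_rank(x, w), tolerance = 1e-12)
  }
})

test_that("concentration curve has the documented geometry", {
  w <- rep(1, 8); x <- rep(1:4, each = 2)
  # constant outcome: curve on the diagonal
  rk <- ranked_outcome(rep(3, 8), x, w)
  cc <- concentration_curve(rk)
  expect_equal(cc$outcome_share, cc$pop_share, tolerance = 1e-12)
  expect_equal(cc$pop_share[1], 0)
  expect_equal(cc$pop_share[nrow(cc)], 1)
  expect_equal(cc$outcome_share[nrow(cc)], 1)

  # outcome entirely in the top block: curve below the diagonal
  rk2 <- ranked_outcome(as.numeric(x == 4), x, w)
  cc2 <- concentration_curve(rk2)
  inner <- seq(2, nrow(cc2) - 1)
  expect_true(all(cc2$outcome_share[inner] < cc2$pop_share[inner]))

  expect_error(concentration_curve(ranked_outcome(rep(0, 8), x, w)),
               "zero weighted outcome")
})

test_that("worked micro-examples give CIX 0.25 and 0.5", {
  r1 <- ranked_outcome(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(2 * sum((r1$y - 2.5) * (r1$rank - 0.5)) / 4 / 2.5, 0.25)
  expect_equal(concentration_index(r1)$cix, 0.25, tolerance = 1e-12)
  expect_equal(concentration_index(r1)$cix,
               oracle_cix_double_sum(c(1, 2, 3, 4), c(1, 2, 3, 4), rep(1, 4)),
               tolerance = 1e-12)

  r2 <- ranked_outcome(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(concentration_index(r2)$cix, 0.5, tolerance = 1e-12)

  # constant outcome: zero index
  r3 <- ranked_outcome(rep(2, 4), c(1, 2, 3, 4))
  expect_equal(concentration_index(r3)$cix, 0, tolerance = 1e-12)

  # reversing the stratifier negates the index exactly
  r4 <- ranked_outcome(c(0, 0, 1, 1), c(4, 3, 2, 1))
  expect_equal(concentration_index(r4)$cix, -0.5, tolerance = 1e-12)
})

test_that("covariance formula matches the double-sum oracle on fixtures", {
  set.seed(909)
  for (i in 1:12) {
    n <- sample(20:300, 1)
    x <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2) next
    w <- rgamma(n, 3, 3)
    y <- rbinom(n, 1, plogis(-2 + 0.5 * x))
    if (sum(y) == 0) y[1] <- 1
    rk <- ranked_outcome(y, x, w)
    C <- concentration_index(rk)$cix
    expect_equal(C, oracle_cix_double_sum(y, x, w), tolerance = 1e-10)
    expect_lte(abs(C), 1)
    # binary outcome upper bound (finite-sample slack)
    mu <- sum(w * y) / sum(w)
    expect_lte(C, 1 - mu + 2 / n)
  }
})

test_that("curve area is consistent with the index for distinct ranks", {
  set.seed(33)
  n <- 5000
  x <- rnorm(n)                         # continuous stratifier, no ties
  y <- rbinom(n, 1, plogis(-2 + 0.8 * x))
  rk <- ranked_outcome(y, x, rep(1, n))
  C <- concentration_index(rk)$cix
  cc <- concentration_curve(rk)
  area <- sum(diff(cc$pop_share) *
                (head(cc$outcome_share, -1) + tail(cc$outcome_share, -1)) / 2)
  expect_equal(C, 1 - 2 * area, tolerance = 0.01)
})

test_that("CIX significance has sensible power and SE scaling", {
  spec <- small_spec(n = 5000, seed = 73)
  pooled <- pooled_fixture(spec)
  res <- concentration_index(
    ranked_outcome(pooled$anc8, pooled$wealth_quintile, pooled$pooled_weight,
                   label = "wealth_quintile"))
  expect_gt(res$cix, 0)
  expect_lt(res$p_value, 1e-4)
  expect_equal(format_p(res$p_value), "< 0.0001")

  # SE shrinks like 1/sqrt(n): log-log slope -0.5 +/- 0.1
  set.seed(88)
  ns <- c(500, 2000, 8000)
  mean_se <- vapply(ns, function(n) {
    mean(replicate(20, {
      x <- sample(1:5, n, replace = TRUE)
      y <- rbinom(n, 1, 0.1)
      cix_significance(ranked_outcome(y, x, rep(1, n)))$se
    }))
  }, numeric(1))
  slope <- coef(lm(log(mean_se) ~ log(ns)))[2]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("per-group indices behave under symmetry and sign reversal", {
  spec <- small_spec(n = 1200, seed = 57)
  pooled <- pooled_fixture(spec)

  one <- pooled[pooled$country == "alpha", ]
  res <- cix_by_group(one, "wealth_quintile")
  expect_equal(res$alpha$cix, res$pooled$cix, tolerance = 1e-12)

  # two identical groups: identical per-group indices
  b <- one; b$country <- "bravo"
  two <- rbind(as.data.frame(one), as.data.frame(b))
  res2 <- cix_by_group(two, "wealth_quintile")
  expect_equal(res2$alpha$cix, res2$bravo$cix, tolerance = 1e-12)

  # engineered opposite gradients give opposite signs
  flip <- one
  flip$country <- "flip"
  flip$wealth_quintile <- factor(
    rev(anc_schema()$wealth_quintile)[as.integer(one$wealth_quintile)],
    levels = anc_schema()$wealth_quintile)
  mixed <- rbind(as.data.frame(one), as.data.frame(flip))
  res3 <- cix_by_group(mixed, "wealth_quintile")
  expect_equal(res3$flip$cix, -res3$alpha$cix, tolerance = 1e-12)

  # group with zero outcome mean is skipped with a warning
  z <- one; z$country <- "zulu"; z$anc8 <- 0L
  expect_warning(res4 <- cix_by_group(rbind(as.data.frame(one),
                                            as.data.frame(z)),
                                      "wealth_quintile"),
                 "zulu")
  expect_false("zulu" %in% names(res4))
})

test_that("rank self-index approaches one third", {
  n <- 20000
  r <- fractional_rank(seq_len(n))
  C <- 2 * weighted_cov(r, r, rep(1, n)) / weighted_mean(r, rep(1, n))
  expect_equal(C, 1 / 3, tolerance = 0.001)
})
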
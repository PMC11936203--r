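test_that("population_spec validates its inputs", {
  expect_error(population_spec(asset_load = 0), "degenerate asset_load")
  expect_error(population_spec(n_assets = 1), "n_assets")
  expect_error(population_spec(seed = -1), "seed")
  expect_error(population_spec(asset_load = 1.5), "asset_load")
  expect_error(
    population_spec(countries = data.frame(country = "a", n_women = 10,
                                           total_pop = 5)),
    "total_pop")
})

test_that("asset simulation is deterministic and saturates in the limit", {
  spec <- small_spec(n = 200, seed = 9)
  expect_identical(simulate_assets(spec), simulate_assets(spec))

  sat <- simulate_assets(population_spec(
    countries = data.frame(country = "a", n_women = 2, total_pop = 100),
    n_assets = 4, asset_load = 1, seed = 1),
    affluence = c(-50, 50))
  expect_equal(unname(unclass(sat)[1, ]), rep(0L, 4))
  expect_equal(unname(unclass(sat)[2, ]), rep(1L, 4))
})

test_that("every asset correlates positively with latent affluence", {
  spec <- small_spec(n = 10000, seed = 3)
  assets <- simulate_assets(spec)
  aff <- attr(assets, "affluence")
  cors <- apply(unclass(assets), 2, cor, y = aff)
  expect_true(all(cors > 0))
})

test_that("PCA wealth score recovers the affluence ranking", {
  spec <- small_spec(n = 10000, seed = 5)
  assets <- simulate_assets(spec)
  pca <- score_wealth_pca(assets)
  rho <- cor(pca$score, attr(assets, "affluence"), method = "spearman")
  expect_gt(rho, 0.8)
  # quintiles are monotone in the score
  expect_true(all(diff(tapply(pca$score, pca$quintile, min)[
    order(match(levels(pca$quintile), anc_schema()$wealth_quintile))]) > 0))
})

test_that("single-asset scoring is monotone and complement mirrors quintiles", {
  m <- matrix(c(0, 0, 0, 1, 1, 1, 0, 1, 1, 1), ncol = 1)
  s <- score_wealth_pca(m)
  expect_true(all(s$score[m[, 1] == 1] > max(s$score[m[, 1] == 0])))

  # distinct multi-asset scores, equal weights, n divisible by 5:
  # complementing all bits mirrors the quintile assignment exactly
  set.seed(11)
  mm <- matrix(rbinom(10 * 8, 1, 0.5), nrow = 10)
  while (anyDuplicated(mm) || any(apply(mm, 2, var) == 0)) {
    mm <- matrix(rbinom(10 * 8, 1, 0.5), nrow = 10)
  }
  a <- score_wealth_pca(mm)
  b <- score_wealth_pca(1 - mm)
  expect_false(anyDuplicated(a$score) > 0)
  expect_equal(as.integer(b$quintile), 6L - as.integer(a$quintile))
})

test_that("degenerate asset tables are refused", {
  expect_error(score_wealth_pca(matrix(1, 100, 3)), "constant")
  expect_error(score_wealth_pca(matrix(c(0, 1), 4, 2)), "at least 5")
})

test_that("weight dispersion zero gives equal raw weights", {
  spec <- small_spec(n = 120, seed = 2, weight_dispersion = 0)
  s <- simulate_women(spec)
  expect_true(all(s$v005 == 1e6))
})

test_that("zero education gradient makes education independent of wealth", {
  spec <- small_spec(n = 10000, seed = 17, edu_gradient = 0)
  s <- simulate_women(spec)
  p <- suppressWarnings(
    chisq.test(table(s$education, s$wealth_quintile))$p.value)
  expect_gt(p, 0.01)
})

test_that("category frequencies match their specified distributions", {
  big <- big_pooled()
  s <- big$pooled
  shares <- default_category_shares()
  for (v in c("age_band", "marital", "parity", "insurance", "residence",
              "education")) {
    emp <- as.numeric(prop.table(table(s[[v]])))
    expect_lt(max(abs(emp - shares[[v]])), 0.01, label = v)
  }
})

test_that("outcome model hits its calibration targets", {
  # logistic(0) = 0.5 when all coefficients vanish
  null_coefs <- list(intercept = 0, employed = c(yes = 0))
  spec0 <- small_spec(n = 50000, seed = 23, outcome_coefs = null_coefs)
  s0 <- simulate_outcome(simulate_women(spec0), spec0)
  expect_equal(mean(s0$anc8), 0.5, tolerance = 0.01)

  # default spec: weighted prevalence calibrated near 9%
  big <- big_pooled()
  pw <- big$pooled$v005 / 1e6
  prev <- weighted.mean(big$pooled$anc8, pw)
  expect_gt(prev, 0.07)
  expect_lt(prev, 0.11)

  # positive wealth gradient: prevalence non-decreasing across quintiles
  prev_q <- tapply(seq_len(nrow(big$pooled)), big$pooled$wealth_quintile,
                   function(i) weighted.mean(big$pooled$anc8[i], pw[i]))
  expect_true(all(diff(prev_q) >= 0))
})

test_that("visit counts are consistent with the binary outcome", {
  spec <- small_spec(n = 2000, seed = 31)
  s <- simulate_survey(spec)
  expect_true(all(s$anc_visits[s$anc8 == 1] >= 8))
  expect_true(all(s$anc_visits[s$anc8 == 0] <= 7))
  expect_identical(recode_anc(s$anc_visits), s$anc8)
})

test_that("missing outcome coefficients are reported by category", {
  spec <- small_spec(n = 200, seed = 1)
  spec$outcome_coefs <- list(intercept = -2,
                             wealth_quintile = c(poorer = 0.1, middle = 0.2))
  s <- simulate_women(spec)
  expect_error(simulate_outcome(s, spec), "richer")
})

test_that("fixture files are byte-identical under a fixed seed", {
  spec <- small_spec(n = 300, seed = 77)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- write_survey_fixture(simulate_survey(spec), spec, d1)
  p2 <- write_survey_fixture(simulate_survey(spec), spec, d2)
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  back <- read_survey_csv(p1[["records"]])
  expect_equal(nrow(back), 300)
  expect_s3_class(back$education, "factor")
})
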
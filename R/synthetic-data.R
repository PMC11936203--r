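#' Specification of a synthetic multi-country survey population
#'
#' Bundles every parameter of the synthetic DHS-like generator: country
#' sample sizes and female populations, the latent-affluence asset model
#' behind the PCA wealth index, the affluence gradients on education and
#' residence, the outcome model coefficients, the dispersion of raw
#' sampling weights, and the master seed.
#'
#' The default population is a 15-country pool whose relative sample sizes
#' follow the country shares of a pooled sub-Saharan African DHS analysis,
#' scaled down to `n_total` women. Per-household assets are Bernoulli with
#' probability `plogis(load * affluence + offset)` where affluence is
#' standard normal, so the first principal component of the asset table
#' recovers the latent affluence ranking. Education follows a
#' proportional-odds model on affluence (`edu_gradient` log-odds per SD);
#' residence follows a binary logit on affluence (`residence_gradient`).
#' The outcome intercept, when `NULL`, is calibrated by bisection so the
#' weighted prevalence of the binary outcome matches `target_prevalence`
#' (default 9%, the pooled prevalence of eight or more ANC visits the
#' generator emulates).
#'
#' @param countries data frame with columns `country`, `n_women`,
#'   `total_pop` (women aged 15-49 in the country at survey time). Default:
#'   15 countries with heterogeneous sizes and sampling fractions.
#' @param n_total total sample size used to scale the default country table.
#' @param n_assets number of binary household asset indicators.
#' @param asset_load per-asset loading on latent affluence, each in [0, 1];
#'   recycled to `n_assets`.
#' @param edu_gradient log-odds of education per SD of affluence.
#' @param residence_gradient log-odds of urban residence per SD of affluence.
#' @param outcome_coefs named list: per-variable named numeric vectors of
#'   log-odds for non-reference categories, plus `intercept` (may be `NULL`
#'   for calibration).
#' @param target_prevalence weighted outcome prevalence targeted when the
#'   intercept is calibrated.
#' @param weight_dispersion coefficient of variation of raw v005-style
#'   weights (0 gives equal weights).
#' @param category_shares named list of marginal category probabilities for
#'   the remaining covariates; defaults to [default_category_shares()].
#' @param seed non-negative integer master seed.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(countries = NULL,
                            n_total = 15000L,
                            n_assets = 15L,
                            asset_load = 0.9,
                            edu_gradient = 1.0,
                            residence_gradient = 0.9,
                            outcome_coefs = default_outcome_coefs(),
                            target_prevalence = 0.09,
                            weight_dispersion = 0.3,
                            category_shares = default_category_shares(),
                            seed = 1L) {
  if (is.null(countries)) countries <- default_country_table(n_total)
  stopifnot(is.data.frame(countries),
            all(c("country", "n_women", "total_pop") %in% names(countries)))
  if (any(countries$n_women < 1)) stop("every n_women must be >= 1")
  if (any(countries$total_pop < countries$n_women)) {
    stop("total_pop must be >= n_women for every country")
  }
  if (!is_count(seed)) stop("seed must be a non-negative integer")
  if (!is_count(n_assets) || n_assets < 2) stop("n_assets must be >= 2")
  asset_load <- rep_len(asset_load, n_assets)
  if (any(asset_load < 0 | asset_load > 1)) {
    stop("asset_load entries must lie in [0, 1]")
  }
  if (all(asset_load == 0)) {
    stop("degenerate asset_load: all loadings zero give an uninformative wealth model")
  }
  if (weight_dispersion < 0) stop("weight_dispersion must be >= 0")
  if (!is.null(target_prevalence) &&
      (target_prevalence <= 0 || target_prevalence >= 1)) {
    stop("target_prevalence must be in (0, 1)")
  }
  structure(
    list(
      countries = countries, n_assets = as.integer(n_assets),
      asset_load = asset_load, edu_gradient = edu_gradient,
      residence_gradient = residence_gradient,
      outcome_coefs = outcome_coefs,
      target_prevalence = target_prevalence,
      weight_dispersion = weight_dispersion,
      category_shares = category_shares,
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

# 15 countries with sample shares mirroring a pooled SSA DHS sample and
# country-specific sampling fractions between roughly 1/1500 and 1/3500,
# so de-normalized weights differ materially across countries.
default_country_table <- function(n_total = 15000L) {
  shares <- c(7.5, 6.8, 5.9, 6.4, 4.6, 4.7, 4.6, 3.2, 8.0, 4.7, 6.8,
              18.0, 6.4, 6.6, 5.8) / 100
  n <- pmax(1L, as.integer(round(shares * n_total)))
  ratio <- seq(1500, 3500, length.out = length(shares))
  data.frame(
    country = sprintf("country%02d", seq_along(shares)),
    n_women = n,
    total_pop = as.integer(round(n * ratio))
  )
}

#' Default outcome-model coefficients of the synthetic generator
#'
#' Log-odds per non-reference category, with positive wealth and education
#' gradients (richest quintile OR 1.87, higher education OR 5.30) and the
#' familiar signatures of ANC utilisation data: working women more likely,
#' grand multiparity, insurance-covered and rural women less likely. The
#' `intercept` is `NULL`, meaning it is calibrated to the target prevalence.
#'
#' @return Named list suitable for the `outcome_coefs` field of
#'   [population_spec()].
#' @export
default_outcome_coefs <- function() {
  list(
    intercept = NULL,
    wealth_quintile = c("poorer" = log(1.25), "middle" = log(1.45),
                        "richer" = log(1.65), "richest" = log(1.87)),
    education = c("incomplete primary" = log(1.05),
                  "complete primary" = log(1.40),
                  "incomplete secondary" = log(1.90),
                  "complete secondary" = log(3.40),
                  "higher" = log(5.30)),
    age_band = c("20-24" = log(1.25), "25-29" = log(1.50), "30-34" = log(1.70),
                 "35-39" = log(1.80), "40-44" = log(1.91), "45-49" = log(1.30)),
    employed = c("yes" = log(1.69)),
    marital = c("married" = log(0.95), "cohabiting" = log(0.95),
                "widowed" = log(1.10), "divorced" = log(0.43),
                "separated" = log(0.78)),
    parity = c("two-four" = log(0.95), "five or more" = log(0.71)),
    insurance = c("yes" = log(0.48)),
    media_newspaper = c("yes" = log(0.86)),
    media_radio = c("yes" = log(1.10)),
    internet = c("yes" = log(1.15)),
    barrier_permission = c("big problem" = log(0.90)),
    barrier_distance = c("big problem" = log(0.85)),
    head_sex = c("female" = log(1.05)),
    residence = c("rural" = log(0.60))
  )
}

#' Simulate a binary household asset table from a latent affluence model
#'
#' Draws one standard-normal latent affluence value per household and
#' `n_assets` Bernoulli indicators with probability
#' `plogis(load_j * affluence + offset_j)`, with offsets spread over
#' [-1.5, 1.5] so asset prevalences vary. The latent affluence draw is kept
#' as an attribute for ground-truth checks.
#'
#' @param spec a [population_spec()].
#' @param affluence optional numeric vector overriding the latent draw
#'   (used for degenerate-limit checks); length defines household count.
#' @return Object of class `asset_matrix`: integer 0/1 matrix with
#'   attributes `affluence`, `household_id`, `country`.
#' @export
simulate_assets <- function(spec, affluence = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (all(spec$asset_load == 0)) {
    stop("degenerate asset_load: uninformative wealth model")
  }
  n <- sum(spec$countries$n_women)
  country <- rep(spec$countries$country, spec$countries$n_women)
  set.seed(stage_seed(spec$seed, "assets"))
  if (is.null(affluence)) {
    affluence <- stats::rnorm(n)
  } else {
    n <- length(affluence)
    country <- rep_len(country, n)
  }
  offsets <- seq(-1.5, 1.5, length.out = spec$n_assets)
  p <- plogis(outer(affluence, spec$asset_load) +
                matrix(offsets, n, spec$n_assets, byrow = TRUE))
  m <- matrix(as.integer(stats::runif(n * spec$n_assets) < p), n, spec$n_assets)
  colnames(m) <- sprintf("asset%02d", seq_len(spec$n_assets))
  structure(m, affluence = affluence,
            household_id = seq_len(n), country = country,
            class = c("asset_matrix", class(m)))
}

#' Score a household wealth index by principal component analysis
#'
#' Standardizes the asset indicators, extracts the first principal
#' component, orients it so wealthier (more-asset) households score higher,
#' and cuts the scores into weighted quintiles labelled poorest to richest.
#'
#' @param assets 0/1 matrix (rows = households), e.g. from
#'   [simulate_assets()].
#' @param w optional positive household weights for the quintile split.
#' @return list with `score` (numeric), `quintile` (factor, 5 levels),
#'   `loadings` (PC1 loadings on the non-constant assets).
#' @export
score_wealth_pca <- function(assets, w = NULL) {
  m <- unclass(assets)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  if (nrow(m) < 5L) stop("need at least 5 households to form quintiles")
  keep <- apply(m, 2L, function(x) stats::var(x) > 0)
  if (!any(keep)) stop("constant asset table: wealth index undefined")
  m <- m[, keep, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1L]
  loadings <- pc$rotation[, 1L]
  # orient so the score increases with overall asset ownership
  if (stats::cor(score, rowSums(m)) < 0) {
    score <- -score
    loadings <- -loadings
  }
  if (is.null(w)) w <- rep(1, nrow(m))
  check_positive_weights(w)
  q <- weighted_ntile(score, w, 5L)
  list(
    score = as.numeric(score),
    quintile = factor(anc_schema()$wealth_quintile[q],
                      levels = anc_schema()$wealth_quintile),
    loadings = loadings
  )
}

# Proportional-odds cutpoints calibrated so the marginal education
# distribution matches `shares` when affluence is standard normal and the
# per-SD gradient is `gradient`: solves E[plogis(c_k - g*a)] = cum share.
edu_cutpoints <- function(shares, gradient) {
  cum <- cumsum(shares)[-length(shares)]
  grid <- stats::qnorm(seq(0.0005, 0.9995, length.out = 2000))
  vapply(cum, function(s) {
    stats::uniroot(function(c) mean(plogis(c - gradient * grid)) - s,
                   interval = c(-40, 40), tol = 1e-10)$root
  }, numeric(1))
}

#' Simulate woman-level survey records
#'
#' Generates one record per woman across the spec's countries: a v005-style
#' raw sampling weight (gamma with mean 1e6 and CV `weight_dispersion`), a
#' household wealth quintile from the PCA-scored asset index, ordinal
#' education from a proportional-odds model on latent affluence, urban or
#' rural residence from a logit on affluence, and the remaining covariates
#' from their marginal category distributions.
#'
#' @param spec a [population_spec()].
#' @return data frame (class `synthetic_survey`) with one row per woman and
#'   attribute `ground_truth` holding the latent affluence and wealth score.
#' @export
simulate_women <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  assets <- simulate_assets(spec)
  affluence <- attr(assets, "affluence")
  country <- attr(assets, "country")
  n <- length(affluence)

  set.seed(stage_seed(spec$seed, "weights"))
  if (spec$weight_dispersion == 0) {
    v005 <- rep(1e6, n)
  } else {
    shape <- 1 / spec$weight_dispersion^2
    v005 <- 1e6 * stats::rgamma(n, shape = shape, rate = shape)
  }
  pca <- score_wealth_pca(assets, w = v005 / 1e6)

  set.seed(stage_seed(spec$seed, "education"))
  sch <- anc_schema()
  cuts <- edu_cutpoints(spec$category_shares$education, spec$edu_gradient)
  lat <- spec$edu_gradient * affluence + stats::rlogis(n)
  edu_idx <- 1L + rowSums(outer(lat, cuts, `>`))
  education <- factor(sch$education[edu_idx], levels = sch$education)

  set.seed(stage_seed(spec$seed, "covariates"))
  draw_cat <- function(v) {
    p <- spec$category_shares[[v]]
    factor(sample(sch[[v]], n, replace = TRUE, prob = p), levels = sch[[v]])
  }
  out <- data.frame(
    country = country,
    v005 = v005,
    eligible = 1L,
    wealth_quintile = pca$quintile,
    education = education,
    stringsAsFactors = FALSE
  )
  for (v in c("age_band", "employed", "marital", "parity", "insurance",
              "media_tv", "media_radio", "media_newspaper", "internet",
              "barrier_permission", "barrier_distance", "barrier_money",
              "barrier_alone", "head_sex")) {
    out[[v]] <- draw_cat(v)
  }
  # urban residence rises with affluence; offset calibrated to the marginal
  p_urban_target <- spec$category_shares$residence[1L]
  grid <- stats::qnorm(seq(0.0005, 0.9995, length.out = 2000))
  off <- stats::uniroot(
    function(c) mean(plogis(c + spec$residence_gradient * grid)) - p_urban_target,
    interval = c(-40, 40), tol = 1e-10
  )$root
  urban <- stats::runif(n) < plogis(off + spec$residence_gradient * affluence)
  out$residence <- factor(ifelse(urban, "urban", "rural"),
                          levels = sch$residence)
  structure(out,
            ground_truth = list(affluence = affluence,
                                wealth_score = pca$score,
                                pca_loadings = pca$loadings),
            class = c("synthetic_survey", class(out)))
}

# Per-record linear predictor (excluding intercept) under the spec's
# outcome model. Errors if an observed non-reference category lacks a
# coefficient.
outcome_linear_predictor <- function(survey, coefs) {
  lp <- numeric(nrow(survey))
  for (v in setdiff(names(coefs), "intercept")) {
    if (!v %in% names(survey)) {
      stop(sprintf("outcome model variable '%s' absent from survey", v))
    }
    beta <- coefs[[v]]
    ref <- levels(survey[[v]])[1L]
    observed <- setdiff(levels(droplevels(survey[[v]])), ref)
    missing_cat <- setdiff(observed, names(beta))
    if (length(missing_cat)) {
      stop(sprintf("missing outcome coefficient for category '%s' of '%s'",
                   missing_cat[1L], v))
    }
    full <- c(stats::setNames(0, ref), beta)
    lp <- lp + unname(full[as.character(survey[[v]])])
  }
  lp
}

# Bisection for the intercept hitting a weighted target prevalence.
calibrate_intercept <- function(lp, w, target) {
  f <- function(b) weighted_mean(plogis(b + lp), w) - target
  stats::uniroot(f, interval = c(-40, 40), tol = 1e-12)$root
}

#' Attach a simulated binary outcome and visit count to a survey
#'
#' Draws the eight-or-more-visits indicator from
#' `Bernoulli(plogis(intercept + sum of category log-odds))` under the
#' spec's outcome model. When the spec's intercept is `NULL` it is first
#' calibrated by bisection so the weighted prevalence of the outcome equals
#' the spec's target (default 9%). An integer ANC visit count consistent
#' with the indicator is back-filled (uniform on 8-12 when positive, 0-7
#' when negative) so the dichotomisation step downstream is exercised.
#'
#' @param survey data frame from [simulate_women()].
#' @param spec the generating [population_spec()].
#' @return `survey` with columns `anc_visits` and `anc8` added; the
#'   `ground_truth` attribute gains the realized intercept and coefficients.
#' @export
simulate_outcome <- function(survey, spec) {
  stopifnot(inherits(spec, "population_spec"))
  lp <- outcome_linear_predictor(survey, spec$outcome_coefs)
  w <- survey$v005 / 1e6
  b0 <- spec$outcome_coefs$intercept
  if (is.null(b0)) {
    b0 <- calibrate_intercept(lp, w, spec$target_prevalence)
  }
  set.seed(stage_seed(spec$seed, "outcome"))
  p <- plogis(b0 + lp)
  y <- as.integer(stats::runif(nrow(survey)) < p)
  set.seed(stage_seed(spec$seed, "backfill"))
  visits <- ifelse(y == 1L,
                   sample(8:12, nrow(survey), replace = TRUE),
                   sample(0:7, nrow(survey), replace = TRUE))
  survey$anc_visits <- as.integer(visits)
  survey$anc8 <- y
  gt <- attr(survey, "ground_truth") %||% list()
  gt$intercept <- b0
  gt$outcome_coefs <- spec$outcome_coefs
  attr(survey, "ground_truth") <- gt
  survey
}

#' Simulate a complete synthetic survey (covariates plus outcome)
#'
#' @param spec a [population_spec()].
#' @return data frame as from [simulate_outcome()].
#' @export
simulate_survey <- function(spec) {
  simulate_outcome(simulate_women(spec), spec)
}

#' Write a synthetic survey fixture to disk
#'
#' Writes the record CSV, a country metadata CSV, and a ground-truth JSON
#' with the generating parameters, so a fixture is fully reproducible and
#' auditable.
#'
#' @param survey data frame from [simulate_survey()].
#' @param spec the generating [population_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_survey_fixture <- function(survey, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    records = file.path(dir, "survey.csv"),
    countries = file.path(dir, "countries.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  utils::write.csv(as.data.frame(survey), paths[["records"]], row.names = FALSE)
  utils::write.csv(spec$countries, paths[["countries"]], row.names = FALSE)
  gt <- attr(survey, "ground_truth") %||% list()
  truth <- list(
    seed = spec$seed,
    n_assets = spec$n_assets,
    asset_load = spec$asset_load,
    edu_gradient = spec$edu_gradient,
    residence_gradient = spec$residence_gradient,
    target_prevalence = spec$target_prevalence,
    weight_dispersion = spec$weight_dispersion,
    intercept = gt$intercept,
    outcome_coefs = spec$outcome_coefs[setdiff(names(spec$outcome_coefs),
                                               "intercept")]
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
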
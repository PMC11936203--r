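# Internal weighted-statistics helpers shared across modules.
# All weighted moments use population-style denominators (sum of weights),
# which is what the concentration-index algebra assumes.

weighted_mean <- function(x, w) {
  stopifnot(length(x) == length(w))
  sum(w * x) / sum(w)
}

# population-style weighted covariance: sum w (x - xbar)(y - ybar) / sum w
weighted_cov <- function(x, y, w) {
  xb <- weighted_mean(x, w)
  yb <- weighted_mean(y, w)
  sum(w * (x - xb) * (y - yb)) / sum(w)
}

weighted_var <- function(x, w) weighted_cov(x, x, w)

# Weighted n-tile assignment (1 = lowest). Cut points are placed on the
# cumulative weight scale; each record is assigned by the midpoint of its
# own weight mass, so the split is deterministic and order-invariant for
# distinct values. Ties in x are kept contiguous via a stable sort.
weighted_ntile <- function(x, w, n = 5L) {
  stopifnot(length(x) == length(w), all(w > 0), n >= 2L)
  ord <- order(x)
  ws <- w[ord]
  mid <- cumsum(ws) - ws / 2
  g <- pmin(n, pmax(1L, ceiling(mid / (sum(ws) / n))))
  out <- integer(length(x))
  out[ord] <- as.integer(g)
  out
}

check_positive_weights <- function(w) {
  if (length(w) == 0L || anyNA(w) || any(w <= 0)) {
    stop("weights must be positive and non-missing", call. = FALSE)
  }
  invisible(w)
}

# Scale weights to mean 1 so likelihood-based quantities (logLik, AIC,
# model-based standard errors) are on the effective scale of the actual
# sample size rather than the (possibly population-scale) weight total.
normalize_weights <- function(w) {
  check_positive_weights(w)
  w * (length(w) / sum(w))
}

# Deterministic per-stage RNG streams derived from one master seed.
# Offsets keep stages reproducible independently of each other.
stage_seed <- function(seed, stage) {
  offsets <- c(
    assets = 11L, weights = 23L, education = 37L, covariates = 41L,
    outcome = 53L, backfill = 67L, missing = 79L
  )
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  as.integer((as.numeric(seed) + offsets[[stage]]) %% 2147483646L)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
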
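#' Dichotomise ANC visit counts at the WHO eight-visit threshold
#'
#' Recodes a count of antenatal care visits to 1 (eight or more visits) or
#' 0 (fewer than eight). Missing counts propagate as missing; DHS-style
#' "don't know" codes (98, 99) are treated as missing.
#'
#' @param anc_visits non-negative integer vector of visit counts.
#' @return integer vector of 0/1 (with NAs preserved).
#' @export
recode_anc <- function(anc_visits) {
  if (!is.numeric(anc_visits)) stop("anc_visits must be numeric counts")
  ok <- is.na(anc_visits) | (anc_visits >= 0 & anc_visits == floor(anc_visits))
  if (!all(ok)) stop("anc_visits must be non-negative integers or missing")
  x <- ifelse(!is.na(anc_visits) & anc_visits %in% c(98, 99), NA, anc_visits)
  as.integer(x >= 8)
}

#' Derive the per-woman sampling weight from a raw v005-style weight
#'
#' DHS stores the women's weight scaled by one million; the analysis weight
#' is `v005 / 1e6`.
#'
#' @param v005 positive raw weight(s).
#' @return numeric per-woman weight(s).
#' @export
derive_weight <- function(v005) {
  if (!is.numeric(v005)) stop("v005 must be numeric")
  if (anyNA(v005) || any(v005 <= 0)) {
    stop("invalid sampling weight: v005 must be positive and non-missing")
  }
  v005 / 1e6
}

#' De-normalize per-woman weights for multi-country pooling
#'
#' Rescales a country's per-woman weights by the ratio of the national
#' population of women aged 15-49 to the eligible sample size, so pooled
#' estimates across countries reflect population sizes rather than sample
#' sizes.
#'
#' @param pw per-woman weight(s) from [derive_weight()].
#' @param total_pop women aged 15-49 in the country at survey time.
#' @param sample_n eligible sample size (women with a recent birth).
#' @return numeric pooled weight(s): `pw * total_pop / sample_n`.
#' @export
denormalize_weight <- function(pw, total_pop, sample_n) {
  if (!is_count(sample_n) || sample_n < 1) stop("sample_n must be a positive count")
  if (!is.numeric(total_pop) || length(total_pop) != 1L || is.na(total_pop) ||
      total_pop < sample_n) {
    stop("total_pop must be a single number >= sample_n")
  }
  if (anyNA(pw) || any(pw <= 0)) stop("per-woman weights must be positive")
  pw * total_pop / sample_n
}

#' Apply the eligibility and complete-case filter
#'
#' Retains records flagged as having a birth in the last five years
#' (`eligible` column, when present) and complete on all the analysis
#' variables. A per-variable exclusion count is attached as the
#' `exclusion_log` attribute (a record missing several variables is counted
#' once per variable).
#'
#' @param records survey data frame.
#' @param vars variables that must be non-missing; defaults to every
#'   analysis column present.
#' @return filtered data frame with attribute `exclusion_log`.
#' @export
filter_eligible <- function(records,
                            vars = intersect(c("anc8", "anc_visits",
                                               names(anc_schema())),
                                             names(records))) {
  stopifnot(is.data.frame(records))
  keep <- rep(TRUE, nrow(records))
  log <- c()
  if ("eligible" %in% names(records)) {
    inel <- is.na(records$eligible) | records$eligible != 1L
    if (any(inel)) log <- c(log, "not_eligible" = sum(inel))
    keep <- keep & !inel
  }
  for (v in vars) {
    miss <- is.na(records[[v]])
    n_miss <- sum(miss & keep)
    if (n_miss > 0) log <- c(log, stats::setNames(n_miss, v))
    keep <- keep & !miss
  }
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no records remain after eligibility filtering")
  attr(out, "exclusion_log") <- if (length(log)) log else stats::setNames(integer(0), character(0))
  out
}

#' Pool per-country surveys with de-normalized weights
#'
#' Appends per-country record collections after checking that schemas
#' (columns and category codings) agree, derives per-woman weights from
#' `v005`, de-normalizes them against the supplied country populations, and
#' returns the pooled analysis dataset.
#'
#' @param surveys either a single data frame with a `country` column or a
#'   named list of per-country data frames.
#' @param country_meta data frame with columns `country` and `total_pop`.
#' @return data frame of class `pooled_dataset` with a `pooled_weight`
#'   column and attribute `country_meta` (including eligible sample sizes).
#' @export
pool_surveys <- function(surveys, country_meta) {
  stopifnot(is.data.frame(country_meta),
            all(c("country", "total_pop") %in% names(country_meta)))
  if (is.data.frame(surveys)) {
    surveys <- split(surveys, surveys$country)
  }
  schemas <- lapply(surveys, function(d) {
    lapply(d[sort(names(d))], function(col) if (is.factor(col)) levels(col) else class(col))
  })
  ref <- schemas[[1L]]
  for (i in seq_along(schemas)[-1L]) {
    if (!identical(schemas[[i]], ref)) {
      differing <- names(ref)[!vapply(names(ref), function(nm)
        identical(schemas[[i]][[nm]], ref[[nm]]), logical(1))]
      stop(sprintf("conflicting schemas across countries (columns: %s)",
                   paste(unique(c(differing,
                                  setdiff(names(schemas[[i]]), names(ref)))),
                         collapse = ", ")))
    }
  }
  pooled <- do.call(rbind, c(lapply(surveys, as.data.frame),
                             list(make.row.names = FALSE)))
  meta <- country_meta
  meta$sample_n <- vapply(meta$country, function(cc)
    sum(pooled$country == cc), numeric(1))
  if (any(meta$sample_n == 0)) {
    stop("country_meta lists countries absent from the surveys: ",
         paste(meta$country[meta$sample_n == 0], collapse = ", "))
  }
  pw <- derive_weight(pooled$v005)
  idx <- match(pooled$country, meta$country)
  if (anyNA(idx)) {
    stop("countries without metadata: ",
         paste(unique(pooled$country[is.na(idx)]), collapse = ", "))
  }
  pooled$pooled_weight <- pw * meta$total_pop[idx] / meta$sample_n[idx]
  structure(pooled, country_meta = meta,
            class = c("pooled_dataset", "data.frame"))
}

#' Weighted country shares of a pooled dataset
#'
#' @param pooled a [pool_surveys()] result.
#' @return data.frame with per-country summed pooled weight and percentage
#'   share.
#' @export
country_shares <- function(pooled) {
  w <- tapply(pooled$pooled_weight, pooled$country, sum)
  data.frame(country = names(w),
             pooled_weight = as.numeric(w),
             share_pct = 100 * as.numeric(w) / sum(w),
             row.names = NULL)
}

#' Read a survey CSV with schema validation
#'
#' @param path CSV file with the documented column schema.
#' @return data frame with schema columns as canonical factors.
#' @export
read_survey_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("country", "v005")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop("survey file lacks required columns: ", paste(miss, collapse = ", "))
  }
  apply_schema(d)
}
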
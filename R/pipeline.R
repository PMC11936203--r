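#' Run the full inequality-analysis pipeline
#'
#' Orchestrates the stages end to end: simulate (or read) the survey, pool
#' with de-normalized weights, describe, select covariates, fit the
#' weighted logistic model, compute concentration curves and indices
#' (pooled and per country, for each requested stratifier), decompose, and
#' aggregate contributions. All artifacts are written under `config$out`
#' together with a manifest of MD5 hashes, so repeated seeded runs can be
#' compared byte for byte.
#'
#' @param config list with fields:
#'   \describe{
#'     \item{spec}{a [population_spec()] for synthetic input, or `NULL`;}
#'     \item{input, country_meta}{paths to a survey CSV and a country
#'       metadata CSV (mutually exclusive with `spec`);}
#'     \item{stratifiers}{subset of `c("wealth_quintile", "education")`;}
#'     \item{variables}{explicit covariate vector, or `"select"` to run
#'       best-subset selection over `candidates`;}
#'     \item{candidates}{optional list of candidate groups for selection;}
#'     \item{stages}{subset of
#'       `c("describe", "select", "regress", "cix", "decompose")`;}
#'     \item{by_country}{logical, per-country concentration indices;}
#'     \item{out}{output directory.}
#'   }
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out))
  has_spec <- !is.null(config$spec)
  has_input <- !is.null(config$input)
  if (has_spec == has_input) {
    stop("config must name exactly one input source: 'spec' or 'input'")
  }
  stages <- config$stages %||%
    c("describe", "select", "regress", "cix", "decompose")
  stratifiers <- config$stratifiers %||% c("wealth_quintile", "education")
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, msg) {
    message(jsonlite::toJSON(list(stage = stage, msg = msg,
                                  time = format(Sys.time(), "%H:%M:%S")),
                             auto_unbox = TRUE))
  }
  run_stage <- function(stage, expr) {
    log_stage(stage, "start")
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  results <- list()

  pooled <- run_stage("prepare", {
    if (has_spec) {
      survey <- simulate_survey(config$spec)
      meta <- config$spec$countries
    } else {
      survey <- read_survey_csv(config$input)
      meta <- utils::read.csv(config$country_meta, stringsAsFactors = FALSE)
      if (!"anc8" %in% names(survey) && "anc_visits" %in% names(survey)) {
        survey$anc8 <- recode_anc(survey$anc_visits)
      }
    }
    filtered <- filter_eligible(survey)
    p <- pool_surveys(filtered, meta[, c("country", "total_pop")])
    utils::write.csv(as.data.frame(p), file.path(config$out, "pooled.csv"),
                     row.names = FALSE)
    log <- attr(filtered, "exclusion_log")
    log_stage("prepare", paste("exclusions:",
                               paste(names(log), log, sep = "=", collapse = " ")))
    p
  })
  results$pooled <- pooled
  w <- pooled$pooled_weight

  if ("describe" %in% stages) {
    results$describe <- run_stage("describe", {
      tab <- bivariable_table(pooled)
      utils::write.csv(tab, file.path(config$out, "table_bivariable.csv"),
                       row.names = FALSE)
      shares <- country_shares(pooled)
      utils::write.csv(shares, file.path(config$out, "country_shares.csv"),
                       row.names = FALSE)
      tab
    })
  }

  variables <- config$variables %||% "select"
  if (identical(variables, "select") && "select" %in% stages) {
    results$selection <- run_stage("select", {
      cands <- config$candidates %||% default_candidates()
      sel <- best_subset_aic(pooled, cands)
      jsonlite::write_json(
        list(selected = sel$selected, table = sel$table,
             vif = as.list(sel$vif %||% list()),
             vif_summary = as.list(sel$vif_summary %||% list())),
        file.path(config$out, "selection.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      sel
    })
    variables <- results$selection$selected
  } else if (identical(variables, "select")) {
    variables <- intersect(names(anc_schema()), names(pooled))
  }

  fit <- NULL
  if (any(c("regress", "decompose") %in% stages)) {
    fit <- run_stage("regress", {
      f <- fit_weighted_logit(pooled, variables)
      utils::write.csv(f$aor, file.path(config$out, "aor_table.csv"),
                       row.names = FALSE)
      f
    })
    results$fit <- fit
  }

  if ("cix" %in% stages) {
    results$cix <- run_stage("cix", lapply(stats::setNames(stratifiers,
                                                           stratifiers),
      function(sv) {
        res <- if (isTRUE(config$by_country)) {
          cix_by_group(pooled, sv)
        } else {
          list(pooled = concentration_index(
            ranked_outcome(pooled$anc8, pooled[[sv]], w, label = sv)))
        }
        summ <- do.call(rbind, lapply(res, function(r)
          data.frame(group = r$group, cix = r$cix, se = r$se,
                     p_value = r$p_value, mu = r$mu, n = r$n)))
        utils::write.csv(summ,
                         file.path(config$out, sprintf("cix_%s.csv", sv)),
                         row.names = FALSE)
        for (r in res) {
          utils::write.csv(r$curve,
                           file.path(config$out,
                                     sprintf("curve_%s_%s.csv", sv, r$group)),
                           row.names = FALSE)
        }
        res
      }))
  }

  if ("decompose" %in% stages) {
    results$decomposition <- run_stage("decompose",
      lapply(stats::setNames(stratifiers, stratifiers), function(sv) {
        rk <- ranked_outcome(pooled$anc8, pooled[[sv]], w, label = sv)
        dec <- decompose_cix(fit, rk)
        render_decomposition_csv(dec,
          file.path(config$out, sprintf("decomposition_%s.csv", sv)))
        agg <- aggregate_contributions(dec)
        jsonlite::write_json(as.list(agg),
          file.path(config$out, sprintf("contributions_%s.json", sv)),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
        dec
      }))
  }

  files <- sort(setdiff(list.files(config$out, full.names = TRUE),
                        file.path(config$out, "manifest.json")))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  log_stage("done", sprintf("%d artifacts", nrow(manifest)))
  invisible(results)
}

# A small, fixed candidate ladder mirroring the idea of best-variable
# selection without exhaustively enumerating all 2^16 subsets: nested
# groups from stratifiers-only to the full covariate list.
default_candidates <- function() {
  core <- c("wealth_quintile", "education")
  mid <- c(core, "age_band", "employed", "parity", "residence")
  big <- c(mid, "marital", "insurance", "media_newspaper", "media_radio",
           "internet", "barrier_permission", "barrier_distance", "head_sex")
  list(core, mid, big)
}

# Decomposition CSV in published column order, with explicit reference rows.
render_decomposition_csv <- function(dec, path) {
  stopifnot(inherits(dec, "cix_decomposition"))
  sch <- anc_schema()
  rows <- list()
  for (v in unique(dec$variable)) {
    ref <- if (v %in% names(sch)) sch[[v]][1L] else "(reference)"
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, category = ref, elasticity = NA_real_, cix = NA_real_,
      abs_contribution = NA_real_, pct_contribution = NA_real_,
      note = "Reference", stringsAsFactors = FALSE)
    sub <- dec[dec$variable == v, , drop = FALSE]
    sub$note <- ""
    rows[[length(rows) + 1L]] <- as.data.frame(sub)
  }
  out <- do.call(rbind, rows)
  out[c("elasticity", "cix", "abs_contribution", "pct_contribution")] <-
    lapply(out[c("elasticity", "cix", "abs_contribution",
                 "pct_contribution")], round, 3L)
  out <- rbind(out, data.frame(
    variable = "residual", category = "Residual concentration index",
    elasticity = NA_real_, cix = NA_real_,
    abs_contribution = round(attr(dec, "residual"), 3L),
    pct_contribution = round(attr(dec, "residual_pct"), 3L), note = "",
    stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Format a p-value in survey-report style
#'
#' Four decimal places with a "< 0.0001" floor.
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 1e-4, "< 0.0001", sprintf("%.4f", p)))
}
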
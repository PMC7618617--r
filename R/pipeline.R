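#' Assemble the analytic dataset
#'
#' Joins covariates, SRI results and the adiposity panel into one analytic
#' table: computes the index panel from anthropometry, winsorizes BMI, WC,
#' total fat mass, percent fat and SAD at the 1st/99th percentiles, and
#' halves the survey weights to combine the two survey cycles.
#'
#' @param covariates covariate table (with `survey_weight`).
#' @param sri table with `participant_id`, `sri_final`, `quintile`.
#' @param anthro anthropometry table (see [compute_indices()]).
#' @param combine_cycles number of survey cycles pooled into the weights.
#' @return `data.table` of analytic records.
#' @export
make_analytic <- function(covariates, sri, anthro, combine_cycles = 2L) {
  panel <- data.table::as.data.table(compute_indices(anthro))
  for (v in c("bmi", "wc", "fat_mass", "pct_fat", "sad")) {
    panel[[v]] <- winsorize_percentile(panel[[v]])$values
  }
  cov <- data.table::as.data.table(covariates)
  out <- merge(cov, data.table::as.data.table(sri), by = "participant_id")
  out <- merge(out, panel, by = "participant_id")
  out$survey_weight <- combine_cycle_weights(out$survey_weight, combine_cycles)
  out[]
}

#' Run configuration for the end-to-end pipeline
#'
#' @param n_participants cohort size of the synthetic run.
#' @param out_dir artifact directory.
#' @param generator named list of [generator_config()] overrides.
#' @param null_sims Monte-Carlo null simulation size.
#' @param models model ids to fit.
#' @param outcomes outcome columns to model.
#' @param B bootstrap resamples for the MF tables.
#' @param seeds named integer seeds (`generator`, `null`, `bootstrap`).
#' @param weighted fit with survey weights.
#' @param unweighted_sensitivity also refit MF tables with unit weights.
#' @param meal_sensitivity run the meal-timing complete-case refit.
#' @param impute kNN-impute covariates before modelling.
#' @param curves fit the continuous-SRI model and emit prediction curves
#'   (needs enough participants per ethnicity-sex cell).
#' @export
run_config <- function(n_participants = 600L, out_dir = tempfile("sleepreg_run_"),
                       generator = list(), null_sims = 100000L,
                       models = c(1, 2, 3, 4), outcomes = "bmi", B = 200L,
                       seeds = c(generator = 1L, null = 2L, bootstrap = 3L),
                       weighted = TRUE, unweighted_sensitivity = FALSE,
                       meal_sensitivity = FALSE, impute = TRUE, curves = TRUE) {
  stopifnot(all(c("generator", "null", "bootstrap") %in% names(seeds)))
  structure(
    list(n_participants = as.integer(n_participants), out_dir = out_dir,
         generator = generator, null_sims = as.integer(null_sims),
         models = models, outcomes = outcomes, B = as.integer(B),
         seeds = seeds, weighted = weighted,
         unweighted_sensitivity = unweighted_sensitivity,
         meal_sensitivity = meal_sensitivity, impute = impute,
         curves = curves),
    class = "run_config")
}

#' Run the full pipeline end-to-end on a synthetic cohort
#'
#' Stages, in order: synthetic cohort generation (minute epochs +
#' covariates), actigraphy QC, SRI computation with null-based
#' winsorization, quintile assignment, outcome generation from the recorded
#' truth, adiposity panel, optional kNN imputation, survey-weighted models
#' with MF tables, interaction and trend tests, and continuous-SRI
#' prediction curves. Artifacts are written under `config$out_dir`:
#' `descriptives.csv` (quintile-stratified, unweighted), `panel_summary.csv`,
#' `mf_table.csv`, `ledger.json`, `curves.csv` and `manifest.json` (seeds,
#' row counts per stage, exclusion ledger). Deterministic under fixed
#' seeds.
#'
#' @param config a [run_config()].
#' @return list with the analytic table, fits, MF tables, tests, curves,
#'   ledger and manifest (invisibly also written to disk).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[sleepreg] stage %s", name))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  gen_args <- modifyList(
    list(n_participants = config$n_participants,
         seed = unname(config$seeds[["generator"]])),
    config$generator)
  gcfg <- stage("synth", do.call(generator_config, gen_args))
  cohort <- stage("synth", generate_cohort(gcfg, detail = "epochs"))

  qc <- stage("qc", qc_pipeline(cohort$epochs))

  null <- stage("sri", simulate_null(n_sims = config$null_sims,
                                     seed = unname(config$seeds[["null"]])))
  sri_raw <- stage("sri", vapply(qc$series, function(s) compute_sri(s)$sri_raw,
                                 numeric(1)))
  wins <- stage("sri", winsorize_sri(sri_raw, null,
                                     seed = unname(config$seeds[["null"]]) + 1L))
  qs <- stage("sri", assign_quintiles(wins$sri_final))
  sri_dt <- data.table::data.table(
    participant_id = names(qc$series), sri_raw = sri_raw,
    sri_final = wins$sri_final, winsorized = wins$winsorized,
    quintile = qs$quintile)

  retained <- stage("outcomes", {
    idx <- match(sri_dt$participant_id, cohort$covariates$participant_id)
    cohort$covariates[idx, ]
  })
  anthro <- stage("outcomes",
    generate_outcomes(retained, sri_dt$quintile, cohort$truth, gcfg))

  analytic <- stage("panel", make_analytic(retained, sri_dt, anthro))
  if (config$impute) {
    analytic <- stage("impute", {
      keep <- c("participant_id", "survey_weight", "age", names(.cov_levels),
                "vitamin_d", "kcal", "phq9", "activity")
      imp <- knn_impute(as.data.frame(analytic)[keep])
      for (v in setdiff(keep, c("participant_id", "survey_weight"))) {
        analytic[[v]] <- imp[[v]]
      }
      analytic
    })
  }

  fits <- list(); mf_tables <- list()
  all_strata <- expand.grid(ethnicity = .ethnicities, sex = .sexes,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (out_name in config$outcomes) {
    for (m in config$models) {
      key <- paste0(out_name, "_m", m)
      strata <- switch(as.character(m),
                       "3" = data.frame(sex = .sexes),
                       "4" = all_strata,
                       NULL)
      fits[[key]] <- stage("models",
        fit_model(analytic, m, out_name, weighted = config$weighted))
      mf_tables[[key]] <- stage("models", {
        tab <- if (config$B > 0) {
          mf_with_ci(analytic, m, out_name, strata = strata, B = config$B,
                     seed = unname(config$seeds[["bootstrap"]]),
                     weighted = config$weighted)
        } else {
          multiplication_factors(fits[[key]], strata)
        }
        tab$outcome <- out_name
        tab
      })
    }
  }

  tests <- stage("tests", {
    out1 <- config$outcomes[1]
    res <- list(trend = trend_test(analytic, model_id = 2, outcome = out1,
                                   weighted = config$weighted))
    if (all(c(2, 3) %in% config$models)) {
      res$sex <- interaction_test(fits[[paste0(out1, "_m3")]],
                                  fits[[paste0(out1, "_m2")]])
    }
    if (all(c(3, 4) %in% config$models)) {
      res$ethnicity <- interaction_test(fits[[paste0(out1, "_m4")]],
                                        fits[[paste0(out1, "_m3")]])
    }
    res
  })

  curves <- NULL
  if (config$curves) {
    curves <- stage("curves", {
      fit_c <- fit_model(analytic, "4c", config$outcomes[1],
                         weighted = config$weighted)
      prof <- covariate_profile(analytic)
      predict_curve(fit_c, prof, sri_grid = seq(0, 100, 5))
    })
  }

  sens <- NULL
  if (config$meal_sensitivity) {
    sens <- stage("meal_sensitivity",
      sensitivity_meal_timing(analytic, outcome = config$outcomes[1],
                              weighted = config$weighted))
  }
  unw <- NULL
  if (config$unweighted_sensitivity) {
    unw <- stage("unweighted", {
      f <- fit_model(analytic, max(config$models), config$outcomes[1],
                     weighted = FALSE)
      multiplication_factors(f, all_strata)
    })
  }

  descr <- stage("descriptives", .describe_by_quintile(analytic))
  mf_all <- data.table::rbindlist(mf_tables, fill = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sleepreg")),
    seeds = as.list(config$seeds),
    n_input = config$n_participants,
    n_retained = length(qc$series),
    n_analytic = nrow(analytic),
    exclusion_ledger = unclass(qc$ledger),
    null = unclass(null)[c("n_sims", "mean", "sd", "q005", "q995", "cutoff")],
    n_winsorized_sri = wins$n_replaced,
    models = config$models, outcomes = config$outcomes, B = config$B)

  out_dir <- config$out_dir
  data.table::fwrite(descr$covariates, file.path(out_dir, "descriptives.csv"))
  data.table::fwrite(descr$panel, file.path(out_dir, "panel_summary.csv"))
  data.table::fwrite(mf_all, file.path(out_dir, "mf_table.csv"))
  if (!is.null(curves)) {
    data.table::fwrite(curves$curves, file.path(out_dir, "curves.csv"))
  }
  jsonlite::write_json(unclass(qc$ledger), file.path(out_dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(analytic = analytic, fits = fits, mf_tables = mf_tables,
                 mf_table = mf_all, tests = tests, curves = curves,
                 sensitivity = sens, unweighted = unw, ledger = qc$ledger,
                 null = null, truth = cohort$truth, manifest = manifest,
                 descriptives = descr))
}

# unweighted quintile-stratified descriptives: medians/IQR for continuous,
# counts/percent for categorical; panel measures summarised the same way
.describe_by_quintile <- function(analytic) {
  a <- as.data.frame(analytic)
  q <- a$quintile
  cont <- c("sri_final", "age", "vitamin_d", "kcal", "phq9", "activity")
  cat_ <- names(.cov_levels)
  fmt_cont <- function(x, by) {
    vapply(split(x, by), function(v) {
      sprintf("%.1f (%.1f, %.1f)", median(v, na.rm = TRUE),
              quantile(v, 0.25, na.rm = TRUE), quantile(v, 0.75, na.rm = TRUE))
    }, character(1))
  }
  qrow <- function(head, vals) {
    cbind(head, setNames(as.data.frame(as.list(unname(vals)),
                                       stringsAsFactors = FALSE),
                         paste0("Q", 1:5)))
  }
  rows <- list()
  for (v in cont) {
    rows[[v]] <- qrow(data.frame(variable = v, level = ""),
                      fmt_cont(a[[v]], q))
  }
  for (v in cat_) {
    tab <- table(a[[v]], q)
    pct <- prop.table(tab, 2) * 100
    for (l in rownames(tab)) {
      rows[[paste(v, l)]] <- qrow(data.frame(variable = v, level = l),
                                  sprintf("%d (%.1f%%)", tab[l, ], pct[l, ]))
    }
  }
  cov_tab <- do.call(rbind, rows)
  rownames(cov_tab) <- NULL
  panel_vars <- c("bmi", "wc", "absi", "whtr", "sad", "sadhtr", "vai",
                  "fat_mass", "fmi", "pct_fat", "bri", "lap")
  prow <- lapply(panel_vars, function(v) {
    r <- qrow(data.frame(measure = v), fmt_cont(a[[v]], q))
    r$missing_pct <- 100 * mean(is.na(a[[v]]))
    r
  })
  panel_tab <- do.call(rbind, prow)
  rownames(panel_tab) <- NULL
  list(covariates = cov_tab, panel = panel_tab)
}
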
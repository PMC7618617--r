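#' Synthetic cohort generator
#'
#' Generates minute-level actigraphy series, covariates, survey weights and
#' anthropometry with the statistical structure the downstream analysis
#' assumes, together with a [synthetic truth][make_truth] object recording
#' the quintile-contrast multiplication factors and covariate effects used,
#' so that every pipeline stage can be validated against known ground truth.
#'
#' @name synthetic_cohort
NULL

.ethnicities <- c("Mexican American", "Other Hispanic", "Non-Hispanic White",
                  "Non-Hispanic Black", "Non-Hispanic Asian",
                  "Other Race - Including Multi-Racial")
.sexes <- c("Male", "Female")

# marginal category mixes for the covariate table (loosely matched to the
# population the generator emulates; proportions bounded away from 0)
.cov_levels <- list(
  ethnicity = list(levels = .ethnicities,
                   p = c(0.12, 0.096, 0.41, 0.234, 0.11, 0.03)),
  sex = list(levels = .sexes, p = c(0.47, 0.53)),
  education = list(levels = c("LessThan9th", "Grade9to11", "HighSchool",
                              "SomeCollege", "CollegeGrad"),
                   p = c(0.091, 0.137, 0.221, 0.30, 0.251)),
  income = list(levels = c("Under20k", "Over20k"), p = c(0.23, 0.77)),
  occupation = list(levels = c("Working", "RetiredOrStudent", "UnableToWork",
                               "Unemployed", "Other"),
                    p = c(0.515, 0.237, 0.178, 0.046, 0.024)),
  marital = list(levels = c("Married", "Widowed", "Divorced", "Separated",
                            "NeverMarried", "LivingWithPartner"),
                 p = c(0.509, 0.091, 0.116, 0.033, 0.183, 0.068)),
  alcohol = list(levels = c("Heavy", "Moderate", "NeverNon"),
                 p = c(0.025, 0.802, 0.173)),
  smoking = list(levels = c("Heavy", "Light", "Moderate", "Non", "Previous"),
                 p = c(0.109, 0.064, 0.019, 0.561, 0.247))
)

#' Default true multiplication-factor grid
#'
#' Per (ethnicity, sex) stratum, the true multiplicative effect on expected
#' BMI of being in quintile Qj of sleep regularity versus Q1, for j = 2..5.
#' The default grid spans MFs from roughly 0.88 to 1.04, with inverse
#' associations concentrated among women, strongest for non-Hispanic white
#' and other/multi-racial women, and near-null to slightly positive effects
#' among Mexican American and non-Hispanic black men.
#'
#' @return data.frame with columns `ethnicity`, `sex`, `quintile`
#'   ("Q2".."Q5") and `mf` (> 0).
#' @export
default_true_mf <- function() {
  g <- rbind(
    c(1.015, 1.024, 1.032, 1.040), c(0.992, 0.987, 0.984, 0.980),
    c(0.997, 0.995, 0.993, 0.991), c(0.974, 0.959, 0.947, 0.934),
    c(0.987, 0.980, 0.973, 0.967), c(0.964, 0.945, 0.928, 0.910),
    c(1.014, 1.021, 1.028, 1.036), c(0.990, 0.985, 0.980, 0.975),
    c(0.992, 0.987, 0.984, 0.979), c(0.969, 0.952, 0.938, 0.922),
    c(0.975, 0.961, 0.949, 0.937), c(0.952, 0.927, 0.905, 0.882))
  data.frame(
    ethnicity = rep(rep(.ethnicities, each = 2), times = 4),
    sex = rep(rep(.sexes, times = 6), times = 4),
    quintile = rep(paste0("Q", 2:5), each = 12),
    mf = as.vector(g))
}

#' Uniform-by-sex multiplication-factor grid
#'
#' A simplified truth grid in which the Q5-vs-Q1 multiplication factor
#' depends on sex only, with geometric interpolation across the
#' intermediate quintiles (log-linear in quintile rank).
#'
#' @param female_q5,male_q5 Q5-vs-Q1 MFs by sex.
#' @export
uniform_true_mf <- function(female_q5 = 0.92, male_q5 = 0.98) {
  stopifnot(female_q5 > 0, male_q5 > 0)
  grid <- expand.grid(ethnicity = .ethnicities, sex = .sexes,
                      quintile = paste0("Q", 2:5),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  q5 <- ifelse(grid$sex == "Female", female_q5, male_q5)
  step <- (as.integer(substring(grid$quintile, 2)) - 1) / 4
  grid$mf <- q5^step
  grid
}

#' Generator configuration
#'
#' Bundles and validates every knob of the synthetic cohort.
#'
#' @param n_participants cohort size.
#' @param n_days days of actigraphy per participant.
#' @param onset_jitter_sd SD (minutes) of the Normal jitter applied to each
#'   night's sleep onset and offset; 0 gives perfectly regular sleep. In
#'   cohort mode each participant's own jitter SD is drawn around this
#'   scale so the cohort spans the full SRI range.
#' @param sleep_duration_mean nightly sleep duration (minutes).
#' @param nonwear_rate per-minute probability of an injected non-wear or
#'   unknown epoch.
#' @param covariate_missingness named fractions (<= 0.30) of
#'   missing-completely-at-random cells per covariate.
#' @param true_mf multiplication-factor grid, see [default_true_mf()].
#' @param residual_sd_logbmi residual SD of log BMI.
#' @param weight_distribution named family for survey weights:
#'   `list(family = "lognormal", meanlog, sdlog)`, `"gamma"` (shape, rate)
#'   or `"constant"` (value).
#' @param seed integer master seed; regeneration with the same seed is
#'   bit-identical.
#' @param start_weekday weekday label of day 1.
#' @param sleep_model `"block"` (one consolidated jittered nightly block)
#'   or `"iid"` (each minute independently asleep with `p_sleep`).
#' @param p_sleep sleep probability for the `"iid"` model.
#' @param age_effect_logbmi slope of log BMI in age (per year, age centred
#'   at 50); the only non-zero covariate effect by default.
#' @param fat_mass_missingness fraction of participants without DXA fat
#'   mass.
#' @param meal_missingness fraction missing the meal-timing fields.
#' @export
generator_config <- function(n_participants,
                             n_days = 7L,
                             onset_jitter_sd = 45,
                             sleep_duration_mean = 480,
                             nonwear_rate = 0.03,
                             covariate_missingness = c(alcohol = 0.24),
                             true_mf = default_true_mf(),
                             residual_sd_logbmi = 0.22,
                             weight_distribution = list(family = "lognormal",
                                                        meanlog = 0, sdlog = 0.5),
                             seed = 1L,
                             start_weekday = "Mon",
                             sleep_model = c("block", "iid"),
                             p_sleep = 0.5,
                             age_effect_logbmi = 0.002,
                             fat_mass_missingness = 0.49,
                             meal_missingness = 0.38) {
  sleep_model <- match.arg(sleep_model)
  stopifnot(n_participants >= 1, n_days >= 1, onset_jitter_sd >= 0,
            sleep_duration_mean > 0, nonwear_rate >= 0, nonwear_rate <= 1,
            residual_sd_logbmi >= 0, fat_mass_missingness >= 0,
            fat_mass_missingness <= 1, p_sleep >= 0, p_sleep <= 1,
            start_weekday %in% .weekdays)
  if (length(covariate_missingness) &&
      (any(covariate_missingness < 0) || any(covariate_missingness > 0.30))) {
    stop("covariate missingness fractions must lie in [0, 0.30]")
  }
  if (any(true_mf$mf <= 0)) stop("true multiplication factors must be positive")
  stopifnot(all(c("ethnicity", "sex", "quintile", "mf") %in% names(true_mf)))
  structure(
    list(n_participants = as.integer(n_participants), n_days = as.integer(n_days),
         onset_jitter_sd = onset_jitter_sd,
         sleep_duration_mean = sleep_duration_mean, nonwear_rate = nonwear_rate,
         covariate_missingness = covariate_missingness, true_mf = true_mf,
         residual_sd_logbmi = residual_sd_logbmi,
         weight_distribution = weight_distribution, seed = as.integer(seed),
         start_weekday = start_weekday, sleep_model = sleep_model,
         p_sleep = p_sleep, age_effect_logbmi = age_effect_logbmi,
         fat_mass_missingness = fat_mass_missingness,
         meal_missingness = meal_missingness),
    class = "generator_config")
}

#' Ground truth of the generator
#'
#' Records, before any noise is added, everything needed to predict the
#' expected log BMI of a participant exactly: the intercept, the
#' (ethnicity, sex, quintile) multiplication-factor grid and the covariate
#' coefficients. Immutable by convention.
#'
#' @param config a [generator_config()].
#' @export
make_truth <- function(config) {
  structure(
    list(intercept_logbmi = log(29), age_center = 50,
         age_effect = config$age_effect_logbmi,
         mf = config$true_mf, residual_sd = config$residual_sd_logbmi),
    class = "synthetic_truth")
}

#' Expected log BMI under the generator truth
#'
#' @param truth a [make_truth()] object.
#' @param covariates data.frame with `age`, `sex`, `ethnicity`.
#' @param quintile quintile labels "Q1".."Q5".
#' @export
predict_truth <- function(truth, covariates, quintile) {
  log_mf <- numeric(nrow(covariates))
  q <- as.character(quintile)
  idx <- q != "Q1"
  if (any(idx)) {
    key <- paste(covariates$ethnicity[idx], covariates$sex[idx], q[idx])
    mf_key <- paste(truth$mf$ethnicity, truth$mf$sex, truth$mf$quintile)
    m <- match(key, mf_key)
    if (anyNA(m)) stop("quintile/stratum combination absent from truth grid")
    log_mf[idx] <- log(truth$mf$mf[m])
  }
  truth$intercept_logbmi + log_mf +
    truth$age_effect * (covariates$age - truth$age_center)
}

.participant_seed <- function(config, index, salt = 0L) {
  (config$seed * 10007L + salt * 271L + as.integer(index)) %% 2147483647L
}

#' Generate one participant's minute-epoch sleep series
#'
#' Block model: one consolidated nightly sleep block per night; each
#' night's onset and offset equal the base schedule (onset 23:00, offset
#' onset + nightly duration) plus independent Normal(0, `onset_jitter_sd`)
#' jitter. The night preceding day 1 is included so that under zero jitter
#' all days are identical. Non-wear/unknown minutes are injected
#' independently per minute at `nonwear_rate`.
#'
#' @param config a [generator_config()].
#' @param participant_index 1-based index (seeds the participant's stream).
#' @param jitter_sd optional override of `config$onset_jitter_sd` for this
#'   participant.
#' @return `data.table` of `n_days * 1440` epoch records with columns
#'   `participant_id`, `day_index`, `weekday`, `minute_of_day`, `state`,
#'   `quality_flagged`, `seconds_measured`.
#' @export
generate_sleep_series <- function(config, participant_index,
                                  jitter_sd = config$onset_jitter_sd) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.participant_seed(config, participant_index, salt = 1L))
  n_days <- config$n_days
  total <- n_days * 1440L
  sleep <- integer(total)
  if (config$sleep_model == "iid") {
    sleep <- rbinom(total, 1L, config$p_sleep)
  } else {
    base_onset <- 1380  # 23:00
    for (night in 0:n_days) {
      onset <- (night - 1) * 1440 + base_onset + rnorm(1, 0, jitter_sd)
      offset <- (night - 1) * 1440 + base_onset + config$sleep_duration_mean +
        rnorm(1, 0, jitter_sd)
      a <- max(0L, as.integer(floor(onset)))
      b <- min(total, as.integer(floor(offset)))
      if (b > a) sleep[(a + 1L):b] <- 1L
    }
  }
  state <- ifelse(sleep == 1L, "sleep", "wake")
  if (config$nonwear_rate > 0) {
    u <- runif(total)
    state[u < 0.9 * config$nonwear_rate] <- "nonwear"
    state[u >= 0.9 * config$nonwear_rate & u < config$nonwear_rate] <- "unknown"
  }
  wd_start <- match(config$start_weekday, .weekdays)
  data.table::data.table(
    participant_id = sprintf("P%05d", participant_index),
    day_index = rep(seq_len(n_days), each = 1440L),
    weekday = rep(.weekdays[((wd_start - 1L + seq_len(n_days) - 1L) %% 7L) + 1L],
                  each = 1440L),
    minute_of_day = rep(0:1439, times = n_days),
    state = state,
    quality_flagged = FALSE,
    seconds_measured = 60L)
}

#' Generate the covariate table and survey weights
#'
#' Categorical covariates are drawn from fixed marginal mixes, continuous
#' covariates (age, vitamin D, caloric intake, PHQ-9 depression score,
#' activity level) from skew-matched families, survey weights from the
#' configured family (lognormal with median 1 by default, mimicking unequal
#' selection probabilities). Missingness is injected completely at random
#' at the configured per-covariate rates; meal-timing fields (weekday vs
#' weekend differences in last-meal timing and eating window, hours) carry
#' their own missingness fraction.
#'
#' @param config a [generator_config()].
#' @return `data.table`, one row per participant.
#' @export
generate_covariates <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.participant_seed(config, 0L, salt = 2L))
  n <- config$n_participants
  draw_cat <- function(spec) {
    factor(sample(spec$levels, n, replace = TRUE, prob = spec$p),
           levels = spec$levels)
  }
  cov <- data.table::data.table(participant_id = sprintf("P%05d", seq_len(n)))
  for (nm in names(.cov_levels)) cov[[nm]] <- draw_cat(.cov_levels[[nm]])
  cov$age <- round(pmin(80, pmax(20, 20 + 60 * rbeta(n, 1.25, 1.1))))
  cov$vitamin_d <- rlnorm(n, log(63), 0.4)
  cov$kcal <- rlnorm(n, log(1917), 0.42)
  cov$phq9 <- pmin(27, stats::rnbinom(n, size = 1.2, mu = 3))
  cov$activity <- rlnorm(n, log(7.7), 0.55)
  cov$last_meal_diff <- rnorm(n, 0, 1.5)
  cov$eating_window_diff <- rnorm(n, 0, 2)
  wd <- config$weight_distribution
  cov$survey_weight <- switch(wd$family,
    lognormal = rlnorm(n, wd$meanlog %||% 0, wd$sdlog %||% 0.5),
    gamma = stats::rgamma(n, shape = wd$shape, rate = wd$rate),
    constant = rep(wd$value %||% 1, n),
    stop("unknown weight family: ", wd$family))
  for (nm in names(config$covariate_missingness)) {
    if (!nm %in% names(cov)) stop("unknown covariate in missingness map: ", nm)
    r <- config$covariate_missingness[[nm]]
    if (r > 0) cov[[nm]][runif(n) < r] <- NA
  }
  if (config$meal_missingness > 0) {
    gone <- runif(n) < config$meal_missingness
    cov$last_meal_diff[gone] <- NA
    cov$eating_window_diff[gone] <- NA
  }
  cov[]
}

#' Generate anthropometry and lipids with log-linear BMI structure
#'
#' log(BMI) = intercept + log(true MF of the participant's quintile within
#' their ethnicity-sex stratum) + covariate effects + Normal(0,
#' `residual_sd_logbmi`). Height, weight, waist circumference, sagittal
#' abdominal diameter, fat mass, triglycerides and HDL are generated
#' conditionally on BMI so the panel has realistic correlation structure
#' (corr(BMI, WC) >= 0.85 at n >= 2,000).
#'
#' @param covariates table from [generate_covariates()].
#' @param quintile quintile labels "Q1".."Q5" per participant.
#' @param truth a [make_truth()] object.
#' @param config a [generator_config()].
#' @return `data.table` of anthropometry columns (`weight_kg`, `height_m`,
#'   `wc_cm`, `sad_cm`, `tg_mmol_l`, `hdl_mmol_l`, `fat_mass_kg`, `sex`).
#' @export
generate_outcomes <- function(covariates, quintile, truth, config) {
  if (any(truth$mf$mf <= 0)) stop("true multiplication factors must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.participant_seed(config, 0L, salt = 3L))
  n <- nrow(covariates)
  stopifnot(length(quintile) == n)
  mu <- predict_truth(truth, covariates, quintile)
  log_bmi <- mu + rnorm(n, 0, truth$residual_sd)
  bmi <- exp(log_bmi)
  male <- covariates$sex == "Male"
  height <- ifelse(male, rnorm(n, 1.77, 0.07), rnorm(n, 1.63, 0.065))
  height <- pmin(2.1, pmax(1.35, height))
  weight <- bmi * height^2
  wc <- -8 + 2.2 * bmi + 6 * male + rnorm(n, 0, 4)
  sad <- 0.235 * wc + rnorm(n, 0, 1.5)
  pct_fat <- pmin(60, pmax(8,
    1.2 * bmi + 0.23 * covariates$age - 10.8 * male - 5.4 + rnorm(n, 0, 3)))
  fat_mass <- pct_fat / 100 * weight
  if (config$fat_mass_missingness > 0) {
    fat_mass[runif(n) < config$fat_mass_missingness] <- NA
  }
  tg <- exp(0.35 + 0.012 * (wc - 98) + rnorm(n, 0, 0.45))
  hdl <- exp(0.30 - 0.006 * (wc - 98) + 0.10 * !male + rnorm(n, 0, 0.25))
  data.table::data.table(
    participant_id = covariates$participant_id,
    sex = covariates$sex,
    weight_kg = weight, height_m = height, wc_cm = wc, sad_cm = sad,
    tg_mmol_l = tg, hdl_mmol_l = hdl, fat_mass_kg = fat_mass)
}

#' Generate a full synthetic cohort
#'
#' `detail = "latent"` skips minute-level actigraphy: each participant's
#' SRI is drawn directly from a latent regularity distribution (Beta-shaped,
#' spanning roughly 0-95 with median near 60 and negative skew), quintiles
#' are assigned, and outcomes generated — the fast path for validating the
#' modelling stages. `detail = "epochs"` additionally generates the
#' minute-epoch records (per-participant jitter SDs drawn lognormally
#' around `onset_jitter_sd` so the cohort spans the SRI range); the SRI is
#' then obtained by running the QC and SRI stages on those epochs, and
#' outcomes are generated afterwards via [generate_outcomes()].
#'
#' @param config a [generator_config()].
#' @param detail `"latent"` or `"epochs"`.
#' @return list with `covariates`, `truth`, and either `sri`/`anthro`
#'   (latent; `sri` has `participant_id`, `sri_final`, `quintile`) or
#'   `epochs` (epochs mode).
#' @export
generate_cohort <- function(config, detail = c("latent", "epochs")) {
  detail <- match.arg(detail)
  covariates <- generate_covariates(config)
  truth <- make_truth(config)
  if (detail == "latent") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(.participant_seed(config, 0L, salt = 4L))
    sri <- 95 * rbeta(config$n_participants, 4.2, 2.6)
    qs <- assign_quintiles(sri)
    anthro <- generate_outcomes(covariates, qs$quintile, truth, config)
    sri_dt <- data.table::data.table(
      participant_id = covariates$participant_id,
      sri_final = sri, quintile = qs$quintile)
    list(covariates = covariates, truth = truth, sri = sri_dt,
         anthro = anthro, quintile_medians = qs$medians)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(.participant_seed(config, 0L, salt = 5L))
    jit <- rlnorm(config$n_participants,
                  log(config$onset_jitter_sd + 1e-9), 0.9)
    if (config$onset_jitter_sd == 0) jit <- rep(0, config$n_participants)
    epochs <- data.table::rbindlist(lapply(seq_len(config$n_participants),
      function(i) generate_sleep_series(config, i, jitter_sd = jit[i])))
    list(covariates = covariates, truth = truth, epochs = epochs,
         jitter_sd = jit)
  }
}

#' Write cohort inputs as CSV plus a truth JSON
#'
#' Writes `epochs.csv` (when present), `covariates.csv`, `anthro.csv` and
#' `truth.json` into `dir`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$epochs)) {
    data.table::fwrite(cohort$epochs, file.path(dir, "epochs.csv"))
  }
  data.table::fwrite(cohort$covariates, file.path(dir, "covariates.csv"))
  if (!is.null(cohort$anthro)) {
    data.table::fwrite(cohort$anthro, file.path(dir, "anthro.csv"))
  }
  truth <- cohort$truth
  jsonlite::write_json(
    list(intercept_logbmi = truth$intercept_logbmi,
         age_center = truth$age_center, age_effect = truth$age_effect,
         residual_sd = truth$residual_sd, mf = truth$mf),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
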
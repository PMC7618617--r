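test_that("config validation rejects out-of-range settings", {
  expect_error(generator_config(10, covariate_missingness = c(alcohol = 0.4)),
               "0.30")
  expect_error(generator_config(10, nonwear_rate = 1.2))
  tm <- uniform_true_mf(0.9, 0.9); tm$mf[1] <- -1
  expect_error(generator_config(10, true_mf = tm), "positive")
  expect_error(generator_config(10, n_days = 0))
})

test_that("zero jitter and zero non-wear give SRI exactly 100", {
  cfg <- generator_config(3, onset_jitter_sd = 0, nonwear_rate = 0, seed = 2)
  for (i in 1:3) {
    ep <- generate_sleep_series(cfg, i)
    expect_equal(nrow(ep), 7 * 1440)
    vals <- recode_state(ep$state, ep$quality_flagged, ep$seconds_measured)
    expect_equal(compute_sri(vals)$sri_raw, 100)
  }
})

test_that("i.i.d. random sleep yields SRI near zero for essentially all participants", {
  cfg <- generator_config(300, sleep_model = "iid", p_sleep = 0.5,
                          nonwear_rate = 0, seed = 4)
  sris <- vapply(1:300, function(i) {
    ep <- generate_sleep_series(cfg, i)
    compute_sri(recode_state(ep$state))$sri_raw
  }, numeric(1))
  # 7-day null SD is 200*sqrt(0.25/(6*1440)) ~ 1.08; +-8 is > 7 SDs out
  expect_gte(mean(abs(sris) <= 8), 0.99)
  expect_lt(abs(mean(sris)), 0.5)
})

test_that("mean SRI decreases in onset jitter (Monte-Carlo, 500 replicates per level)", {
  mean_sri <- function(jitter, n = 500) {
    cfg <- generator_config(n, onset_jitter_sd = jitter, nonwear_rate = 0.02,
                            n_days = 4, seed = 17)
    mean(vapply(seq_len(n), function(i) {
      ep <- generate_sleep_series(cfg, i)
      compute_sri(recode_state(ep$state))$sri_raw
    }, numeric(1)))
  }
  m10 <- mean_sri(10); m45 <- mean_sri(45); m120 <- mean_sri(120)
  expect_gt(m10, m45)
  expect_gt(m45, m120)
})

test_that("each day contains 1440 epochs and the series includes a weekend day", {
  cfg <- generator_config(2, n_days = 7, seed = 9)
  ep <- generate_sleep_series(cfg, 1)
  expect_true(all(table(ep$day_index) == 1440L))
  expect_equal(length(unique(ep$day_index)), 7L)
  expect_true(any(ep$weekday %in% c("Sat", "Sun")))
  # configurable start day still yields exactly 1440 epochs/day
  cfg2 <- generator_config(1, n_days = 3, start_weekday = "Fri", seed = 9)
  ep2 <- generate_sleep_series(cfg2, 1)
  expect_identical(unique(ep2$weekday), c("Fri", "Sat", "Sun"))
})

test_that("covariate generation honours missingness settings and category support", {
  cfg0 <- generator_config(400, covariate_missingness = c(),
                           meal_missingness = 0, seed = 6)
  cov0 <- generate_covariates(cfg0)
  expect_false(anyNA(cov0))
  expect_true(all(cov0$survey_weight > 0))

  cfg <- generator_config(7000, covariate_missingness = c(alcohol = 0.24),
                          seed = 6)
  cov <- generate_covariates(cfg)
  expect_equal(mean(is.na(cov$alcohol)), 0.24, tolerance = 0.02)

  cfg2 <- generator_config(7085, seed = 8)
  cov2 <- generate_covariates(cfg2)
  expect_equal(length(table(cov2$ethnicity)), 6L)
  expect_true(all(table(cov2$ethnicity) > 0))
})

test_that("outcome generation recovers the configured geometric-mean ratio", {
  # truth MF(Q5 vs Q1) = 0.91, covariates balanced (no age effect)
  la <- latent_analytic(50000, true_mf = uniform_true_mf(0.91, 0.91),
                        seed = 13, age_effect_logbmi = 0)
  an <- la$analytic
  gm <- tapply(log(an$bmi), an$quintile, mean)
  expect_equal(exp(gm[["Q5"]] - gm[["Q1"]]), 0.91, tolerance = 0.02)
})

test_that("zero residual noise makes BMI a deterministic function of covariates and truth", {
  cfg <- generator_config(200, true_mf = uniform_true_mf(1, 1),
                          residual_sd_logbmi = 0, age_effect_logbmi = 0.002,
                          covariate_missingness = c(), fat_mass_missingness = 0,
                          seed = 3)
  coh <- generate_cohort(cfg, detail = "latent")
  anthro <- coh$anthro
  bmi <- anthro$weight_kg / anthro$height_m^2
  # truth predicts log BMI exactly
  expect_equal(log(bmi),
               predict_truth(coh$truth, coh$covariates, coh$sri$quintile),
               tolerance = 1e-12)
  # with MF = 1 everywhere, same age => same BMI regardless of quintile
  same_age <- split(bmi, coh$covariates$age)
  expect_true(all(vapply(same_age, function(v) diff(range(v)) < 1e-12,
                         logical(1))))
})

test_that("non-positive multiplication factors are rejected at generation", {
  cfg <- generator_config(50, seed = 2)
  truth <- make_truth(cfg)
  truth$mf$mf[3] <- 0
  expect_error(generate_outcomes(generate_covariates(cfg),
                                 rep("Q1", 50), truth, cfg),
               "positive")
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- generator_config(30, n_days = 4, seed = 44)
  a <- generate_cohort(cfg, detail = "epochs")
  b <- generate_cohort(cfg, detail = "epochs")
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$covariates, b$covariates)
  la1 <- generate_cohort(cfg, detail = "latent")
  la2 <- generate_cohort(cfg, detail = "latent")
  expect_identical(la1$anthro, la2$anthro)
  expect_identical(la1$sri, la2$sri)
})

test_that("cohort CSVs and truth JSON are written and re-readable", {
  cfg <- generator_config(10, n_days = 3, seed = 5)
  coh <- generate_cohort(cfg, detail = "latent")
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  expect_true(all(file.exists(file.path(d, c("covariates.csv", "anthro.csv",
                                             "truth.json")))))
  tr <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  expect_equal(tr$intercept_logbmi, coh$truth$intercept_logbmi)
  expect_equal(nrow(tr$mf), nrow(coh$truth$mf))
})
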
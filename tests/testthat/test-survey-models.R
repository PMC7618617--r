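test_that("cycle-weight combination halves two-cycle weights and rejects bad input", {
  expect_equal(combine_cycle_weights(30000), 15000)
  expect_equal(combine_cycle_weights(7, n_cycles = 1), 7)
  expect_error(combine_cycle_weights(0), "positive")
  expect_error(combine_cycle_weights(-3), "positive")
})

test_that("unit-weight fits equal the closed-form least-squares solution", {
  set.seed(10)
  n <- 50
  d <- data.frame(
    quintile = factor(sample(paste0("Q", 1:5), n, replace = TRUE)),
    sex = factor(sample(c("Male", "Female"), n, replace = TRUE)),
    age = runif(n, 20, 80),
    survey_weight = rep(1, n))
  d$bmi <- exp(3.3 - 0.02 * (d$quintile == "Q5") + 0.001 * d$age + rnorm(n, 0, 0.1))
  fit <- fit_model(d, 1, "bmi")
  X <- model.matrix(~ quintile + age + sex, d)
  beta <- solve(crossprod(X), crossprod(X, log(d$bmi)))
  expect_equal(unname(fit$coefficients), unname(drop(beta)), tolerance = 1e-8)
})

test_that("design-based covariance matches the sandwich-package oracle", {
  skip_if_not_installed("sandwich")
  set.seed(11)
  n <- 300
  d <- data.frame(
    quintile = factor(sample(paste0("Q", 1:5), n, replace = TRUE)),
    sex = factor(sample(c("Male", "Female"), n, replace = TRUE)),
    age = runif(n, 20, 80),
    survey_weight = rlnorm(n, 0, 0.5))
  d$bmi <- exp(3.3 + 0.001 * d$age + rnorm(n, 0, 0.2))
  fit <- fit_model(d, 1, "bmi")
  v_or <- sandwich::vcovHC(fit$lm, type = "HC0")
  expect_equal(unname(fit$vcov), unname(v_or), tolerance = 1e-10)
})

test_that("rescaling the outcome shifts only the intercept", {
  set.seed(12)
  n <- 120
  d <- data.frame(
    quintile = factor(sample(paste0("Q", 1:5), n, replace = TRUE)),
    sex = factor(sample(c("Male", "Female"), n, replace = TRUE)),
    age = runif(n, 20, 80), survey_weight = rlnorm(n, 0, 0.3))
  d$bmi <- exp(rnorm(n, 3.3, 0.2))
  f1 <- fit_model(d, 1, "bmi")
  d2 <- transform(d, bmi = 3 * bmi)
  f2 <- fit_model(d2, 1, "bmi")
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-10)
  expect_equal(unname(f2$coefficients[1] - f1$coefficients[1]), log(3),
               tolerance = 1e-10)
})

test_that("rank deficiency is reported with the collinear term names", {
  la <- latent_analytic(300, seed = 61)
  an <- as.data.frame(la$analytic)
  # empty quintile-sex cell makes the interaction indicator all-zero
  an <- an[!(an$quintile == "Q5" & an$sex == "Female"), ]
  an$quintile <- factor(as.character(an$quintile), paste0("Q", 1:5))
  expect_error(fit_model(an, 3, "bmi"), "collinear")
})

test_that("multiplication factors recover the generator truth and satisfy identities", {
  la <- latent_analytic(7000, true_mf = uniform_true_mf(0.95, 0.95), seed = 19)
  fit <- fit_model(la$analytic, 2)
  mf <- multiplication_factors(fit)
  expect_equal(mf$mf[mf$contrast == "Q5vsQ1"], 0.95, tolerance = 0.02)
  # MF(Q1 vs Q1) = 1 identically
  mf1 <- multiplication_factors(fit, contrasts = "Q1")
  expect_equal(mf1$mf, 1)
  # telescoping: product of stepwise contrasts equals Q5 vs Q1
  fit3 <- fit_model(la$analytic, 3)
  st <- data.frame(sex = c("Male", "Female"))
  tab <- multiplication_factors(fit3, st)
  for (s in c("Male", "Female")) {
    m <- tab[tab$sex == s, ]
    steps <- m$mf[match(paste0("Q", 2:5, "vsQ1"), m$contrast)]
    ratio <- steps / c(1, steps[-4])
    expect_equal(prod(ratio), m$mf[m$contrast == "Q5vsQ1"], tolerance = 1e-10)
  }
  expect_error(multiplication_factors(fit3, data.frame(sex = "Other")),
               "absent")
})

test_that("stratified MF recovery is unbiased across the full truth grid", {
  strata <- expand.grid(ethnicity = unique(default_true_mf()$ethnicity),
                        sex = c("Male", "Female"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- default_true_mf()
  reps <- 30
  err <- matrix(NA_real_, reps, nrow(strata))
  for (r in seq_len(reps)) {
    la <- latent_analytic(7000, true_mf = truth, seed = 300 + r)
    fit <- fit_model(la$analytic, 4)
    tab <- multiplication_factors(fit, strata)
    q5 <- tab[tab$contrast == "Q5vsQ1", ]
    tru <- truth[truth$quintile == "Q5", ]
    key <- paste(q5$ethnicity, q5$sex)
    err[r, ] <- q5$mf - tru$mf[match(key, paste(tru$ethnicity, tru$sex))]
  }
  bias <- colMeans(err)
  mix <- c(0.12, 0.096, 0.41, 0.234, 0.11, 0.03)[match(strata$ethnicity,
            unique(default_true_mf()$ethnicity))]
  # bias bound scaled to each stratum's sampling error at this replicate count
  expect_true(all(abs(bias[mix >= 0.05]) < 0.015))
  expect_true(all(abs(bias) < 0.04))
})

test_that("bootstrap CIs behave on degenerate, Normal-mean and failure cases", {
  # degenerate: constant outcome -> zero-width interval at the point estimate
  d <- data.frame(y = rep(2.5, 40), survey_weight = 1)
  ci <- bootstrap_ci(d, function(x) c(m = mean(x$y)), B = 50, seed = 1)
  expect_equal(unname(ci$lower), 2.5)
  expect_equal(unname(ci$upper), 2.5)
  # sample mean of N(0,1), n = 400: width within 15% of 2*1.96/sqrt(400)
  set.seed(14)
  d2 <- data.frame(y = rnorm(400), survey_weight = 1)
  ci2 <- bootstrap_ci(d2, function(x) c(m = mean(x$y)), B = 2000, seed = 2)
  expect_equal(unname(ci2$upper - ci2$lower), 2 * 1.96 / sqrt(400),
               tolerance = 0.15)
  # reproducible
  ci3 <- bootstrap_ci(d2, function(x) c(m = mean(x$y)), B = 200, seed = 5)
  ci4 <- bootstrap_ci(d2, function(x) c(m = mean(x$y)), B = 200, seed = 5)
  expect_identical(ci3, ci4)
  # abort when the estimator fails on too many resamples (but not on the
  # point estimate itself)
  k <- 0L
  flaky <- function(x) {
    k <<- k + 1L
    if (k > 1L && k %% 2L == 0L) stop("boom")
    c(m = mean(x$y))
  }
  expect_error(bootstrap_ci(d2, flaky, B = 100, seed = 3), "resamples")
})

test_that("Rao-Scott test degenerates correctly and agrees with the classical LR oracle", {
  la <- latent_analytic(2000, true_mf = uniform_true_mf(0.95, 0.95), seed = 23,
                        weight_distribution = list(family = "constant", value = 1))
  an <- la$analytic
  f2 <- fit_model(an, 2); f3 <- fit_model(an, 3)
  same <- interaction_test(f3, f3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  it <- interaction_test(f3, f2)
  # classical LR oracle under equal weights / independence
  rss_f <- sum(stats::residuals(f3$lm)^2)
  rss_r <- sum(stats::residuals(f2$lm)^2)
  lr_classic <- f3$n * log(rss_r / rss_f)
  p_classic <- pchisq(lr_classic, df = it$df, lower.tail = FALSE)
  expect_equal(it$statistic, lr_classic, tolerance = 1e-8)
  expect_equal(it$p_value, p_classic, tolerance = 0.1 * max(p_classic, 1e-10))
  expect_equal(it$design_effect, 1, tolerance = 0.1)
  expect_error(interaction_test(f2, f3), "not nested")
})

test_that("the sex-interaction test detects the configured effect modification", {
  la <- latent_analytic(7000, true_mf = uniform_true_mf(0.90, 1.00), seed = 29)
  it <- interaction_test(fit_model(la$analytic, 3), fit_model(la$analytic, 2))
  expect_lt(it$p_value, 1e-4)
})

test_that("trend p-values are uniform under the null and significant under monotone truth", {
  ps <- vapply(1:120, function(r) {
    la <- latent_analytic(700, true_mf = uniform_true_mf(1, 1), seed = 700 + r)
    trend_test(la$analytic, model_id = 1)$p_trend
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # monotone decreasing MFs: strong negative trend
  la <- latent_analytic(7000, true_mf = uniform_true_mf(0.92, 0.92), seed = 41)
  tr <- trend_test(la$analytic, model_id = 2)
  expect_lt(tr$p_trend, 0.001)
  expect_lt(tr$estimate, 0)
})

test_that("kNN imputation preserves observed cells and beats the marginal baseline", {
  la <- latent_analytic(500, seed = 37)
  cov <- as.data.frame(la$analytic)[c("participant_id", "survey_weight", "age",
                                      "sex", "ethnicity", "alcohol", "kcal")]
  expect_identical(knn_impute(cov), cov)  # nothing missing -> identity

  # single missing categorical with identical donors
  toy <- data.frame(participant_id = 1:6, survey_weight = 1,
                    a = c(NA, rep("x", 5)), b = rnorm(6))
  expect_identical(knn_impute(toy)$a[1], "x")

  # MCAR 20% on a continuous covariate correlated with the others
  set.seed(5)
  n <- 400
  z <- rnorm(n)
  dd <- data.frame(participant_id = 1:n, survey_weight = 1,
                   x1 = z + rnorm(n, 0, 0.4), x2 = z + rnorm(n, 0, 0.4),
                   x3 = z + rnorm(n, 0, 0.4))
  truth <- dd$x1
  miss <- sample(n, 80)
  dd$x1[miss] <- NA
  imp <- knn_impute(dd)
  expect_false(anyNA(imp$x1))
  expect_identical(imp$x1[-miss], truth[-miss])
  rmse_knn <- sqrt(mean((imp$x1[miss] - truth[miss])^2))
  rmse_mean <- sqrt(mean((mean(truth[-miss]) - truth[miss])^2))
  expect_lt(rmse_knn, rmse_mean)

  # rows with every covariate missing cannot be imputed
  allna <- data.frame(participant_id = 1:3, survey_weight = 1,
                      a = c(NA, 1, 2), b = c(NA, 3, 4))
  expect_error(knn_impute(allna), "every covariate")
})

test_that("covariate profile follows the skewness rule and weighted mode", {
  set.seed(6)
  n <- 3000
  d <- data.frame(sym = rnorm(n, 10, 2), skw = rlnorm(n, 0, 1),
                  cat = factor(sample(c("a", "b"), n, TRUE, prob = c(0.7, 0.3))),
                  survey_weight = rlnorm(n, 0, 0.3))
  pr <- covariate_profile(d, vars = c("sym", "skw", "cat"))
  expect_equal(pr$sym, weighted.mean(d$sym, d$survey_weight), tolerance = 1e-9)
  expect_equal(pr$skw, weighted_quantile(d$skw, d$survey_weight, 0.5),
               tolerance = 1e-9)
  expect_identical(pr$cat, "a")
})

test_that("prediction curves are flat without an SRI effect and envelope bands are wider", {
  la <- latent_analytic(2500, true_mf = uniform_true_mf(0.9, 1.0), seed = 47)
  an <- la$analytic
  fit <- fit_model(an, "4c")
  prof <- covariate_profile(an)
  # zeroing the SRI coefficients must flatten every stratum's curve
  fit0 <- fit
  fit0$coefficients[grep("sri_final", names(fit0$coefficients))] <- 0
  flat <- predict_curve(fit0, prof, sri_grid = seq(0, 100, 25))
  spread <- tapply(flat$curves$fit,
                   paste(flat$curves$sex, flat$curves$ethnicity),
                   function(v) diff(range(v)))
  expect_true(all(spread < 1e-10))
  # female curves decline, male curves are near-flat (truth 0.9 vs 1.0)
  cv <- predict_curve(fit, prof, sri_grid = c(5, 95),
                      strata = data.frame(sex = c("Female", "Male"),
                                          ethnicity = "Non-Hispanic White"))
  f <- cv$curves[cv$curves$sex == "Female", ]
  expect_lt(f$fit[f$sri == 95], f$fit[f$sri == 5])
  # bootstrap bands at the profile vs the covariate-dispersion envelope
  cv2 <- predict_curve(fit, prof, sri_grid = c(10, 50, 90),
                       strata = data.frame(sex = "Female",
                                           ethnicity = "Non-Hispanic White"),
                       records = an, B = 40, n_draws = 4000, seed = 3)
  band <- cv2$curves$hi - cv2$curves$lo
  env <- cv2$envelope$hi - cv2$envelope$lo
  expect_true(all(env > band))
  expect_error(predict_curve(fit, prof, sri_grid = c(-5, 50)), "range")
})

test_that("meal-timing sensitivity uses complete cases and reproduces the main MFs", {
  la <- latent_analytic(4000, true_mf = uniform_true_mf(0.93, 0.99), seed = 53,
                        meal_missingness = 0.38)
  an <- la$analytic
  n_cc <- sum(!is.na(an$last_meal_diff) & !is.na(an$eating_window_diff))
  st <- data.frame(ethnicity = "Non-Hispanic White", sex = c("Male", "Female"))
  sens <- sensitivity_meal_timing(an, strata = st)
  expect_equal(sens$n, n_cc)
  main <- mf_with_ci(an, 4, strata = st, B = 60, seed = 4)
  q5 <- main$contrast == "Q5vsQ1"
  # meal covariates are independent of the outcome: sensitivity MFs stay
  # inside the main analysis' bootstrap CIs
  expect_true(all(sens$mf$mf[q5] >= main$ci_low[q5] - 0.02 &
                  sens$mf$mf[q5] <= main$ci_high[q5] + 0.02))
  an2 <- an
  an2$last_meal_diff <- NA_real_
  expect_error(sensitivity_meal_timing(an2), "too small")
})
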
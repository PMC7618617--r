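# sleepreg

Sleep regularity and adiposity: actigraphy QC, the Sleep Regularity Index,
and survey-weighted log-linear models of obesity measures.

## What this package does

Irregular sleep — going to sleep and waking at different times from day to
day — is an emerging risk factor for obesity, and the strength of the
association appears to differ by sex and race/ethnicity. `sleepreg`
implements, as a tested and reusable pipeline, an epidemiological analysis
linking accelerometer-derived sleep regularity to a panel of adiposity
measures in a survey-weighted cohort:

1. **Actigraphy QC** (`read_epochs()`, `qc_pipeline()`): parses minute-epoch
   state predictions (wake / sleep / non-wear / unknown), recodes them to a
   binary-with-missing sleep variable (quality-flagged or short minutes
   become missing), and applies the inclusion filters — exactly 1,440
   timesteps per day, under 2 h of daily non-wear, at least three
   consecutive valid days including a Saturday or Sunday, and at most 30%
   missingness — emitting an exclusion ledger with one reason per excluded
   participant.
2. **Sleep Regularity Index** (`compute_sri()`): the probability-based
   index of being in the same sleep/wake state at minutes 24 h apart,

   SRI = −100 + 200 (1 − (1/N_v) Σᵢ |sᵢ − sᵢ₊c|),  c = 1,440 min,

   where N_v counts comparisons with both epochs observed. SRI = 100 for
   perfectly periodic sleep, ≈ 0 for random sleep, −100 for perfect
   anti-periodicity. A Monte-Carlo null distribution under random sleep
   (`simulate_null()`: 100,000 simulated sleepers, two days, fair-coin
   minutes) gives a central 99% range of ± 6.8; values below −6.8 are
   replaced by draws from a Normal with the null's mean and SD
   (`winsorize_sri()`), and exposure quintiles are assigned
   (`assign_quintiles()`).
3. **Adiposity panel** (`compute_indices()`): BMI (rounded to one decimal),
   waist circumference, waist-to-height ratio, A Body Shape Index, Body
   Roundness Index, Visceral Adiposity Index, Lipid Accumulation Product,
   sagittal abdominal diameter and its height ratio, fat mass index and
   percent body fat, with 1st/99th-percentile winsorization
   (`winsorize_percentile()`) and a Pearson correlation summary.
4. **Survey-weighted models** (`fit_model()`): weighted least squares of
   log(outcome) on SRI quintiles in four nested specifications (quintiles +
   age + sex; + full covariates; + quintile×sex; + quintile×ethnicity),
   with design-based sandwich covariance. Multiplication factors —
   exp(linear combinations of coefficients), the ratio of expected outcome
   between quintiles — come with percentile bootstrap CIs
   (`multiplication_factors()`, `bootstrap_ci()`), effect modification is
   tested with a first-order Rao-Scott corrected working likelihood-ratio
   test (`interaction_test()`), trend with a quintile-median score
   (`trend_test()`), and model-based prediction curves span the full SRI
   range 0–100 (`predict_curve()`). k-nearest-neighbour imputation under
   Gower distance (`knn_impute()`) completes the covariates.
5. **Synthetic cohort with ground truth** (`generate_cohort()`): minute-level
   sleep series of controllable regularity, covariates, survey weights and
   log-linear anthropometry with a known multiplication-factor grid, so
   every stage can be validated against truth.

`run_pipeline()` chains everything and writes the full artifact set
(quintile descriptives, panel summary, MF tables, exclusion ledger,
prediction curves, manifest). A thin script wrapper lives at
`inst/scripts/run_pipeline.R`.

## Worked example

End-to-end on a synthetic cohort (minute-level epochs → QC → SRI → panel →
models):

```r
library(sleepreg)
cfg <- run_config(n_participants = 800, out_dir = "artifacts", B = 100L,
                  models = c(1, 2, 3),
                  seeds = c(generator = 1L, null = 2L, bootstrap = 3L))
res <- run_pipeline(cfg)
cat(sprintf("null SRI: mean %.3f, sd %.3f, 99%% range (%.2f, %.2f)\n",
            res$null$mean, res$null$sd, res$null$q005, res$null$q995))
```

```
null SRI: mean 0.005, sd 2.633, 99% range (-6.81, 6.81)
```

The simulated null matches the closed form 200·2.576·√(0.25/1440) ≈ 6.79:
random sleepers produce SRI values essentially inside ± 6.8, which is the
winsorization cutoff.

Parameter recovery at the headline effect sizes (truth: Q5-vs-Q1
multiplication factor 0.92 for women, 0.98 for men; the fast latent-SRI
generator path skips minute-level epochs):

```r
cfg <- generator_config(7000, true_mf = uniform_true_mf(0.92, 0.98),
                        covariate_missingness = c(), fat_mass_missingness = 0,
                        meal_missingness = 0, seed = 7)
coh <- generate_cohort(cfg, detail = "latent")
analytic <- make_analytic(coh$covariates, coh$sri, coh$anthro)
fit3 <- fit_model(analytic, 3)
mf <- multiplication_factors(fit3, data.frame(sex = c("Female", "Male")))
print(subset(mf, contrast == "Q5vsQ1"), digits = 3)
it <- interaction_test(fit3, fit_model(analytic, 2))
cat(sprintf("Rao-Scott sex interaction: X2 = %.1f (df %d, design effect %.2f), p = %.2g\n",
            it$statistic, it$df, it$design_effect, it$p_value))
tr <- trend_test(analytic, 2)
cat(sprintf("P_trend = %.2g (slope %.5f per SRI point)\n", tr$p_trend, tr$estimate))
```

```
  model_id ethnicity    sex contrast    mf
4        3      <NA> Female   Q5vsQ1 0.923
8        3      <NA>   Male   Q5vsQ1 0.974
Rao-Scott sex interaction: X2 = 20.5 (df 4, design effect 1.24), p = 0.0024
P_trend = 9.9e-10 (slope -0.00116 per SRI point)
```

A multiplication factor of 0.923 means the most-regular sleepers' expected
BMI is 7.7% lower than the least-regular sleepers', holding covariates
fixed; the recovered factors sit within sampling error of the configured
truth, the negative trend across quintiles is strongly significant, and the
design effect near 1 + CV²(weights) shows the sandwich variance reacting to
the survey weights as theory predicts.

## Methods documentation

The methods vignette (`vignettes/sri-adiposity-methods.Rmd`) describes the
model and its assumptions, the generator's design, boundary conventions,
numerical choices and known limitations.
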
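---
title: "Sleep regularity and adiposity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep regularity and adiposity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepreg)
```

This vignette documents the statistical methods implemented in `sleepreg`,
the assumptions behind them, the conventions adopted at every boundary or
tie, and the design of the synthetic cohort the test suite validates
against. It is the package's reference for *why* things are computed the
way they are; the README shows *how* to run them.

## The exposure: Sleep Regularity Index

The SRI asks a simple question of a minute-resolution sleep/wake series:
if you look at a person at some minute and again exactly 24 hours later,
how often are they in the same state? Writing $s_i \in \{0, 1\}$ for
wake/sleep at minute $i$ and $c = 1440$ minutes,

$$\mathrm{SRI} = -100 + 200\left(1 - \frac{1}{N_v}
  \sum_{i=1}^{N_v} |s_i - s_{i+c}|\right),$$

scaled so that 100 means perfect day-to-day agreement, $-100$ perfect
disagreement, and 0 the expectation under random sleep. Minutes classified
non-wear or unknown are missing; a comparison pair with a missing member
contributes nothing to the sum and is excluded from the valid-comparison
count $N_v$. A participant with $N_v = 0$ has no defined SRI and is
excluded. For multi-day windows the comparisons span the full window
($N_v$ up to length $-$ 1440), which is exactly the index range the
formula prescribes.

Two useful invariants, both tested: the SRI is unchanged by complementing
the series ($s \mapsto 1-s$ leaves every mismatch indicator alone), and it
depends on the day ordering only through day adjacency (verified against a
brute-force day-pair oracle).

### The Monte-Carlo null and one-sided winsorization

Real sleep essentially never produces large negative SRI values; strongly
negative values are measurement pathology rather than biology. To
winsorize them in a principled way, `simulate_null()` simulates sleepers
whose every minute is an independent Bernoulli(0.5) draw over two 1,440
minute days, computing the SRI of each of 100,000 replicates. The mismatch
indicator of each comparison is then itself Bernoulli(0.5), so the SRI has
mean 0 and standard deviation $200\sqrt{0.25/1440} \approx 2.635$, and the
central 99% of the null spans
$\pm\, 200 \cdot 2.576 \sqrt{0.25/1440} \approx \pm 6.79$ — the simulation
reproduces this closed form, which is the package's internal consistency
check on the whole SRI implementation.

`winsorize_sri()` replaces values below $-6.8$ with draws from
$\mathcal{N}(\hat\mu_0, \hat\sigma_0)$, the null's estimated mean and SD.
Conventions, each deliberate:

* replacement is **one-sided** — values at or above the cutoff, however
  large, are untouched, preserving 0 as the interpretable baseline of
  random sleep;
* replacement draws are **not truncated** at the cutoff; a rare draw below
  $-6.8$ is accepted (the replacement distribution is the null itself, not
  a clipped version of it);
* the cutoff is carried as the conventional rounded value $-6.8$ (the
  0.5% null quantile); the simulated quantiles of the concrete run travel
  alongside in the `sri_null` object. The 0.5/99.5 quantile pair and the
  99th percentile of $|\mathrm{SRI}|$ agree to one decimal under the
  null's symmetry; the implementation uses the quantile pair.

Exposure quintiles are unweighted sample quintiles (the equal group sizes
this produces are a deliberate property of the design): cut points are
type-7 (linear-interpolation) quantiles, and a value landing exactly on a
cut point goes to the **lower** quintile. Per-quintile median SRI values
are kept as the continuous trend score.

## Actigraphy quality control

A day of wrist-actigraphy minute predictions enters the analysis only if
it is complete and mostly worn; a participant only with a usable window:

| rule | convention |
|---|---|
| timesteps per day | exactly 1,440 (strict) |
| non-wear per day | `< 120` minutes — 120 itself fails ("less than 2 hours" read literally); counted from the state field |
| window | longest run of ≥ 3 consecutive valid days containing a Sat or Sun; ties to the earliest start |
| missingness | `≤ 30%` of the binary sleep variable over the *selected window* — exactly 30% is retained ("more than 30%" excluded) |

Flagged minutes and minutes with fewer than 60 measured seconds are kept
as timesteps but set to missing: this reconciles "only unflagged, full
minutes carry information" with "a day has 1,440 timesteps", and it means
flags erode the missingness budget rather than day completeness. Whether
the 30% rule applies before or after window selection is ambiguous; it is
evaluated *after*, on the selected window, since that is the series the
SRI actually sees.

The exclusion ledger counts each excluded participant once under the first
failing rule, in a fixed order: `incomplete_day`, `excess_nonwear` (day
failures are attributed when relaxing that specific failure mode would
have produced a qualifying window), `too_few_consecutive_days`,
`no_weekend_day`, then `flagged_minutes` (missingness over 30% driven by
flags/short minutes alone) and `excess_missingness`. The attribution is
deterministic, so an engineered fixture with one violation per participant
reproduces its construction exactly — which is how the QC suite tests it.

## The adiposity panel

BMI is weight (kg) over height (m) squared, rounded **half away from
zero** to one decimal (base R's `round()` is round-half-even, which is not
the convention used for reporting BMI), and rounding happens at
computation, before any winsorization. The further indices follow the
standard formulas: WHtR = WC/height (both cm); FMI = fat mass/height²;
SADHtR = SAD/height (both cm);
ABSI = WC/(BMI^{2/3}·height^{1/2}) in SI units (WC and height in metres);
BRI = 364.2 − 365.5·√(1 − (WC/2π)²/(0.5·height)²) with WC and height in
cm; VAI with the sex-specific constants
(men: (WC/(39.68 + 1.88·BMI))·(TG/1.03)·(1.31/HDL); women:
(WC/(36.58 + 1.89·BMI))·(TG/0.81)·(1.52/HDL)); LAP = (WC − 65)·TG for men
and (WC − 58)·TG for women. Fat-mass-derived measures (fat mass, FMI,
percent fat) propagate missingness — they are analysed complete-case and
never imputed.

One unit note: under the SI convention ABSI values are ≈ 0.08; some
published tabulations print ≈ 0.8, i.e. a factor-10 (decimetre-based)
convention. This package produces SI values and does not rescale.

BMI, WC, total fat mass, percent fat and SAD are winsorized at the sample
1st/99th percentiles (type-7 quantiles, so capped values are exactly
reproducible). Re-winsorizing with re-estimated percentiles moves the
caps by a floating-point-scale amount (the capped mass shifts the order
statistics); capping at *fixed* bounds is exactly idempotent, and
`winsorize_percentile(bounds =)` exposes that form.

## Survey-weighted log-linear models

BMI and most other panel measures are right-skewed, so outcomes are
log-transformed and effects reported as **multiplication factors** —
$\mathrm{MF} = e^{L^\top\beta}$ for the linear combination $L$ contrasting
quintile $Q_j$ against $Q_1$ within a sex-ethnicity stratum. Four nested
specifications are fitted by weighted least squares: (1) quintiles + age +
sex; (2) + ethnicity, education, income, occupation, marital status,
alcohol, smoking, vitamin D, caloric intake, depression score, activity;
(3) + quintile×sex; (4) + quintile×ethnicity. MF(Q1 vs Q1) is identically
1, and stepwise contrasts telescope
(MF(Q5 vs Q1) = ∏ MF(Q_{j+1} vs Q_j)) — both tested identities of the
contrast construction rather than of the data.

Coefficient covariance is **design-based**: the weighted sandwich
$(X'WX)^{-1}(\sum_i w_i^2 e_i^2 x_i x_i')(X'WX)^{-1}$, treating
participants as independent sampling units. Survey strata and cluster
identifiers are deliberately out of scope — the synthetic cohort has no
cluster structure, so claiming cluster-robust variances would be
decoration. Two-cycle examination weights are combined by halving. The
unweighted sensitivity refit is a flag away (`weighted = FALSE`).

Effect modification uses the working likelihood-ratio statistic from the
weighted Gaussian likelihood (weights normalised to mean 1), scaled by the
first-order **Rao-Scott** correction: the mean generalized design effect
$\bar\delta = \mathrm{tr}(V_\mathrm{model}^{-1} V_\mathrm{design})/q$ over
the $q$ tested coefficients, with $LR/\bar\delta \sim \chi^2_q$. The
model-based covariance must be computed on the *normalised*-weight scale —
using raw weights makes $\bar\delta$ depend on the arbitrary scale of the
weights and (for example) halving weights for cycle combination would
silently double the test statistic. With equal weights the correction is
≈ 1 and the test reproduces the classical LR test; with lognormal weights
of log-SD 0.5 the design effect settles near $1 + \mathrm{CV}^2 \approx
1.28$, both verified in the suite. The second-order (Satterthwaite)
correction is a possible extension, not implemented.

`P_trend` enters the per-quintile median SRI as a single continuous score
and reports the design-based Wald p-value of its slope — the standard
epidemiological convention when a trend p-value is reported without
further definition. Under a null generator the trend p-values are uniform
(KS-tested in the suite).

Bootstrap confidence intervals are percentile intervals from resampling
participants with replacement (weights travel with the row), default
B = 1000, seed-reproducible; an estimator failing on more than 5% of
resamples aborts with a diagnostic rather than returning a quietly
truncated interval.

Prediction curves over the full SRI range use a continuous-SRI variant of
model 4 (linear SRI main effect with the same sex and ethnicity
interactions) — the quintile model cannot extrapolate between and beyond
quintile medians, and a linear-in-SRI log outcome is the most parsimonious
choice consistent with the quintile structure. Curves are evaluated at a
reference covariate profile: survey-weighted median for skewed continuous
covariates (|weighted skewness| > 1 — the rule needs a threshold, and 1 is
the conventional "markedly skewed" boundary), weighted mean for symmetric
ones, weighted modal category otherwise. Besides bootstrap bands at the
fixed profile, a dispersion envelope re-applies the model to covariate
combinations drawn from the data (200,000 draws at full scale; tests use
fewer), which is necessarily wider than the profile-conditional band.
Missing covariates are completed by k-nearest-neighbour imputation under
Gower distance (k = 5; continuous cells take the donor median, categorical
the donor mode); fat-mass outcomes are excluded from imputation. The
meal-timing sensitivity refits model 4 plus the weekday-weekend
differences in last-meal timing and eating window on complete cases only.

## The synthetic cohort: what it emulates, what it does not

The generator produces, under one master seed (bit-identical on
regeneration):

* **Sleep series** — one consolidated nightly sleep block (onset 23:00,
  configurable duration, default 480 min), each night's onset and offset
  jittered independently by $\mathcal{N}(0, \sigma_\mathrm{jitter})$; the
  night before day 1 is included so zero jitter yields SRI = 100 exactly.
  Non-wear/unknown minutes are injected i.i.d. per minute. An `iid` mode
  (every minute Bernoulli) provides the random-sleep extreme. Day labels
  start Monday by default and are configurable, so weekend-rule violations
  can be constructed. Expected SRI is monotone decreasing in the jitter SD
  (tested by Monte Carlo). In cohort mode, per-participant jitter SDs are
  drawn lognormally around the configured scale so the cohort spans the
  SRI range ≈ 0–95; the fast `latent` path instead draws each
  participant's SRI directly from a Beta-shaped latent distribution
  (median near 60, negative skew, range ≈ 0–95).
* **Covariates and weights** — categorical mixes with all six ethnicity
  levels bounded away from zero, skew-matched continuous covariates,
  missingness injected completely at random (alcohol defaults to the
  maximum rate of 24%; fat mass to 49%; meal-timing fields to 38%), and
  lognormal survey weights with median 1 emulating unequal selection
  probabilities (uninformative of the outcome by construction).
* **Outcomes** — $\log \mathrm{BMI} = \log(29) + \log
  \mathrm{MF}(\text{quintile}, \text{sex}, \text{ethnicity}) +
  0.002\,(\mathrm{age}-50) + \mathcal{N}(0, 0.22)$. The default truth grid
  spans MFs ≈ 0.88–1.04 with inverse associations concentrated among
  women; `uniform_true_mf()` builds simplified sex-only grids with
  geometric interpolation across intermediate quintiles. The residual SD
  0.22 matches a BMI interquartile range of roughly 24–33 on the log
  scale; covariate effects other than the small age term default to zero
  so SRI-effect recovery is isolated. Height, weight, WC, SAD, fat mass,
  and lipids are generated conditionally on BMI with realistic correlation
  (corr(BMI, WC) ≥ 0.85 at n ≥ 2,000 is a tested generator contract). The
  `synthetic_truth` object records everything needed to predict expected
  log BMI exactly (exact at zero residual SD, a tested identity).

Passing tests on this cohort demonstrate that the *procedures* are
implemented correctly and recover known truth; they cannot demonstrate
robustness to what the generator does not contain — circadian physiology,
informative weights, cluster sampling, informative missingness, seasonal
structure, or classifier error in the sleep/wake labels (the upstream
machine-learning classifier is explicitly out of scope; its output is this
package's input).

## Problem sizes, determinism, and a known power boundary

The suite's simulation scales are chosen so the full test run completes in
a few minutes: the null simulation uses its full 100,000 replicates
(seconds, via chunked vectorisation that a dedicated test pins to the
scalar `compute_sri()`); parameter-recovery runs 100 cohorts of n = 7,000
through the latent path; bootstrap coverage runs 200 cohorts of n = 1,000
with B = 500. Every stochastic step takes an explicit seed, and the
end-to-end pipeline is byte-deterministic under a fixed configuration.

One boundary worth stating plainly: at the headline effect contrast
(Q5-vs-Q1 MFs of 0.92 in women vs 0.98 in men), n = 7,000, residual log
BMI SD 0.22 and uninformative lognormal weights, the df-4 sex-interaction
test is correctly calibrated but attains p < 0.001 in well under half of
replicates — the recovery test in the suite computes this fraction
directly. Reaching near-certain detection at that threshold would require
materially smaller residual noise or unweighted fits; the package reports
the measured power rather than engineering the conditions to inflate it.

## Known limitations

* Variance estimation treats participants as independent units; no
  strata/PSU machinery, so design effects from clustering are outside the
  model.
* Single-completion kNN imputation: imputation uncertainty is not
  propagated into variances (no multiple-imputation combining).
* The continuous-SRI curve model assumes log-linearity in SRI; splines or
  step functions are plausible alternatives the quintile analysis cannot
  distinguish.
* The generator's covariate joint distribution matches margins only; no
  dependence structure between covariates is modelled.
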
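# fixture builders shared across test files (all data generated in code)

# one calendar day of epoch records with engineered defects
epoch_day <- function(id, day_index, weekday,
                      sleep_minutes = 1:480,   # minutes of day asleep
                      nonwear_idx = integer(0),
                      unknown_idx = integer(0),
                      flagged_idx = integer(0),
                      drop_idx = integer(0)) {
  state <- rep("wake", 1440)
  state[sleep_minutes] <- "sleep"
  state[nonwear_idx] <- "nonwear"
  state[unknown_idx] <- "unknown"
  flagged <- rep(FALSE, 1440)
  flagged[flagged_idx] <- TRUE
  d <- data.table::data.table(
    participant_id = id, day_index = day_index, weekday = weekday,
    minute_of_day = 0:1439, state = state, quality_flagged = flagged,
    seconds_measured = 60L)
  if (length(drop_idx)) d <- d[-drop_idx]
  d
}

# a clean weekend-containing block of n_days starting Friday
clean_days <- function(id, n_days = 3, weekdays = c("Fri", "Sat", "Sun")) {
  data.table::rbindlist(lapply(seq_len(n_days), function(d) {
    epoch_day(id, d, weekdays[(d - 1) %% length(weekdays) + 1])
  }))
}

# the engineered 10-participant QC fixture: one violation each
qc_fixture <- function() {
  fss <- c("Fri", "Sat", "Sun")
  parts <- list(
    # incomplete_day: middle day has 1439 epochs
    data.table::rbindlist(list(epoch_day("P01", 1, "Fri"),
                               epoch_day("P01", 2, "Sat", drop_idx = 700L),
                               epoch_day("P01", 3, "Sun"))),
    data.table::rbindlist(list(epoch_day("P02", 1, "Fri", drop_idx = 1L),
                               epoch_day("P02", 2, "Sat"),
                               epoch_day("P02", 3, "Sun"))),
    # excess_nonwear: middle day has exactly 120 non-wear minutes
    data.table::rbindlist(list(epoch_day("P03", 1, "Fri"),
                               epoch_day("P03", 2, "Sat", nonwear_idx = 600:719),
                               epoch_day("P03", 3, "Sun"))),
    data.table::rbindlist(list(epoch_day("P04", 1, "Fri", nonwear_idx = 1:120),
                               epoch_day("P04", 2, "Sat"),
                               epoch_day("P04", 3, "Sun"))),
    # too_few_consecutive_days: only two days supplied
    data.table::rbindlist(list(epoch_day("P05", 1, "Sat"),
                               epoch_day("P05", 2, "Sun"))),
    data.table::rbindlist(list(epoch_day("P06", 1, "Sat"),
                               epoch_day("P06", 2, "Sun"))),
    # no_weekend_day: five valid weekdays
    data.table::rbindlist(lapply(1:5, function(d) {
      epoch_day("P07", d, c("Mon", "Tue", "Wed", "Thu", "Fri")[d])
    })),
    data.table::rbindlist(lapply(1:5, function(d) {
      epoch_day("P08", d, c("Mon", "Tue", "Wed", "Thu", "Fri")[d])
    })),
    # flagged_minutes: 35% of each day's minutes quality-flagged
    data.table::rbindlist(lapply(1:3, function(d) {
      epoch_day("P09", d, fss[d], flagged_idx = 1:504)
    })),
    # excess_missingness: 35% unknown state (non-wear untouched)
    data.table::rbindlist(lapply(1:3, function(d) {
      epoch_day("P10", d, fss[d], unknown_idx = 1:504)
    }))
  )
  data.table::rbindlist(parts)
}

# expected ledger for qc_fixture()
qc_fixture_ledger <- function() {
  list(incomplete_day = 2L, excess_nonwear = 2L,
       too_few_consecutive_days = 2L, no_weekend_day = 2L,
       flagged_minutes = 1L, excess_missingness = 1L, retained = 0L)
}

# brute-force SRI oracle: averages minute-by-minute mismatches over
# adjacent day pairs, skipping pairs with a missing member
sri_oracle <- function(values, lag = 1440L) {
  n_days <- length(values) %/% lag
  num <- 0; den <- 0
  for (d in seq_len(n_days - 1)) {
    a <- values[((d - 1) * lag + 1):(d * lag)]
    b <- values[(d * lag + 1):((d + 1) * lag)]
    ok <- !is.na(a) & !is.na(b)
    num <- num + sum(abs(a[ok] - b[ok]))
    den <- den + sum(ok)
  }
  -100 + 200 * (1 - num / den)
}

# fast latent-path analytic cohort for model tests
latent_analytic <- function(n, true_mf = uniform_true_mf(0.92, 0.98),
                            seed = 1, ...) {
  args <- modifyList(
    list(n_participants = n, true_mf = true_mf,
         covariate_missingness = c(), fat_mass_missingness = 0,
         meal_missingness = 0, seed = seed),
    list(...))
  cfg <- do.call(generator_config, args)
  coh <- generate_cohort(cfg, detail = "latent")
  list(analytic = make_analytic(coh$covariates, coh$sri, coh$anthro),
       truth = coh$truth, config = cfg)
}
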
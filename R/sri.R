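#' Compute the Sleep Regularity Index (SRI)
#'
#' The SRI measures the probability that a person is in the same sleep/wake
#' state at two time points 24 hours apart, rescaled so that 100 means the
#' state always agrees across consecutive days, -100 that it always
#' disagrees, and 0 the level expected under random sleep:
#' \deqn{SRI = -100 + 200\Big(1 - \frac{1}{N_v}\sum_{i=1}^{N_v}
#'   |s_i - s_{i+c}|\Big)}
#' where \eqn{s_i \in \{0, 1\}} codes wake/sleep at minute \eqn{i},
#' \eqn{c} is the lag (1440 minutes, one day), and \eqn{N_v} counts the
#' valid comparisons: pairs in which neither epoch is missing. Pairs with a
#' missing member contribute nothing to the sum and are excluded from
#' \eqn{N_v}.
#'
#' @param series a [sleep_series()] object, or a numeric/integer vector over
#'   \{0, 1, NA\} (NA = non-wear/unknown epoch).
#' @param lag comparison lag in minutes; one day by default.
#' @return list of class `sri_result` with `participant_id`, `sri_raw`,
#'   `n_valid` (\eqn{N_v}), and placeholders `sri_final`, `winsorized`,
#'   `quintile` filled by later stages.
#' @seealso [simulate_null()], [winsorize_sri()], [assign_quintiles()]
#' @export
compute_sri <- function(series, lag = 1440L) {
  if (inherits(series, "sleep_series")) {
    values <- series$values
    id <- series$participant_id
    lag <- series$lag %||% lag
  } else {
    values <- series
    id <- NA_character_
  }
  n <- length(values)
  if (n <= lag) stop("series length must exceed the lag (", lag, " minutes)")
  x <- values[seq_len(n - lag)]
  y <- values[seq_len(n - lag) + lag]
  ok <- !is.na(x) & !is.na(y)
  n_valid <- sum(ok)
  if (n_valid == 0L) {
    stop("SRI undefined: no valid epoch-by-epoch comparisons (N_v = 0)")
  }
  sri <- -100 + 200 * (1 - sum(abs(x[ok] - y[ok])) / n_valid)
  structure(
    list(participant_id = id, sri_raw = sri, sri_final = sri,
         n_valid = n_valid, winsorized = FALSE, quintile = NA_character_),
    class = "sri_result"
  )
}

#' Monte-Carlo null distribution of the SRI under random sleep
#'
#' Simulates the SRI of sleepers whose minute-level state is an independent
#' Bernoulli draw each minute, to establish the range of SRI values
#' compatible with purely random sleep. With the defaults (two days of
#' 1,440 minutes, p = 0.5) the central 99% of the null distribution spans
#' approximately \eqn{\pm 6.8} SRI points, in agreement with the closed form
#' \eqn{200 \cdot 2.576 \sqrt{0.25/1440} \approx 6.79}.
#'
#' States are drawn explicitly in chunks and each replicate's SRI evaluated
#' with the same formula as [compute_sri()] (vectorised across replicates).
#'
#' @param n_sims number of simulated sleepers.
#' @param n_days days per simulated sleeper (>= 2).
#' @param p_sleep per-minute sleep probability.
#' @param seed integer seed; the simulation is bit-reproducible.
#' @param cutoff lower SRI cutoff stored for winsorization. The default -6.8
#'   is the conventional rounded 0.5% null quantile; pass `NULL` to use the
#'   simulated 0.5% quantile of this run instead.
#' @return list of class `sri_null` with `n_sims`, `mean`, `sd`, `q005`,
#'   `q995`, `cutoff`, `seed`.
#' @export
simulate_null <- function(n_sims = 100000L, n_days = 2L, p_sleep = 0.5,
                          seed = 1L, cutoff = -6.8) {
  stopifnot(n_days >= 2L, p_sleep >= 0, p_sleep <= 1, n_sims >= 1L)
  minutes <- 1440L
  n_pairs <- (n_days - 1L) * minutes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sri <- numeric(n_sims)
  chunk <- 2000L
  done <- 0L
  while (done < n_sims) {
    k <- min(chunk, n_sims - done)
    # k replicates x n_days*1440 i.i.d. states, one row per replicate
    s <- matrix(rbinom(k * n_days * minutes, 1L, p_sleep),
                nrow = k, ncol = n_days * minutes)
    mism <- abs(s[, seq_len(n_pairs), drop = FALSE] -
                  s[, seq_len(n_pairs) + minutes, drop = FALSE])
    sri[done + seq_len(k)] <- -100 + 200 * (1 - rowSums(mism) / n_pairs)
    done <- done + k
  }
  q <- unname(quantile(sri, c(0.005, 0.995), type = 7))
  structure(
    list(n_sims = n_sims, mean = mean(sri), sd = sd(sri),
         q005 = q[1], q995 = q[2],
         cutoff = if (is.null(cutoff)) q[1] else cutoff,
         seed = seed),
    class = "sri_null"
  )
}

#' Replace implausibly negative SRI values with null-distribution noise
#'
#' SRI values below the null cutoff (default -6.8) are rarer than random
#' sleep can produce; they are replaced by draws from a Normal distribution
#' with the mean and standard deviation of the simulated null SRI values.
#' Replacement is one-sided: values at or above the cutoff, including large
#' positive values, are never touched, preserving zero as the baseline for
#' random sleep. Replacement draws are not truncated at the cutoff.
#'
#' @param sri_values numeric vector of raw SRI values.
#' @param null an `sri_null` from [simulate_null()].
#' @param seed integer seed for the replacement draws.
#' @return list with `sri_final` (same length, replaced where flagged),
#'   `winsorized` (logical vector), `n_replaced`.
#' @export
winsorize_sri <- function(sri_values, null, seed = 1L) {
  stopifnot(inherits(null, "sri_null"))
  flag <- !is.na(sri_values) & sri_values < null$cutoff
  out <- sri_values
  if (any(flag)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    out[flag] <- rnorm(sum(flag), mean = null$mean, sd = null$sd)
  }
  list(sri_final = out, winsorized = flag, n_replaced = sum(flag))
}

#' Assign SRI exposure quintiles
#'
#' Unweighted sample quintiles: cut points are the 20/40/60/80% quantiles
#' (linear interpolation, type 7); a value equal to a cut point goes to the
#' lower quintile, so groups have equal size up to ties.
#'
#' @param sri_values numeric vector (at least 5 distinct values).
#' @return list with `quintile` (factor Q1..Q5) and `medians` (named vector
#'   of per-quintile median SRI, used as the continuous trend score).
#' @export
assign_quintiles <- function(sri_values) {
  x <- sri_values
  if (length(unique(x[!is.na(x)])) < 5L) {
    stop("need at least 5 distinct SRI values to form quintiles")
  }
  br <- quantile(x, probs = seq(0, 1, 0.2), type = 7, na.rm = TRUE)
  br[1] <- -Inf; br[6] <- Inf
  q <- cut(x, breaks = br, labels = paste0("Q", 1:5), right = TRUE)
  med <- setNames(as.numeric(tapply(x, q, median, na.rm = TRUE)), levels(q))
  list(quintile = q, medians = med)
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
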
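#' Minute-epoch actigraphy QC
#'
#' Parsing, state recoding, and the inclusion filters applied to
#' minute-level wrist-actigraphy state predictions before the SRI is
#' computed:
#' * only minutes without a quality flag and with exactly 60 measured
#'   seconds contribute sleep/wake information (others become missing);
#' * a day is valid iff it has exactly 1,440 timesteps and strictly less
#'   than 2 hours of non-wear;
#' * a participant needs at least three consecutive valid days including a
#'   Saturday or Sunday;
#' * participants with more than 30% missingness of the binary sleep
#'   variable over the selected window are excluded.
#'
#' @name actigraphy_qc
NULL

.states <- c("wake", "sleep", "nonwear", "unknown")
.weekdays <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
.reasons <- c("incomplete_day", "excess_nonwear", "too_few_consecutive_days",
              "no_weekend_day", "flagged_minutes", "excess_missingness")

#' Construct a per-participant sleep series
#'
#' A binary-with-missing minute series (1 = sleep, 0 = wake, NA = excluded
#' epoch) of length `n_days * 1440`, carrying the comparison lag `c`
#' (1,440 minutes) and the weekday of its first day.
#'
#' @param participant_id scalar id.
#' @param values integer vector over \{0, 1, NA\}, length a multiple of 1440.
#' @param start_weekday weekday of the first day ("Mon".."Sun").
#' @param lag lag constant `c` in minutes.
#' @export
sleep_series <- function(participant_id, values, start_weekday = "Mon",
                         lag = 1440L) {
  if (length(values) %% 1440L != 0L) {
    stop("sleep series length must be a multiple of 1440")
  }
  stopifnot(start_weekday %in% .weekdays)
  structure(
    list(participant_id = participant_id, values = as.integer(values),
         start_weekday = start_weekday, lag = as.integer(lag)),
    class = "sleep_series"
  )
}

#' @export
print.sleep_series <- function(x, ...) {
  cat(sprintf("<sleep_series> participant %s: %d days starting %s, %.1f%% missing\n",
              x$participant_id, length(x$values) / 1440L, x$start_weekday,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read minute-epoch records from CSV
#'
#' Expected header: `participant_id,day_index,weekday,minute_of_day,state,
#' quality_flagged,seconds_measured`. Rows are returned typed and ordered by
#' (participant, day, minute); an unknown state string is an error naming
#' the offending line.
#'
#' @param path path to the epoch CSV.
#' @return a `data.table` of epoch records (possibly 0 rows).
#' @export
read_epochs <- function(path) {
  cols <- c("participant_id", "day_index", "weekday", "minute_of_day",
            "state", "quality_flagged", "seconds_measured")
  empty <- data.table::data.table(
    participant_id = character(), day_index = integer(),
    weekday = character(), minute_of_day = integer(), state = character(),
    quality_flagged = logical(), seconds_measured = integer())
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(empty)
  dt <- data.table::fread(path, colClasses = list(
    character = c("participant_id", "weekday", "state"),
    integer = c("day_index", "minute_of_day", "seconds_measured"),
    logical = "quality_flagged"))
  miss <- setdiff(cols, names(dt))
  if (length(miss)) stop("epoch file missing columns: ", paste(miss, collapse = ", "))
  if (nrow(dt) == 0L) return(empty)
  bad <- which(!dt$state %in% .states)
  if (length(bad)) {
    stop(sprintf("unrecognised state '%s' at line %d (data row %d)",
                 dt$state[bad[1]], bad[1] + 1L, bad[1]))
  }
  bad_wd <- which(!dt$weekday %in% .weekdays)
  if (length(bad_wd)) {
    stop(sprintf("unrecognised weekday '%s' at line %d",
                 dt$weekday[bad_wd[1]], bad_wd[1] + 1L))
  }
  if (any(dt$seconds_measured < 0L | dt$seconds_measured > 60L)) {
    stop("seconds_measured outside 0..60")
  }
  data.table::setorder(dt, participant_id, day_index, minute_of_day)
  dt[]
}

#' Recode a predicted state to the binary sleep variable
#'
#' sleep -> 1, wake -> 0; non-wear and unknown -> NA. Additionally, a minute
#' with a quality flag or with fewer than 60 measured seconds is set to NA
#' (it remains a timestep, so the day can still have 1,440 timesteps).
#'
#' @param state character vector over wake/sleep/nonwear/unknown.
#' @param quality_flagged logical vector.
#' @param seconds_measured integer vector.
#' @return integer vector over \{0, 1, NA\}.
#' @export
recode_state <- function(state, quality_flagged = FALSE, seconds_measured = 60L) {
  out <- ifelse(state == "sleep", 1L, ifelse(state == "wake", 0L, NA_integer_))
  out[quality_flagged | seconds_measured != 60L] <- NA_integer_
  out
}

#' Day-level validity
#'
#' A day is valid iff it has exactly 1,440 epochs and strictly fewer than
#' 120 non-wear minutes (the "< 2 hours" rule read literally: 120 is
#' invalid).
#'
#' @param n_epochs epochs present for the day.
#' @param n_nonwear minutes with state non-wear (from the state field).
#' @return list `valid` (logical) and `reason` (`NA`, `"incomplete_day"` or
#'   `"excess_nonwear"`).
#' @export
day_valid <- function(n_epochs, n_nonwear) {
  if (n_epochs != 1440L) {
    list(valid = FALSE, reason = "incomplete_day")
  } else if (n_nonwear >= 120L) {
    list(valid = FALSE, reason = "excess_nonwear")
  } else {
    list(valid = TRUE, reason = NA_character_)
  }
}

#' Select the analysis window of consecutive valid days
#'
#' Returns the longest run of at least three consecutive valid days that
#' contains a Saturday or Sunday (ties broken by earliest start). If no
#' qualifying run exists the participant is excluded with reason
#' `too_few_consecutive_days` (no run of >= 3 valid days) or
#' `no_weekend_day` (such runs exist, but none touches a weekend).
#'
#' @param valid logical vector, one element per calendar day.
#' @param weekdays character vector of weekday labels, same length.
#' @return list with either `start`/`end` (1-based day indices) or `reason`.
#' @export
select_window <- function(valid, weekdays) {
  stopifnot(length(valid) == length(weekdays))
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 3L)
  if (!length(runs)) {
    return(list(start = NA_integer_, end = NA_integer_,
                reason = "too_few_consecutive_days"))
  }
  wk <- vapply(runs, function(i) {
    any(weekdays[starts[i]:ends[i]] %in% c("Sat", "Sun"))
  }, logical(1))
  if (!any(wk)) {
    return(list(start = NA_integer_, end = NA_integer_,
                reason = "no_weekend_day"))
  }
  runs <- runs[wk]
  best <- runs[order(-r$lengths[runs], starts[runs])][1L]
  list(start = starts[best], end = ends[best], reason = NA_character_)
}

#' Missingness rule over the selected window
#'
#' Retained iff the fraction of missing values of the binary sleep variable
#' over the window is at most 0.30 ("more than 30%" excluded; exactly 30%
#' retained).
#'
#' @param values binary-with-missing vector over the window.
#' @export
missingness_ok <- function(values) {
  mean(is.na(values)) <= 0.30
}

#' Run the full actigraphy QC pipeline
#'
#' Applies state recoding, day validity, window selection and the
#' missingness rule in order, returning retained [sleep_series()] objects
#' and an exclusion ledger counting each excluded participant once under
#' the first failing rule. When the missingness rule fails through quality
#' flags / short minutes alone, the participant is counted under
#' `flagged_minutes` rather than `excess_missingness`.
#'
#' @param epochs a `data.table` from [read_epochs()].
#' @return list with `series` (named list of `sleep_series`) and `ledger`
#'   (list of class `exclusion_ledger`: per-reason counts + `retained`,
#'   summing to the number of input participants).
#' @export
qc_pipeline <- function(epochs) {
  . <- participant_id <- day_index <- state <- quality_flagged <-
    seconds_measured <- weekday <- NULL
  ledger <- setNames(as.list(integer(length(.reasons))), .reasons)
  series <- list()
  ids <- unique(epochs$participant_id)
  for (id in ids) {
    p <- epochs[participant_id == id]
    days <- p[, .(
      n_epochs = .N,
      n_nonwear = sum(state == "nonwear"),
      weekday = weekday[1L]
    ), by = day_index]
    dv <- lapply(seq_len(nrow(days)),
                 function(i) day_valid(days$n_epochs[i], days$n_nonwear[i]))
    valid <- vapply(dv, `[[`, logical(1), "valid")
    win <- select_window(valid, days$weekday)
    if (!is.na(win$reason)) {
      reason <- win$reason
      if (reason == "too_few_consecutive_days") {
        # attribute to the day-level failure that broke the run, if
        # ignoring that failure mode would have yielded a qualifying run
        day_reasons <- vapply(dv, `[[`, character(1), "reason")
        for (r in c("incomplete_day", "excess_nonwear")) {
          if (any(day_reasons == r, na.rm = TRUE)) {
            relaxed <- valid | (day_reasons == r & !is.na(day_reasons))
            if (!is.na(select_window(relaxed, days$weekday)$start)) {
              reason <- r
              break
            }
          }
        }
      }
      ledger[[reason]] <- ledger[[reason]] + 1L
      next
    }
    sel_days <- days$day_index[win$start:win$end]
    w <- p[day_index %in% sel_days]
    data.table::setorder(w, day_index, minute_of_day)
    vals <- recode_state(w$state, w$quality_flagged, w$seconds_measured)
    if (!missingness_ok(vals)) {
      flag_frac <- mean(w$quality_flagged | w$seconds_measured != 60L)
      reason <- if (flag_frac > 0.30) "flagged_minutes" else "excess_missingness"
      ledger[[reason]] <- ledger[[reason]] + 1L
      next
    }
    series[[as.character(id)]] <-
      sleep_series(id, vals, start_weekday = days$weekday[win$start])
  }
  ledger$retained <- length(series)
  stopifnot(sum(unlist(ledger)) == length(ids))
  list(series = series, ledger = structure(ledger, class = "exclusion_ledger"))
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Exclusion ledger:\n")
  for (r in .reasons) cat(sprintf("  %-26s %d\n", r, x[[r]]))
  cat(sprintf("  %-26s %d\n", "retained", x$retained))
  invisible(x)
}
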
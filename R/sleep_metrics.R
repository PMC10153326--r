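#' Sleep regularity metrics from epoch-level series
#'
#' The Sleep Regularity Index (SRI) for a contiguous two-day pair is built
#' from the probability p that the participant is in the same state (asleep
#' or awake) at the same clock time on the two days:
#' SRI = 200 p - 100. Identical days score 100; days that agree no better
#' than chance score 0 in expectation; systematic disagreement is negative.
#' A participant observing k valid days contributes k - 1 day-pair values.
#' Nightly onset, duration and WASO summaries and their SDs provide the
#' conventional deviation-based regularity metrics for comparison.
#'
#' @name sleep_metrics
NULL

#' SRI for one contiguous day pair
#'
#' Epoch pairs where either state is missing are excluded from both numerator
#' and denominator. A pair is valid when the number of non-missing epoch pairs
#' reaches `min_pair_fraction` of a full day's epochs; invalid pairs carry
#' `NA` as their value. The value is reported unclipped (it can be negative).
#'
#' @param series an [epoch_series()].
#' @param pair_index j, addressing days (j, j + 1); 1 <= j <= n_days - 1.
#' @param min_pair_fraction minimum fraction of non-missing epoch pairs for
#'   validity (default 0.8).
#' @return one-row data.frame: `participant_id`, `pair_index`, `sri_value`,
#'   `n_valid_pairs`, `weekday_first`, `spans_dst`, `valid`.
#' @export
day_pair_sri <- function(series, pair_index, min_pair_fraction = 0.8) {
  stopifnot(inherits(series, "epoch_series"))
  j <- as.integer(pair_index)
  if (j < 1L || j > series$n_days - 1L) stop("pair_index out of range")
  epd <- length(series$states) %/% series$n_days
  s1 <- series$states[((j - 1L) * epd + 1L):(j * epd)]
  s2 <- series$states[(j * epd + 1L):((j + 1L) * epd)]
  ok <- !is.na(s1) & !is.na(s2)
  n_valid <- sum(ok)
  valid <- n_valid >= min_pair_fraction * epd
  sri <- if (valid) 200 * (sum(s1[ok] == s2[ok]) / n_valid) - 100 else NA_real_
  data.frame(
    participant_id = series$participant_id, pair_index = j,
    sri_value = sri, n_valid_pairs = n_valid,
    weekday_first = series$weekday[j],
    spans_dst = xor(series$dst_flag[j], series$dst_flag[j + 1L]),
    valid = valid, stringsAsFactors = FALSE
  )
}

#' All day-pair SRI values for one participant
#'
#' @inheritParams day_pair_sri
#' @return data.frame with one row per contiguous day pair (n_days - 1 rows),
#'   plus an `exclude` attribute flag set when fewer than 2 pairs are valid
#'   (such participants are excluded upstream of modelling).
#' @export
participant_day_pairs <- function(series, min_pair_fraction = 0.8) {
  stopifnot(inherits(series, "epoch_series"))
  out <- do.call(rbind, lapply(seq_len(series$n_days - 1L), function(j) {
    day_pair_sri(series, j, min_pair_fraction)
  }))
  attr(out, "exclude") <- sum(out$valid) < 2L
  out
}

#' Day-pair SRI table for a cohort
#'
#' @param series_list list of [epoch_series()].
#' @param min_pair_fraction see [day_pair_sri()].
#' @return data.frame of day pairs across participants, with an `excluded`
#'   attribute listing participant ids having fewer than 2 valid pairs.
#' @export
cohort_day_pairs <- function(series_list, min_pair_fraction = 0.8) {
  per <- lapply(series_list, participant_day_pairs, min_pair_fraction = min_pair_fraction)
  excluded <- vapply(per, attr, logical(1), which = "exclude")
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  ids <- sapply(series_list, function(s) s$participant_id)
  attr(out, "excluded") <- ids[excluded]
  out
}

# main sleep period of one day record: sleep runs merged across wake gaps
# shorter than max_gap_h are one period; the period with most sleep wins
main_sleep_span <- function(day_states, epoch_len, max_gap_h = 2) {
  r <- rle(ifelse(is.na(day_states), 0L, day_states))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sleep_runs <- which(r$values == 1L)
  if (!length(sleep_runs)) return(NULL)
  max_gap <- max_gap_h * 3600 / epoch_len
  # group sleep runs: break when the wake/missing gap to the previous run is long
  grp <- cumsum(c(
    1L,
    vapply(seq_along(sleep_runs)[-1], function(i) {
      gap <- starts[sleep_runs[i]] - ends[sleep_runs[i - 1]] - 1L
      as.integer(gap > max_gap)
    }, integer(1))
  ))
  totals <- tapply(r$lengths[sleep_runs], grp, sum)
  best <- as.integer(names(totals)[which.max(totals)])
  runs <- sleep_runs[grp == best]
  c(starts[runs[1]], ends[runs[length(runs)]])
}

#' Nightly onset, duration and WASO summaries
#'
#' Under the noon-to-noon day convention each day record holds at most one
#' main sleep period; for external data the block containing the most sleep is
#' taken as the main period (sleep runs separated by wake gaps under 2 h are
#' merged). Onset is the start of the block, on a linear scale in hours
#' relative to an 18:00 reference; duration is total sleep within the block
#' span; WASO is wake time inside the span. Days with zero sleep epochs yield
#' no summary row.
#'
#' @param series an [epoch_series()].
#' @return data.frame: `participant_id`, `night_index`, `onset_time` (h,
#'   relative to 18:00), `duration` (h), `waso` (h).
#' @export
night_summaries <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  epd <- length(series$states) %/% series$n_days
  el <- series$epoch_len
  rows <- lapply(seq_len(series$n_days), function(d) {
    day <- series$states[((d - 1L) * epd + 1L):(d * epd)]
    span <- main_sleep_span(day, el)
    if (is.null(span)) return(NULL)
    blk <- day[span[1]:span[2]]
    # day record starts at noon; onset hours after 18:00 = offset - 6 h
    onset <- (span[1] - 1L) * el / 3600 - 6
    data.frame(
      participant_id = series$participant_id, night_index = d,
      onset_time = onset,
      duration = sum(blk == 1L, na.rm = TRUE) * el / 3600,
      waso = sum(blk == 0L, na.rm = TRUE) * el / 3600,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(0), night_index = integer(0),
                      onset_time = numeric(0), duration = numeric(0),
                      waso = numeric(0))
  }
  out
}

#' SD-based regularity metrics
#'
#' Sample standard deviations (n - 1 denominator) of nightly sleep duration
#' and of onset time on the fixed 18:00-referenced linear scale — the
#' deviation-based regularity measures used in earlier cardiovascular-risk
#' work, computed for comparison against the SRI.
#'
#' @param nights data.frame from [night_summaries()].
#' @return list with `duration_sd` and `onset_sd` (hours); both `NA` when
#'   fewer than 2 nights have summaries.
#' @export
regularity_sds <- function(nights) {
  if (nrow(nights) < 2L) {
    return(list(duration_sd = NA_real_, onset_sd = NA_real_))
  }
  list(duration_sd = stats::sd(nights$duration), onset_sd = stats::sd(nights$onset_time))
}
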
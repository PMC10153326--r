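#' Synthetic sleep-wake and survival cohort generator
#'
#' Generates epoch-level sleep-wake series with controllable night-to-night
#' variability (onset and duration noise, within-sleep awakenings, nonwear
#' gaps, day-of-week and daylight-saving structure) and linked survival
#' outcomes whose log hazard is a known function of the participant's true
#' regularity. Every downstream stage of the pipeline is testable against this
#' known ground truth without access-controlled cohort data.
#'
#' Days follow a noon-to-noon convention so a night's main sleep period lies
#' within a single day record. States are coded 0 = wake, 1 = sleep,
#' NA = missing (nonwear).
#'
#' @name synthetic_cohort
NULL

#' Sleep simulation parameters
#'
#' @param mean_onset_clock mean sleep onset, hours-of-day on the 24 h clock
#'   (e.g. 23 = 11 pm).
#' @param mean_duration mean nightly sleep duration, hours.
#' @param sigma_onset night-to-night SD of onset, hours.
#' @param sigma_duration night-to-night SD of duration, hours.
#' @param waso_rate expected number of awakenings per night (Poisson).
#' @param waso_bout_mean mean awakening bout length, minutes (exponential).
#' @param nonwear_prob probability per day of one nonwear gap.
#' @param nonwear_len nonwear gap length, hours.
#' @param n_days number of day records (>= 2).
#' @param epoch_len epoch length in seconds; must divide 86400.
#' @param start_weekday weekday of day 1, 0 = Monday ... 6 = Sunday.
#' @param dst_day optional day index at/after which clock labels shift by
#'   `dst_shift` hours (states unchanged; a relabeling of clock time, as a
#'   device recording local time would show).
#' @param dst_shift clock shift in hours, +1 or -1; ignored if `dst_day` is NA.
#' @return object of class `sleep_sim_params`.
#' @export
sleep_sim_params <- function(mean_onset_clock = 23, mean_duration = 8,
                             sigma_onset = 0.75, sigma_duration = 0.75,
                             waso_rate = 2, waso_bout_mean = 15,
                             nonwear_prob = 0.05, nonwear_len = 4,
                             n_days = 7, epoch_len = 30,
                             start_weekday = 0L, dst_day = NA_integer_,
                             dst_shift = 1) {
  if (sigma_onset < 0 || sigma_duration < 0) stop("sigmas must be >= 0")
  if (nonwear_prob < 0 || nonwear_prob > 1) stop("nonwear_prob must be in [0, 1]")
  if (86400 %% epoch_len != 0) stop("epoch_len must divide 86400")
  if (n_days < 2) stop("n_days must be >= 2")
  if (!is.na(dst_day) && !dst_shift %in% c(-1, 1)) stop("dst_shift must be +1 or -1")
  structure(list(
    mean_onset_clock = mean_onset_clock, mean_duration = mean_duration,
    sigma_onset = sigma_onset, sigma_duration = sigma_duration,
    waso_rate = waso_rate, waso_bout_mean = waso_bout_mean,
    nonwear_prob = nonwear_prob, nonwear_len = nonwear_len,
    n_days = as.integer(n_days), epoch_len = as.integer(epoch_len),
    start_weekday = as.integer(start_weekday),
    dst_day = as.integer(dst_day), dst_shift = dst_shift
  ), class = "sleep_sim_params")
}

#' Construct an epoch series object
#'
#' @param participant_id identifier.
#' @param states integer vector over {0 = wake, 1 = sleep, NA = missing},
#'   length a multiple of epochs per day.
#' @param epoch_len epoch length, seconds.
#' @param start POSIXct of the first epoch (noon of day 1 by convention).
#' @param weekday per-day weekday labels 0-6 (0 = Monday).
#' @param dst_flag per-day logical: day at/after a clock shift.
#' @return object of class `epoch_series`.
#' @export
epoch_series <- function(participant_id, states, epoch_len = 30,
                         start = as.POSIXct("2014-06-02 12:00:00", tz = "UTC"),
                         weekday = NULL, dst_flag = NULL) {
  epd <- 86400 %/% epoch_len
  if (length(states) %% epd != 0) stop("states length must be a multiple of epochs per day")
  n_days <- length(states) %/% epd
  if (n_days < 2) stop("series must span at least 2 days")
  if (is.null(weekday)) weekday <- (seq_len(n_days) - 1L) %% 7L
  if (is.null(dst_flag)) dst_flag <- rep(FALSE, n_days)
  stopifnot(length(weekday) == n_days, length(dst_flag) == n_days)
  structure(list(
    participant_id = participant_id, epoch_len = as.integer(epoch_len),
    start = start, states = as.integer(states), n_days = as.integer(n_days),
    weekday = as.integer(weekday), dst_flag = as.logical(dst_flag)
  ), class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> participant %s: %d days x %d epochs of %ds (%.1f%% sleep, %.1f%% missing)\n",
    x$participant_id, x$n_days, length(x$states) / x$n_days, x$epoch_len,
    100 * mean(x$states == 1L, na.rm = TRUE), 100 * mean(is.na(x$states))
  ))
  invisible(x)
}

# one participant's states on the noon-to-noon grid; per-participant sigma
# overrides allow ground-truth regularity to vary across a cohort
simulate_one_series <- function(params, id, onset_shift, duration_shift,
                                sigma_onset = params$sigma_onset,
                                sigma_duration = params$sigma_duration) {
  epd <- 86400L %/% params$epoch_len
  n <- params$n_days * epd
  states <- integer(n) # wake
  for (d in seq_len(params$n_days)) {
    dst_h <- if (!is.na(params$dst_day) && d >= params$dst_day) params$dst_shift else 0
    onset_clock <- stats::rnorm(1, params$mean_onset_clock + onset_shift + dst_h,
                                sigma_onset)
    dur <- stats::rnorm(1, params$mean_duration + duration_shift, sigma_duration)
    dur <- min(max(dur, 0.5), 16)
    # hours since this day record's noon start
    off_h <- (onset_clock - 12) %% 24
    i0 <- (d - 1L) * epd + floor(off_h * 3600 / params$epoch_len) + 1L
    i1 <- i0 + round(dur * 3600 / params$epoch_len) - 1L
    idx <- i0:min(i1, n)
    states[idx] <- 1L
    # awakenings inside the sleep period
    n_bouts <- stats::rpois(1, params$waso_rate)
    if (n_bouts > 0 && length(idx) > 2) {
      for (b in seq_len(n_bouts)) {
        blen <- max(1L, round(stats::rexp(1, 1 / params$waso_bout_mean) * 60 /
                                params$epoch_len))
        bstart <- sample(idx[-1], 1) # keep the first sleep epoch (onset) asleep
        states[bstart:min(bstart + blen - 1L, idx[length(idx)])] <- 0L
      }
    }
  }
  # nonwear gaps: runs of missing
  for (d in seq_len(params$n_days)) {
    if (stats::runif(1) < params$nonwear_prob) {
      glen <- round(params$nonwear_len * 3600 / params$epoch_len)
      g0 <- (d - 1L) * epd + sample.int(epd, 1)
      states[g0:min(g0 + glen - 1L, n)] <- NA_integer_
    }
  }
  days <- seq_len(params$n_days)
  # anchor the start date so calendar weekday matches start_weekday
  # (2014-06-02 is a Monday, code 0)
  start <- as.POSIXct("2014-06-02 12:00:00", tz = "UTC") +
    params$start_weekday * 86400
  epoch_series(
    participant_id = id, states = states, epoch_len = params$epoch_len,
    start = start,
    weekday = (params$start_weekday + days - 1L) %% 7L,
    dst_flag = if (is.na(params$dst_day)) rep(FALSE, params$n_days) else days >= params$dst_day
  )
}

#' Simulate epoch-level sleep-wake series for a cohort
#'
#' Each night has one main sleep period with onset ~ Normal(mean_onset +
#' participant offset, sigma_onset) and duration ~ Normal(mean_duration +
#' offset, sigma_duration) truncated to [0.5, 16] h; awakening (WASO) bouts
#' are wake intervals inserted inside the sleep period at the stated Poisson
#' rate and exponential length; nonwear gaps are runs of missing states. If a
#' daylight-saving day is set, clock labels shift by +/-1 h from that day
#' onward (a relabeling; states unchanged in body time).
#'
#' @param params a [sleep_sim_params()].
#' @param participant_offsets data.frame with columns `participant_id`,
#'   `onset_shift` and `duration_shift` (hours); one row per participant.
#'   Optional columns `sigma_onset` and `sigma_duration` override the shared
#'   noise SDs per participant, giving each participant their own
#'   ground-truth regularity.
#' @param seed integer seed.
#' @return list of [epoch_series()] objects, one per participant.
#' @export
simulate_sleep_series <- function(params, participant_offsets, seed = 1L) {
  stopifnot(inherits(params, "sleep_sim_params"))
  req <- c("participant_id", "onset_shift", "duration_shift")
  if (!all(req %in% names(participant_offsets))) {
    stop("participant_offsets needs columns: ", paste(req, collapse = ", "))
  }
  po <- participant_offsets
  if (is.null(po$sigma_onset)) po$sigma_onset <- params$sigma_onset
  if (is.null(po$sigma_duration)) po$sigma_duration <- params$sigma_duration
  set.seed(seed)
  lapply(seq_len(nrow(po)), function(i) {
    simulate_one_series(params, po$participant_id[i], po$onset_shift[i],
                        po$duration_shift[i], po$sigma_onset[i],
                        po$sigma_duration[i])
  })
}

#' Survival simulation parameters
#'
#' @param log_hazard_fn function(sri, covariates_row_or_table) -> log hazard
#'   offset added to log(baseline_rate); vectorized over participants.
#' @param baseline_rate baseline event rate, events per person-year.
#' @param admin_censor administrative censoring time, years.
#' @param cause_mix named probabilities over causes (must sum to 1), e.g.
#'   `c(CVD = 0.20, cancer = 0.57, other = 0.23)` as observed in large
#'   mortality cohorts.
#' @return object of class `surv_sim_params`.
#' @export
surv_sim_params <- function(log_hazard_fn = function(sri, cov) 0,
                            baseline_rate = 0.005, admin_censor = 7.1,
                            cause_mix = c(CVD = 0.20, cancer = 0.57, other = 0.23)) {
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (admin_censor < 0) stop("admin_censor must be >= 0")
  if (abs(sum(cause_mix) - 1) > 1e-8) stop("cause_mix must sum to 1")
  if (is.null(names(cause_mix))) stop("cause_mix must be named")
  structure(list(
    log_hazard_fn = log_hazard_fn, baseline_rate = baseline_rate,
    admin_censor = admin_censor, cause_mix = cause_mix
  ), class = "surv_sim_params")
}

#' Simulate survival outcomes from true regularity
#'
#' Event times are exponential with individual rate
#' `baseline_rate * exp(log_hazard_fn(true_sri, covariates))`; administrative
#' censoring at `admin_censor` years; cause of death assigned by `cause_mix`.
#'
#' @param true_sri numeric vector of per-participant true regularity scores.
#' @param covariates data.frame of covariates (row-aligned with `true_sri`),
#'   passed through to `log_hazard_fn`; may be NULL.
#' @param params a [surv_sim_params()].
#' @param seed integer seed.
#' @return data.frame with `participant_id`, `follow_time` (years), `event`
#'   (0/1) and `cause` (one of the cause_mix names or "none").
#' @export
simulate_survival <- function(true_sri, covariates = NULL, params = surv_sim_params(),
                              seed = 1L) {
  stopifnot(inherits(params, "surv_sim_params"))
  n <- length(true_sri)
  lh <- params$log_hazard_fn(true_sri, covariates)
  if (length(lh) == 1L) lh <- rep(lh, n)
  bad <- which(!is.finite(lh))
  if (length(bad)) {
    stop("non-finite log hazard for participant(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  set.seed(seed)
  rate <- params$baseline_rate * exp(lh)
  t_event <- stats::rexp(n, rate)
  event <- as.integer(t_event <= params$admin_censor)
  follow_time <- pmin(t_event, params$admin_censor)
  cause <- rep("none", n)
  if (any(event == 1L)) {
    cause[event == 1L] <- sample(names(params$cause_mix), sum(event),
                                 replace = TRUE, prob = params$cause_mix)
  }
  ids <- if (!is.null(covariates) && "participant_id" %in% names(covariates)) {
    covariates$participant_id
  } else {
    seq_len(n)
  }
  data.frame(participant_id = ids, follow_time = follow_time,
             event = event, cause = cause, stringsAsFactors = FALSE)
}

#' Simulate participant-level confounders
#'
#' Demographic and clinical covariates with distributions loosely matching a
#' late-middle-aged accelerometry cohort (mean age 62, 56% female, mostly
#' White ethnicity, ~45% retired). Purely a stand-in for testing adjustment
#' machinery; no confounding structure with regularity unless built in by the
#' caller.
#'
#' @param n number of participants.
#' @param seed integer seed.
#' @return data.frame with one row per participant.
#' @export
simulate_covariates <- function(n, seed = 1L) {
  set.seed(seed)
  age <- pmin(pmax(stats::rnorm(n, 62, 8), 43), 79)
  smoking <- sample(c("never", "former", "current"), n, TRUE, c(0.55, 0.35, 0.10))
  data.frame(
    participant_id = seq_len(n),
    age = age,
    sex = factor(sample(c("female", "male"), n, TRUE, c(0.56, 0.44))),
    ethnicity = factor(sample(c("White", "Asian", "Black", "mixed", "other"),
                              n, TRUE, c(0.94, 0.02, 0.02, 0.01, 0.01))),
    townsend = stats::rnorm(n, -1.5, 3),
    retired = stats::rbinom(n, 1, stats::plogis((age - 63) / 3)),
    shift_work = stats::rbinom(n, 1, 0.08),
    sick_disabled = stats::rbinom(n, 1, 0.03),
    income = factor(sample(1:5, n, TRUE, c(0.15, 0.25, 0.25, 0.22, 0.13)),
                    ordered = TRUE),
    education = factor(sample(1:6, n, TRUE), ordered = TRUE),
    smoking_status = factor(smoking, levels = c("never", "former", "current")),
    pack_years = ifelse(smoking == "never", 0, stats::rgamma(n, 2, 0.12)),
    med_sedative = stats::rbinom(n, 1, 0.02),
    med_antidepressant = stats::rbinom(n, 1, 0.07),
    med_antipsychotic = stats::rbinom(n, 1, 0.01),
    prev_cancer = stats::rbinom(n, 1, 0.09),
    prev_cvd = stats::rbinom(n, 1, 0.12),
    prev_mental = stats::rbinom(n, 1, 0.10),
    prev_nervous = stats::rbinom(n, 1, 0.06),
    prev_diabetes = stats::rbinom(n, 1, 0.05),
    bmi = pmax(stats::rnorm(n, 26.7, 4.5), 15),
    sys_bp = stats::rnorm(n, 137, 18),
    bp_med = stats::rbinom(n, 1, 0.21),
    phys_activity = stats::rgamma(n, 2, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Inject missingness completely at random into covariate columns
#'
#' Outcome and identifier columns (`participant_id`, `follow_time`, `event`,
#' `cause`) are protected and may not be targeted.
#'
#' @param cohort participant-level data.frame.
#' @param columns character vector of column names to receive missingness.
#' @param rate per-column probability each entry is set missing, in [0, 1).
#' @param seed integer seed.
#' @return a copy of `cohort` with missing entries; input unmodified.
#' @export
inject_missingness <- function(cohort, columns, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  protected <- c("participant_id", "follow_time", "event", "cause")
  unknown <- setdiff(columns, names(cohort))
  if (length(unknown)) stop("unknown column(s): ", paste(unknown, collapse = ", "))
  hit <- intersect(columns, protected)
  if (length(hit)) {
    stop("outcome/identifier column(s) are protected: ", paste(hit, collapse = ", "))
  }
  if (rate == 0) return(cohort)
  set.seed(seed)
  for (cl in columns) {
    miss <- stats::runif(nrow(cohort)) < rate
    cohort[[cl]][miss] <- NA
  }
  cohort
}
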
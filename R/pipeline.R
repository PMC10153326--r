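#' End-to-end pipeline and delimited-text interfaces
#'
#' Config-driven orchestration of the full analysis on a synthetic cohort:
#' simulate epoch-level sleep-wake series -> score day-pair SRI and nightly
#' summaries -> standardize SRI with the mixed model -> simulate linked
#' survival outcomes -> inject and impute missing confounders -> spline Cox
#' models -> discrete-time models with standardized cumulative incidence.
#' All I/O is delimited text; one master seed spawns per-stage sub-seeds so
#' stages are individually re-runnable and the whole run is deterministic.
#'
#' @name pipeline
NULL

# ---- epoch-series text format -------------------------------------------

#' Write epoch series to delimited text
#'
#' Columns: `participant_id`, `timestamp` (ISO-8601 UTC), `state`
#' (0 = wake, 1 = sleep, NA = missing). Paths ending in `.gz` are
#' gzip-compressed transparently.
#'
#' @param series_list list of [epoch_series()].
#' @param path output file path.
#' @export
write_epoch_series <- function(series_list, path) {
  ts_cache <- new.env() # participants usually share a timestamp grid
  rows <- lapply(series_list, function(s) {
    n <- length(s$states)
    key <- paste(format(s$start, "%Y%m%d%H%M%S"), s$epoch_len, n)
    ts <- ts_cache[[key]]
    if (is.null(ts)) {
      ts <- format(s$start + (seq_len(n) - 1) * s$epoch_len,
                   "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      ts_cache[[key]] <- ts
    }
    data.table::data.table(
      participant_id = rep(s$participant_id, n),
      timestamp = ts,
      state = s$states
    )
  })
  data.table::fwrite(data.table::rbindlist(rows), path, na = "NA", quote = FALSE)
}

#' Read epoch series from delimited text
#'
#' Inverse of [write_epoch_series()]; gzip inputs are read transparently.
#' Weekday labels (0 = Monday) are derived from the calendar date of each
#' noon-to-noon day; DST flags are not serialized and read back as FALSE.
#' A malformed state value raises an error naming the offending line.
#'
#' @param path input file path (plain or .gz).
#' @return list of [epoch_series()].
#' @export
read_epoch_series <- function(path) {
  file <- path
  if (grepl("\\.gz$", path)) {
    # stream-decompress to a scratch file for the fast reader
    file <- tempfile(fileext = ".csv")
    on.exit(unlink(file))
    zin <- gzfile(path, "rb")
    fout <- base::file(file, "wb")
    while (length(chunk <- readBin(zin, "raw", 2^24))) writeBin(chunk, fout)
    close(zin); close(fout)
  }
  d <- data.table::fread(file, colClasses = list(character = 1:3),
                         na.strings = NULL, showProgress = FALSE)
  ok <- d$state %in% c("0", "1", "NA", "")
  if (!all(ok)) {
    ln <- which(!ok)[1] + 1L # + header line
    stop("malformed state value '", d$state[!ok][1], "' at line ", ln)
  }
  states_all <- ifelse(d$state == "1", 1L, ifelse(d$state == "0", 0L, NA_integer_))
  idx <- split(seq_len(nrow(d)), factor(d$participant_id,
                                        levels = unique(d$participant_id)))
  lapply(names(idx), function(id) {
    rows <- idx[[id]]
    ts12 <- as.POSIXct(d$timestamp[rows[1:2]], format = "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC")
    el <- as.integer(round(as.numeric(difftime(ts12[2], ts12[1], units = "secs"))))
    n_days <- length(rows) %/% (86400 %/% el)
    day_starts <- ts12[1] + (seq_len(n_days) - 1) * 86400
    wd <- (as.POSIXlt(day_starts, tz = "UTC")$wday + 6L) %% 7L # Monday = 0
    id_val <- utils::type.convert(id, as.is = TRUE)
    epoch_series(id_val, states_all[rows], epoch_len = el, start = ts12[1],
                 weekday = wd)
  })
}

#' Write/read a participant-level table as delimited text
#'
#' @param table data.frame.
#' @param path file path (gzip-transparent on write via `.gz` suffix).
#' @export
write_cohort_table <- function(table, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(table, con, row.names = FALSE, na = "NA")
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in intersect(c("sex", "ethnicity", "smoking_status"), names(d))) {
    d[[cl]] <- factor(d[[cl]])
  }
  for (cl in intersect(c("income", "education"), names(d))) {
    d[[cl]] <- factor(d[[cl]], ordered = TRUE)
  }
  d
}

# ---- configuration -------------------------------------------------------

#' Default pipeline configuration
#'
#' All simulation, scoring and modelling settings plus the master seed; a
#' plain named list, round-trippable through YAML.
#'
#' @param n_participants cohort size.
#' @param seed master seed; stage sub-seeds are derived from it.
#' @return named list.
#' @export
default_run_config <- function(n_participants = 2000, seed = 20140602) {
  list(
    n_participants = n_participants,
    seed = seed,
    sleep = list(
      mean_onset_clock = 23, mean_duration = 8,
      sigma_onset_range = c(0.1, 2.5), sigma_duration_range = c(0.1, 1.5),
      between_onset_sd = 1.0, between_duration_sd = 0.5,
      waso_rate = 2, waso_bout_mean = 15,
      nonwear_prob = 0.05, nonwear_len = 4,
      n_days = 7, epoch_len = 30
    ),
    metrics = list(min_pair_fraction = 0.8),
    hazard = list(type = "ushape", baseline_rate = 0.005, admin_censor = 7.1),
    missing = list(rate = 0.02,
                   columns = c("townsend", "pack_years", "income")),
    imputation = list(m = 10, k_donors = 5, n_iter = 5),
    models = list(covariate_set = "primary", outcome = "all",
                  interval_len = 0.25, bootstrap_B = 200)
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) yaml::write_yaml(config, path)

# FNV-1a hash of the serialized config, for provenance stamping
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(config)), collapse = "\n"))
  h <- 21661362L
  for (b in bytes) h <- as.integer((bitwXor(h, as.integer(b)) * 16777) %% 2^30)
  sprintf("%08x", h)
}

#' Log-hazard scenario constructor
#'
#' Named ground-truth shapes for the synthetic survival stage: `"null"`
#' (no association), `"linear"` (`beta` per SRI unit), `"threshold"`
#' (`log_hr` below `cutoff`), and `"ushape"` (quadratic in SRI around
#' `center`, scaled so the stated `log_hr_at` is reached `at` units away).
#' The ushape default centers the quadratic near the top of the generator's
#' SRI range, giving a convex risk curve that is highest for the most
#' irregular sleepers and flattens above the median.
#'
#' @param type scenario name.
#' @param ... scenario parameters with defaults: linear `beta = -0.03`;
#'   threshold `cutoff = 45`, `log_hr = log(2)`; ushape `center = 80`,
#'   `at = 30`, `log_hr_at = log(1.5)`.
#' @return function(sri, covariates) -> log hazard offset.
#' @export
make_log_hazard_fn <- function(type = c("null", "linear", "threshold", "ushape"), ...) {
  type <- match.arg(type)
  a <- list(...)
  switch(type,
    null = function(sri, cov) rep(0, length(sri)),
    linear = {
      beta <- a$beta %||% -0.03
      function(sri, cov) beta * (sri - 60)
    },
    threshold = {
      cutoff <- a$cutoff %||% 45
      log_hr <- a$log_hr %||% log(2)
      function(sri, cov) log_hr * (sri < cutoff)
    },
    ushape = {
      center <- a$center %||% 80
      at <- a$at %||% 30
      log_hr_at <- a$log_hr_at %||% log(1.5)
      function(sri, cov) log_hr_at * ((sri - center) / at)^2
    }
  )
}

# ---- orchestration -------------------------------------------------------

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> score -> standardize -> survival -> missingness ->
#' imputation -> Cox -> discrete-time in order and returns a run report. If
#' `out_dir` is given, all intermediate and result tables are written there
#' as delimited text, each stamped with the config hash.
#'
#' @param config configuration list (see [default_run_config()]).
#' @param out_dir optional output directory.
#' @return list of class `srisurv_report`: sample accounting, knots, event
#'   counts, HRs at the 5th/median/95th exposure percentiles, test p-values,
#'   time-varying HR grid and standardized risk curves.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  set.seed(config$seed)
  sub <- sample.int(2^30, 8) # per-stage sub-seeds
  n <- config$n_participants
  sl <- config$sleep

  # stage 1: sleep series with per-participant ground-truth irregularity
  set.seed(sub[1])
  offsets <- data.frame(
    participant_id = seq_len(n),
    onset_shift = stats::rnorm(n, 0, sl$between_onset_sd),
    duration_shift = stats::rnorm(n, 0, sl$between_duration_sd),
    sigma_onset = stats::runif(n, sl$sigma_onset_range[1], sl$sigma_onset_range[2]),
    sigma_duration = stats::runif(n, sl$sigma_duration_range[1],
                                  sl$sigma_duration_range[2])
  )
  params <- sleep_sim_params(
    mean_onset_clock = sl$mean_onset_clock, mean_duration = sl$mean_duration,
    sigma_onset = 0, sigma_duration = 0, waso_rate = sl$waso_rate,
    waso_bout_mean = sl$waso_bout_mean, nonwear_prob = sl$nonwear_prob,
    nonwear_len = sl$nonwear_len, n_days = sl$n_days, epoch_len = sl$epoch_len
  )
  series <- simulate_sleep_series(params, offsets, seed = sub[2])

  # stage 2: scoring
  pairs <- cohort_day_pairs(series, config$metrics$min_pair_fraction)
  nights <- lapply(series, night_summaries)
  sds <- do.call(rbind, lapply(nights, function(ns) {
    s <- regularity_sds(ns)
    data.frame(participant_id = ns$participant_id[1],
               duration_sd = s$duration_sd, onset_sd = s$onset_sd,
               sleep_duration = mean(ns$duration), waso = mean(ns$waso))
  }))
  excluded <- attr(pairs, "excluded")

  # stage 3: mixed-model standardization
  lmm <- fit_sri_lmm(pairs)
  sri_tab <- standardized_sri(lmm)
  sri_tab$participant_id <- type.convert(sri_tab$participant_id, as.is = TRUE)

  # stage 4: covariates and survival linked to the standardized SRI
  covars <- simulate_covariates(n, seed = sub[3])
  cohort <- merge(merge(sri_tab, sds, by = "participant_id"), covars,
                  by = "participant_id")
  hz <- config$hazard
  lh_fn <- do.call(make_log_hazard_fn, c(list(type = hz$type),
                                         hz[setdiff(names(hz), c("type", "baseline_rate", "admin_censor"))]))
  surv <- simulate_survival(cohort$sri_standardized, cohort,
                            surv_sim_params(lh_fn, hz$baseline_rate, hz$admin_censor),
                            seed = sub[4])
  cohort <- merge(cohort, surv, by = "participant_id")

  # stage 5-6: missingness and imputation
  ms <- config$missing
  if (!is.null(ms) && ms$rate > 0) {
    cohort_mis <- inject_missingness(cohort, ms$columns, ms$rate, seed = sub[5])
  } else {
    cohort_mis <- cohort
  }
  imp <- pmm_impute(cohort_mis, m = config$imputation$m,
                    k_donors = config$imputation$k_donors,
                    n_iter = config$imputation$n_iter, seed = sub[6])

  # stage 7: Cox across imputations, Rubin-pooled exposure coefficients
  md <- config$models
  q <- stats::quantile(cohort$sri_standardized, c(0.05, 0.5, 0.95), type = 7)
  spec <- rcs_spec(knot_percentiles(cohort$sri_standardized, c(10, 50, 90)))
  fits <- lapply(imp$tables, function(tb) {
    fit_cox(tb, "sri_standardized",
            exposure_specs = list(sri_standardized = spec),
            covariates = md$covariate_set, outcome = md$outcome)
  })
  cols <- fits[[1]]$exposure_cols$sri_standardized
  pooled <- pool_rubin(lapply(fits, function(f) f$coef[cols]),
                       lapply(fits, function(f) f$vcov[cols, cols, drop = FALSE]))
  hr_at <- function(x) {
    d <- rcs_design(x, spec) - rcs_design(q[[2]], spec)
    exp(as.numeric(d %*% pooled$estimate))
  }
  global_p <- global_spline_test(fits[[1]])$p
  curve <- hr_curve(fits[[1]], reference = q[[2]],
                    grid = seq(q[[1]], q[[3]], length.out = 50))

  # stage 8: discrete-time on the first completed dataset
  first <- imp$tables[[1]]
  pp <- expand_person_periods(first, md$interval_len, md$outcome)
  dfit <- fit_discrete_hazard(pp, "sri_standardized", covariates = md$covariate_set,
                              exposure_spec = spec, with_interaction = TRUE)
  prop <- proportionality_test(dfit)
  tmax <- dfit$n_intervals * dfit$interval_len
  tv <- time_varying_hr(dfit, c(q[[1]], q[[3]]), q[[2]],
                        seq(md$interval_len, tmax, by = md$interval_len))
  risk <- bootstrap_risk_ci(first, c(q[[1]], q[[2]], q[[3]]),
                            B = md$bootstrap_B, seed = sub[7],
                            covariates = md$covariate_set,
                            interval_len = md$interval_len, outcome = md$outcome)

  # sample-characteristics accounting by SRI tertile
  tert <- cut(cohort$sri_standardized,
              stats::quantile(cohort$sri_standardized, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE, labels = c("T1", "T2", "T3"))
  tertiles <- data.frame(
    tertile = levels(tert),
    n = as.integer(table(tert)),
    mean_sri = as.numeric(tapply(cohort$sri_standardized, tert, mean)),
    mean_age = as.numeric(tapply(cohort$age, tert, mean)),
    deaths = as.integer(tapply(cohort$event, tert, sum))
  )

  report <- structure(list(
    config_hash = config_hash(config),
    seed = config$seed,
    accounting = list(
      n_simulated = n, n_excluded_sri = length(excluded),
      n_analysis = nrow(cohort),
      n_events = sum(cohort$event),
      events_by_cause = table(cohort$cause[cohort$event == 1])
    ),
    exposure_percentiles = stats::setNames(as.numeric(q), c("p5", "median", "p95")),
    exposure_knots = spec$knots,
    lmm = list(grand_mean = lmm$grand_mean, var_participant = lmm$var_participant,
               var_residual = lmm$var_residual, singular = lmm$singular),
    cox = list(hr_p5 = hr_at(q[[1]]), hr_p95 = hr_at(q[[3]]),
               global_spline_p = global_p, pooled_m = pooled$m),
    discrete = list(proportionality_p = prop$p,
                    time_knots = dfit$time_spec$knots,
                    bootstrap_B = attr(risk, "B_used")),
    tertiles = tertiles,
    hr_curve = curve, time_varying_hr = tv, risk_curves = risk
  ), class = "srisurv_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(d) { d$config_hash <- report$config_hash; d }
    write_cohort_table(stamp(pairs), file.path(out_dir, "day_pairs.csv"))
    write_cohort_table(stamp(cohort), file.path(out_dir, "cohort.csv"))
    write_cohort_table(stamp(curve), file.path(out_dir, "hr_curve.csv"))
    write_cohort_table(stamp(tv), file.path(out_dir, "time_varying_hr.csv"))
    write_cohort_table(stamp(as.data.frame(risk)), file.path(out_dir, "risk_curves.csv"))
    yaml::write_yaml(list(
      config_hash = report$config_hash,
      accounting = lapply(report$accounting, function(x) if (is.table(x)) as.list(x) else x),
      exposure_percentiles = as.list(report$exposure_percentiles),
      exposure_knots = report$exposure_knots,
      cox = report$cox, discrete = report$discrete
    ), file.path(out_dir, "run_report.yaml"))
  }
  report
}

#' @export
print.srisurv_report <- function(x, ...) {
  a <- x$accounting
  cat(sprintf("<srisurv_report> config %s, seed %d\n", x$config_hash, x$seed))
  cat(sprintf("  cohort: %d simulated, %d excluded (<2 valid pairs), %d analyzed, %d deaths\n",
              a$n_simulated, a$n_excluded_sri, a$n_analysis, a$n_events))
  q <- x$exposure_percentiles
  cat(sprintf("  SRI percentiles: 5th %.1f, median %.1f, 95th %.1f\n",
              q[["p5"]], q[["median"]], q[["p95"]]))
  cat(sprintf("  Cox HR vs median: %.2f (5th), %.2f (95th); global spline p = %.3g\n",
              x$cox$hr_p5, x$cox$hr_p95, x$cox$global_spline_p))
  cat(sprintf("  proportionality (time x SRI) p = %.3g; bootstrap B = %d\n",
              x$discrete$proportionality_p, x$discrete$bootstrap_B))
  invisible(x)
}
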
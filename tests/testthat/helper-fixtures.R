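# Test fixtures built in code.

# epoch series from per-day state vectors; epoch length chosen so the given
# number of epochs fills a day exactly
make_series <- function(days, id = "p1") {
  epd <- length(days[[1]])
  stopifnot(86400 %% epd == 0)
  epoch_series(id, unlist(days), epoch_len = 86400 %/% epd)
}

# independent SRI oracle: brute-force enumeration of aligned epoch pairs
brute_sri <- function(s1, s2) {
  ok <- !is.na(s1) & !is.na(s2)
  if (!sum(ok)) return(NA_real_)
  200 * mean(s1[ok] == s2[ok]) - 100
}

# quick survival cohort with a log-linear SRI effect on the hazard
sim_loglinear_cohort <- function(n, beta = 0, baseline = 0.05, censor = 5,
                                 seed = 1) {
  set.seed(seed)
  sri <- runif(n, 30, 90)
  params <- surv_sim_params(function(s, cov) beta * (s - 60), baseline, censor)
  surv <- simulate_survival(sri, NULL, params, seed = seed + 1)
  surv$sri_standardized <- sri
  surv
}
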
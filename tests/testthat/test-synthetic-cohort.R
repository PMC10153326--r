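test_that("noise-free sleeper is exactly 24-hour periodic", {
  p <- sleep_sim_params(sigma_onset = 0, sigma_duration = 0, waso_rate = 0,
                        nonwear_prob = 0, n_days = 5, epoch_len = 60)
  off <- data.frame(participant_id = 1, onset_shift = 0.3, duration_shift = -0.5)
  s <- simulate_sleep_series(p, off, seed = 3)[[1]]
  epd <- 1440
  st <- matrix(s$states, nrow = epd)
  for (d in 2:5) expect_identical(st[, d], st[, 1])
  expect_equal(participant_day_pairs(s)$sri_value, rep(100, 4))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sleep_sim_params(epoch_len = 7), "divide 86400")
  expect_error(sleep_sim_params(n_days = 1), "n_days")
  expect_error(sleep_sim_params(nonwear_prob = 1.5), "nonwear_prob")
  expect_error(surv_sim_params(cause_mix = c(CVD = 0.5, cancer = 0.2)), "sum to 1")
  expect_error(surv_sim_params(baseline_rate = 0), "baseline_rate")
})

test_that("fixed seed reproduces identical series; different seeds differ", {
  p <- sleep_sim_params(n_days = 3, epoch_len = 300)
  off <- data.frame(participant_id = 1:3, onset_shift = 0, duration_shift = 0)
  a <- simulate_sleep_series(p, off, seed = 42)
  b <- simulate_sleep_series(p, off, seed = 42)
  c <- simulate_sleep_series(p, off, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("downstream SRI decreases in onset variability", {
  off <- data.frame(participant_id = 1:20, onset_shift = 0, duration_shift = 0)
  mean_sri <- vapply(c(0.1, 1, 2.5), function(sg) {
    p <- sleep_sim_params(sigma_onset = sg, sigma_duration = 0.1, waso_rate = 0,
                          nonwear_prob = 0, n_days = 7, epoch_len = 120)
    ser <- simulate_sleep_series(p, off, seed = 7)
    mean(vapply(ser, function(s) mean(participant_day_pairs(s)$sri_value),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sri) < 0))
})

test_that("an all-missing day invalidates both adjacent pairs", {
  p <- sleep_sim_params(sigma_onset = 0, sigma_duration = 0, waso_rate = 0,
                        nonwear_prob = 0, n_days = 5, epoch_len = 300)
  off <- data.frame(participant_id = 1, onset_shift = 0, duration_shift = 0)
  s <- simulate_sleep_series(p, off, seed = 3)[[1]]
  epd <- 288
  s$states[(2 * epd + 1):(3 * epd)] <- NA # day 3 nonwear
  prs <- participant_day_pairs(s)
  expect_equal(prs$valid, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("DST shifts clock labels of subsequent days", {
  base <- sleep_sim_params(sigma_onset = 0, sigma_duration = 0, waso_rate = 0,
                           nonwear_prob = 0, n_days = 4, epoch_len = 120)
  dst <- sleep_sim_params(sigma_onset = 0, sigma_duration = 0, waso_rate = 0,
                          nonwear_prob = 0, n_days = 4, epoch_len = 120,
                          dst_day = 3, dst_shift = 1)
  off <- data.frame(participant_id = 1, onset_shift = 0, duration_shift = 0)
  s0 <- simulate_sleep_series(base, off, seed = 5)[[1]]
  s1 <- simulate_sleep_series(dst, off, seed = 5)[[1]]
  epd <- 720
  shift <- 3600 / 120
  # day 2 unchanged; day 3 onward the sleep block sits one hour later
  expect_identical(s1$states[(epd + 1):(2 * epd)], s0$states[(epd + 1):(2 * epd)])
  d3_0 <- s0$states[(2 * epd + 1):(3 * epd)]
  d3_1 <- s1$states[(2 * epd + 1):(3 * epd)]
  expect_identical(d3_1[(shift + 1):epd], d3_0[1:(epd - shift)])
  expect_equal(s1$dst_flag, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(participant_day_pairs(s1)$spans_dst, c(FALSE, TRUE, FALSE))
})

test_that("null-hazard survival matches the exponential closed form", {
  params <- surv_sim_params(function(s, cov) rep(0, length(s)),
                            baseline_rate = 0.05, admin_censor = 5)
  surv <- simulate_survival(runif(20000, 30, 90), NULL, params, seed = 12)
  expected <- 1 - exp(-0.05 * 5) # 0.2212
  expect_equal(mean(surv$event), expected, tolerance = 0.02)
  expect_true(all(surv$follow_time <= 5))
  expect_true(all(surv$cause[surv$event == 0] == "none"))
  expect_true(all(surv$cause[surv$event == 1] %in% c("CVD", "cancer", "other")))
})

test_that("zero administrative censoring yields no events", {
  params <- surv_sim_params(admin_censor = 0)
  surv <- simulate_survival(runif(50, 30, 90), NULL, params, seed = 1)
  expect_true(all(surv$event == 0))
  expect_true(all(surv$follow_time == 0))
})

test_that("step log-hazard is recovered as a Cox hazard ratio of 2", {
  set.seed(77)
  sri <- runif(20000, 30, 70)
  params <- surv_sim_params(function(s, cov) log(2) * (s < 41),
                            baseline_rate = 0.03, admin_censor = 7)
  surv <- simulate_survival(sri, NULL, params, seed = 78)
  low <- as.integer(sri < 41)
  fit <- survival::coxph(survival::Surv(surv$follow_time, surv$event) ~ low)
  ci <- exp(confint(fit))
  expect_gt(2, ci[1]); expect_lt(2, ci[2])
  expect_equal(unname(exp(coef(fit))), 2, tolerance = 0.1)
})

test_that("non-finite log hazard is rejected with the participant named", {
  params <- surv_sim_params(function(s, cov) ifelse(s > 50, Inf, 0))
  expect_error(simulate_survival(c(40, 60), NULL, params), "participant.*2")
})

test_that("MCAR injection hits the stated per-column rate and guards outcomes", {
  cohort <- data.frame(participant_id = 1:10000, x = rnorm(10000),
                       follow_time = 1, event = 0, cause = "none")
  out0 <- inject_missingness(cohort, "x", 0, seed = 1)
  expect_identical(out0, cohort)

  out <- inject_missingness(cohort, "x", 0.02, seed = 2)
  n_miss <- sum(is.na(out$x))
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.02)
  expect_gte(n_miss, bounds[1]); expect_lte(n_miss, bounds[2])
  expect_false(anyNA(cohort$x)) # input unmodified

  expect_error(inject_missingness(cohort, "follow_time", 0.1), "protected")
  expect_error(inject_missingness(cohort, "nope", 0.1), "unknown column")
  expect_error(inject_missingness(cohort, "x", 1), "rate")
})
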
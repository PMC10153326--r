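test_that("person-period expansion puts each exit in the right interval", {
  tab <- data.frame(participant_id = 1:3,
                    follow_time = c(1.0, 0.30, 2.6),
                    event = c(0L, 1L, 1L),
                    cause = c("none", "CVD", "cancer"),
                    sri_standardized = c(50, 60, 70))
  pp <- expand_person_periods(tab)
  expect_equal(sum(pp$participant_id == 1), 4) # censored at exactly 1.0 y
  expect_equal(sum(pp$event_in_interval[pp$participant_id == 1]), 0)
  p2 <- pp[pp$participant_id == 2, ]
  expect_equal(nrow(p2), 2)
  expect_equal(p2$event_in_interval, c(0L, 1L))
  expect_equal(p2$interval_midpoint, c(0.125, 0.375))

  # arithmetic oracle for the table size
  expect_equal(nrow(pp), sum(ceiling(tab$follow_time / 0.25)))
  # follow-up conserved to within one interval per participant
  per <- tapply(pp$interval_index, pp$participant_id, max) * 0.25
  expect_true(all(abs(per - tab$follow_time) < 0.25 + 1e-12))

  # competing-cause deaths terminate risk without an event
  ppc <- expand_person_periods(tab, outcome = "CVD")
  expect_equal(sum(ppc$event_in_interval), 1)
  expect_equal(nrow(ppc), nrow(pp))
})

test_that("single-interval intercept-only fit reproduces the event fraction", {
  set.seed(3)
  tab <- data.frame(participant_id = 1:400,
                    follow_time = rep(0.2, 400),
                    event = rbinom(400, 1, 0.3),
                    cause = "none")
  tab$cause[tab$event == 1] <- "other"
  pp <- expand_person_periods(tab)
  fit <- fit_discrete_hazard(pp, exposure = NULL, time_spec = "factor")
  expect_equal(plogis(unname(fit$coef[1])), mean(tab$event), tolerance = 1e-8)
})

test_that("standardized risk equals the life-table estimator without covariates", {
  tab <- sim_loglinear_cohort(500, beta = 0, baseline = 0.2, censor = 2, seed = 31)
  pp <- expand_person_periods(tab)
  fit <- fit_discrete_hazard(pp, exposure = NULL, time_spec = "factor")
  risk <- standardized_cumulative_incidence(fit, NULL, tab)

  # actuarial oracle from raw person-period counts
  at_risk <- table(factor(pp$interval_index, levels = 1:max(pp$interval_index)))
  ev <- tapply(pp$event_in_interval, factor(pp$interval_index,
                                            levels = 1:max(pp$interval_index)), sum)
  h <- as.numeric(ev) / as.numeric(at_risk)
  expect_equal(risk$risk, 1 - cumprod(1 - h), tolerance = 1e-7)
})

test_that("forced zero hazard gives zero risk; risks are monotone and ordered", {
  tab <- sim_loglinear_cohort(2000, beta = -0.04, baseline = 0.08, censor = 5,
                              seed = 41)
  pp <- expand_person_periods(tab)
  fit <- fit_discrete_hazard(pp)
  q <- quantile(tab$sri_standardized, c(0.05, 0.5, 0.95))
  risk <- standardized_cumulative_incidence(fit, q, tab)
  expect_true(all(risk$risk >= 0 & risk$risk <= 1))
  for (s in q) {
    r <- risk$risk[risk$sri == s]
    expect_true(all(diff(r) >= -1e-12))
  }
  # lower SRI simulated as higher hazard -> curves ordered at all times
  wide <- matrix(risk$risk, ncol = 3)
  expect_true(all(wide[, 1] > wide[, 2] & wide[, 2] > wide[, 3]))

  fit0 <- fit
  fit0$coef[] <- 0
  fit0$coef[1] <- -50
  r0 <- standardized_cumulative_incidence(fit0, q[2], tab)
  expect_lt(max(r0$risk), 1e-10)
})

test_that("time-varying HR contract: df, reference, flat when proportional", {
  tab <- sim_loglinear_cohort(4000, beta = -0.03, baseline = 0.08, censor = 5,
                              seed = 51)
  pp <- expand_person_periods(tab)
  fit <- fit_discrete_hazard(pp, with_interaction = TRUE)
  # 4-knot time spline (3 cols) x 2-col exposure basis = 6 product terms
  expect_length(fit$inter_cols, 6L)
  expect_equal(proportionality_test(fit)$df, 6L)

  q <- quantile(tab$sri_standardized, c(0.05, 0.5, 0.95))
  tv <- time_varying_hr(fit, q[1], q[2], seq(0.5, 4.5, by = 0.5))
  expect_true(all(tv$lo <= tv$hr & tv$hr <= tv$hi))

  # at the reference the HR is identically 1
  tvr <- time_varying_hr(fit, q[2], q[2], c(1, 2, 3))
  expect_equal(tvr$hr, rep(1, 3))

  # without interaction terms the curve is constant in t
  fit_pi <- fit_discrete_hazard(pp, with_interaction = FALSE)
  tvc <- time_varying_hr(fit_pi, q[1], q[2], c(0.5, 2, 4))
  expect_equal(diff(tvc$hr), c(0, 0))
  expect_error(proportionality_test(fit_pi), "interaction")

  expect_error(time_varying_hr(fit, q[1], q[2], 99), "outside fitted")
})

test_that("Cox HR and discrete-time HR agree under proportional hazards", {
  tab <- sim_loglinear_cohort(30000, beta = -0.03, baseline = 0.05, censor = 5,
                              seed = 61)
  q <- quantile(tab$sri_standardized, c(0.05, 0.5))
  spec <- rcs_spec(knot_percentiles(tab$sri_standardized, c(10, 50, 90)))
  cox <- fit_cox(tab, "sri_standardized",
                 exposure_specs = list(sri_standardized = spec),
                 covariates = "none")
  hr_cox <- hr_curve(cox, q[2], q[1])$hr

  pp <- expand_person_periods(tab)
  dt <- fit_discrete_hazard(pp, exposure_spec = spec, with_interaction = FALSE)
  d <- rcs_design(q[1], spec) - rcs_design(q[2], spec)
  hr_dt <- exp(as.numeric(d %*% dt$coef[dt$sri_cols]))
  expect_equal(hr_dt, hr_cox, tolerance = 0.03)
})

test_that("bootstrap risk CIs are seed-reproducible with min/max bounds at B = 2", {
  tab <- sim_loglinear_cohort(500, beta = -0.03, baseline = 0.15, censor = 3,
                              seed = 71)
  q <- unname(quantile(tab$sri_standardized, c(0.25, 0.75)))
  r1 <- bootstrap_risk_ci(tab, q, B = 2, seed = 5)
  r2 <- bootstrap_risk_ci(tab, q, B = 2, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$lo <= r1$hi))

  # replicate the two resamples by hand: bounds are their min/max
  pp <- expand_person_periods(tab)
  fit0 <- fit_discrete_hazard(pp)
  set.seed(5)
  curves <- lapply(1:2, function(b) {
    ids <- sample.int(nrow(tab), replace = TRUE)
    tb <- tab[ids, ]
    tb$participant_id <- seq_len(nrow(tb))
    ppb <- expand_person_periods(tb)
    fb <- fit_discrete_hazard(ppb, time_spec = fit0$time_spec,
                              exposure_spec = fit0$exposure_spec)
    standardized_cumulative_incidence(fb, q, tb, n_intervals = fit0$n_intervals)$risk
  })
  expect_equal(r1$lo, pmin(curves[[1]], curves[[2]]))
  expect_equal(r1$hi, pmax(curves[[1]], curves[[2]]))

  expect_error(bootstrap_risk_ci(tab, q, B = 1), "B must be")
})
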
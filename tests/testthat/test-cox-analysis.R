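test_that("cause-specific recoding censors competing deaths", {
  tab <- data.frame(
    participant_id = 1:10,
    follow_time = seq(0.5, 5, by = 0.5),
    event = c(rep(1, 10)),
    cause = c(rep("CVD", 3), rep("cancer", 5), rep("other", 2))
  )
  expect_equal(sum(cause_specific_outcome(tab, "all")$event), 10)
  cvd <- cause_specific_outcome(tab, "CVD")
  expect_equal(sum(cvd$event), 3)
  expect_equal(cvd$follow_time, tab$follow_time) # censoring at death time
  # cause-specific events partition the all-cause count
  n_by_cause <- vapply(c("CVD", "cancer", "other"),
                       function(cs) sum(cause_specific_outcome(tab, cs)$event),
                       numeric(1))
  expect_equal(sum(n_by_cause), sum(tab$event))
  # censored rows unchanged under every cause
  tab$event[1] <- 0; tab$cause[1] <- "none"
  expect_equal(cause_specific_outcome(tab, "CVD")$event[1], 0)
})

test_that("sensitivity covariate sets nest the primary set", {
  primary <- covariate_set("primary")
  for (s in c("model2", "model3", "model4")) {
    cs <- covariate_set(s)
    expect_true(all(primary %in% cs))
    expect_identical(cs[seq_along(primary)], primary) # primary order preserved
  }
  expect_true(all(covariate_set("model3") %in% covariate_set("model4")))
  expect_length(covariate_set("none"), 0)
})

test_that("log-linear exposure effect is recovered by the spline Cox fit", {
  tab <- sim_loglinear_cohort(20000, beta = 0.03, baseline = 0.03, censor = 7,
                              seed = 101)
  fit <- fit_cox(tab, "sri_standardized", covariates = "none")
  med <- median(tab$sri_standardized)
  grid <- quantile(tab$sri_standardized, seq(0.05, 0.95, by = 0.05))
  crv <- hr_curve(fit, med, grid)
  truth <- exp(0.03 * (grid - med))
  # truth inside the pointwise 95% CI on nearly the whole grid
  inside <- truth >= crv$lo & truth <= crv$hi
  expect_gte(mean(inside), 0.9)
  expect_lt(max(abs(log(crv$hr) - log(truth))), 0.12)
})

test_that("U-shaped truth is recovered across the 5th-95th percentile grid", {
  set.seed(202)
  n <- 20000
  sri <- runif(n, 30, 90)
  lh <- function(s, cov) log(1.5) * ((s - 60) / 20)^2
  surv <- simulate_survival(sri, NULL, surv_sim_params(lh, 0.03, 7), seed = 203)
  surv$sri_standardized <- sri
  # a symmetric U needs more curvature than the default 3 knots provide
  spec <- rcs_spec(knot_percentiles(sri, c(5, 27.5, 50, 72.5, 95)))
  fit <- fit_cox(surv, "sri_standardized",
                 exposure_specs = list(sri_standardized = spec),
                 covariates = "none")
  med <- median(sri)
  grid <- quantile(sri, seq(0.05, 0.95, by = 0.1))
  crv <- hr_curve(fit, med, grid)
  truth <- exp(lh(grid, NULL) - lh(med, NULL))
  inside <- truth >= crv$lo & truth <= crv$hi
  expect_gte(mean(inside), 0.8)
  expect_lt(max(abs(log(crv$hr) - log(truth))), 0.2)
})

test_that("the HR curve is anchored at 1 and respects its contract", {
  tab <- sim_loglinear_cohort(3000, beta = 0.02, seed = 55)
  fit <- fit_cox(tab, "sri_standardized", covariates = "none")
  med <- median(tab$sri_standardized)
  at_ref <- hr_curve(fit, med, med)
  expect_equal(at_ref$hr, 1)
  expect_equal(at_ref$lo, 1)
  expect_equal(at_ref$hi, 1)

  crv <- hr_curve(fit, med, quantile(tab$sri_standardized, c(0.1, 0.9)))
  expect_true(all(crv$lo <= crv$hr & crv$hr <= crv$hi))

  expect_error(hr_curve(fit, 200, c(50, 60)), "outside fitted")
})

test_that("global spline test has 2 df for 3 knots and detects strong effects", {
  tab <- sim_loglinear_cohort(5000, beta = 0.05, baseline = 0.05, seed = 66)
  fit <- fit_cox(tab, "sri_standardized", covariates = "none")
  gt <- global_spline_test(fit)
  expect_equal(gt$df, 2L)
  expect_lt(gt$p, 1e-6)

  null_tab <- sim_loglinear_cohort(3000, beta = 0, baseline = 0.05, seed = 67)
  fit0 <- fit_cox(null_tab, "sri_standardized", covariates = "none")
  expect_gt(global_spline_test(fit0)$p, 0.01)
})

test_that("covariate adjustment machinery runs with the primary set", {
  tab <- sim_loglinear_cohort(6000, beta = 0.03, baseline = 0.05, seed = 77)
  cov <- simulate_covariates(6000, seed = 78)
  tab <- cbind(tab, cov[, setdiff(names(cov), "participant_id")])
  fit <- fit_cox(tab, "sri_standardized", covariates = "primary")
  # exposure spline + dummies + covariate splines all present
  expect_gt(length(fit$coef), 20)
  expect_equal(global_spline_test(fit)$df, 2L)
  expect_lt(global_spline_test(fit)$p, 1e-4)
  expect_identical(fit$ties, "efron")
})

test_that("interaction test flags a sex-specific effect and rejects degeneracy", {
  set.seed(88)
  n <- 20000
  sri <- runif(n, 30, 90)
  sex <- factor(sample(c("female", "male"), n, TRUE))
  lh <- ifelse(sex == "male", -0.04, -0.01) * (sri - 60)
  surv <- simulate_survival(sri, NULL,
                            surv_sim_params(function(s, cov) lh, 0.03, 7),
                            seed = 89)
  surv$sri_standardized <- sri
  surv$sex <- sex
  it <- interaction_test(surv, "sri_standardized", "sex", covariates = "none")
  expect_lt(it$p, 0.001)
  expect_equal(it$df, 2L) # 2 exposure basis cols x 1 sex dummy

  # modifier equal to the exposure gives collinear products
  surv$dup <- surv$sri_standardized
  expect_error(interaction_test(surv, "sri_standardized", "dup",
                                covariates = "none"), "collinear")

  # modifier independent of the hazard: no signal expected
  surv$noise_mod <- factor(sample(c("a", "b"), n, TRUE))
  it0 <- interaction_test(surv, "sri_standardized", "noise_mod",
                          covariates = "none")
  expect_gt(it0$p, 0.01)
})

test_that("likelihood-ratio comparison handles identical, nested, non-nested", {
  tab <- sim_loglinear_cohort(4000, beta = 0.03, baseline = 0.05, seed = 99)
  tab$other <- rnorm(4000)
  f1 <- fit_cox(tab, "sri_standardized", covariates = "none")
  expect_equal(likelihood_ratio_compare(f1, f1), list(chi2 = 0, df = 0L, p = 1))

  f2 <- fit_cox(tab, c("sri_standardized", "other"), covariates = "none")
  lr <- likelihood_ratio_compare(f1, f2)
  expect_equal(lr$df, 2L)
  expect_gt(lr$p, 0.001) # pure-noise addition

  expect_error(likelihood_ratio_compare(f2, f1), "not nested")
})

test_that("SRI adds information beyond SD metrics but not conversely", {
  set.seed(111)
  n <- 10000
  sri <- runif(n, 30, 90)
  # SD metrics are noisy monotone proxies of (ir)regularity
  tab <- data.frame(
    sri_standardized = sri,
    onset_sd = pmax((90 - sri) / 25 + rnorm(n, 0, 0.8), 0),
    duration_sd = pmax((90 - sri) / 35 + rnorm(n, 0, 0.6), 0)
  )
  surv <- simulate_survival(sri, NULL,
                            surv_sim_params(function(s, cov) -0.035 * (s - 60),
                                            0.04, 7), seed = 112)
  tab <- cbind(tab, surv[, c("follow_time", "event", "cause")])

  f_sd <- fit_cox(tab, c("duration_sd", "onset_sd"), covariates = "none")
  f_sd_sri <- fit_cox(tab, c("duration_sd", "onset_sd", "sri_standardized"),
                      covariates = "none")
  f_sri <- fit_cox(tab, "sri_standardized", covariates = "none")
  f_sri_sd <- fit_cox(tab, c("sri_standardized", "duration_sd", "onset_sd"),
                      covariates = "none")

  p_add_sri <- likelihood_ratio_compare(f_sd, f_sd_sri)$p
  p_add_sd <- likelihood_ratio_compare(f_sri, f_sri_sd)$p
  expect_lt(p_add_sri, 0.001)
  expect_gt(p_add_sd, 0.05)
})

test_that("missing analysis values are rejected before fitting", {
  tab <- sim_loglinear_cohort(200, seed = 5)
  tab$sri_standardized[3] <- NA
  expect_error(fit_cox(tab, "sri_standardized", covariates = "none"),
               "imputation")
})
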
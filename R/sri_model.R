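#' Mixed-model averaging and standardization of day-pair SRI values
#'
#' Day-pair SRI values are averaged with a linear mixed effects model with a
#' random intercept for the participant and fixed effects for the day of the
#' week and daylight-saving transitions. The participant-level SRI is then
#' standardized over day of week and DST: it is the model-predicted mean for a
#' balanced, DST-free week (grand mean + participant BLUP + equal-weight
#' average of the seven weekday effects, DST effect set to zero), so values
#' are comparable across participants regardless of which days they wore the
#' device.
#'
#' @name sri_model
NULL

#' Fit the random-intercept model to day-pair SRI values
#'
#' REML fit of `sri_value ~ weekday + spans_dst + (1 | participant_id)` on
#' valid pairs. The reference weekday is Monday (code 0). Participants with
#' fewer than two valid pairs are excluded before fitting. Terms without
#' variation in the data (e.g. no DST-spanning pairs) are dropped and their
#' effects reported as zero. A boundary fit with zero participant variance is
#' returned with a `singular` flag, not an error.
#'
#' @param pairs day-pair data.frame from [cohort_day_pairs()] /
#'   [participant_day_pairs()].
#' @return object of class `sri_lmm_fit`: `grand_mean`, `weekday_effects`
#'   (length-7 vector, reference and unobserved days 0), `dst_effect`,
#'   `participant_intercepts` (BLUPs), `raw_means`, `n_valid_pairs`,
#'   `var_participant`, `var_residual`, `singular`, `n_excluded`.
#' @export
fit_sri_lmm <- function(pairs) {
  d <- pairs[pairs$valid & !is.na(pairs$sri_value), , drop = FALSE]
  n_per <- table(d$participant_id)
  keep <- names(n_per)[n_per >= 2L]
  n_excluded <- length(n_per) - length(keep)
  d <- d[as.character(d$participant_id) %in% keep, , drop = FALSE]
  if (length(keep) < 2L) stop("need at least 2 participants with >= 2 valid pairs")
  d$wd <- factor(d$weekday_first, levels = 0:6)
  d$dst <- as.numeric(d$spans_dst)
  d$pid <- factor(d$participant_id)

  raw_means <- c(tapply(d$sri_value, d$pid, mean))
  n_valid <- as.integer(table(d$pid))
  names(n_valid) <- levels(d$pid)

  wk_eff <- stats::setNames(rep(0, 7), 0:6)
  dst_eff <- 0
  if (stats::sd(d$sri_value) == 0) {
    # degenerate constant input: both variances at the boundary
    return(structure(list(
      grand_mean = d$sri_value[1], weekday_effects = wk_eff, dst_effect = 0,
      participant_intercepts = stats::setNames(rep(0, nlevels(d$pid)), levels(d$pid)),
      raw_means = raw_means, n_valid_pairs = n_valid,
      var_participant = 0, var_residual = 0, singular = TRUE,
      observed_weekdays = sort(unique(d$weekday_first)),
      n_excluded = n_excluded
    ), class = "sri_lmm_fit"))
  }

  terms <- c(
    if (length(unique(d$weekday_first)) > 1L) "wd",
    if (length(unique(d$dst)) > 1L) "dst"
  )
  rhs <- paste(c(terms, "(1 | pid)"), collapse = " + ")
  fit <- suppressMessages(lme4::lmer(
    stats::as.formula(paste("sri_value ~", rhs)),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  fe <- lme4::fixef(fit)
  if ("wd" %in% terms) {
    for (lev in 1:6) {
      nm <- paste0("wd", lev)
      if (nm %in% names(fe)) wk_eff[as.character(lev)] <- fe[[nm]]
    }
  }
  if ("dst" %in% terms) dst_eff <- fe[["dst"]]
  vc <- as.data.frame(lme4::VarCorr(fit))
  re <- lme4::ranef(fit)$pid
  var_res <- vc$vcov[vc$grp == "Residual"]
  intercepts <- stats::setNames(re[["(Intercept)"]], rownames(re))
  grand <- unname(fe[["(Intercept)"]])

  if (var_res < 1e-6 && "wd" %in% terms) {
    # residual variance at the boundary: the data are exactly fit by fixed +
    # participant effects, so recover them by exact projection (within-
    # participant OLS for the fixed effects; unshrunken participant means)
    W <- stats::model.matrix(~ wd + dst, d)[, -1, drop = FALSE]
    Wd <- apply(W, 2, function(cl) cl - stats::ave(cl, d$pid))
    yd <- d$sri_value - stats::ave(d$sri_value, d$pid)
    keep <- colSums(Wd^2) > 1e-10
    beta <- stats::setNames(rep(0, ncol(W)), colnames(W))
    if (any(keep)) {
      beta[keep] <- stats::coef(stats::lm.fit(Wd[, keep, drop = FALSE], yd))
    }
    for (lev in 1:6) {
      nm <- paste0("wd", lev)
      if (nm %in% names(beta)) wk_eff[as.character(lev)] <- beta[[nm]]
    }
    if ("dst" %in% colnames(W)) dst_eff <- beta[["dst"]]
    adj <- d$sri_value - as.vector(W %*% beta)
    part_mean <- c(tapply(adj, d$pid, mean))
    grand <- mean(part_mean)
    intercepts <- part_mean - grand
    var_res <- stats::var(adj - part_mean[as.character(d$pid)])
  }

  structure(list(
    grand_mean = grand,
    weekday_effects = wk_eff, dst_effect = dst_eff,
    participant_intercepts = intercepts,
    raw_means = raw_means, n_valid_pairs = n_valid,
    var_participant = vc$vcov[vc$grp == "pid"],
    var_residual = var_res,
    singular = lme4::isSingular(fit),
    observed_weekdays = sort(unique(d$weekday_first)),
    n_excluded = n_excluded
  ), class = "sri_lmm_fit")
}

#' @export
print.sri_lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<sri_lmm_fit> %d participants; grand mean %.2f; var(participant) %.2f; var(residual) %.2f%s\n",
    length(x$participant_intercepts), x$grand_mean, x$var_participant,
    x$var_residual, if (x$singular) " [singular]" else ""
  ))
  invisible(x)
}

#' Standardized participant-level SRI
#'
#' The standardized SRI is the model-predicted mean day-pair SRI over a
#' balanced, DST-free week: grand mean + participant random intercept (BLUP)
#' + the equal-weight average of the weekday effects over the weekdays
#' observed in the fitted data (all seven in a realistic cohort; effects for
#' unobserved weekdays are inestimable), with the DST effect set to zero. Setting `use_blup = FALSE` returns the unshrunken raw
#' per-participant means instead (sensitivity option).
#'
#' @param fit an `sri_lmm_fit` from [fit_sri_lmm()].
#' @param use_blup use the shrunken random-effect predictions (default) or
#'   raw participant means.
#' @return data.frame: `participant_id`, `sri_standardized`, `n_valid_pairs`.
#' @export
standardized_sri <- function(fit, use_blup = TRUE) {
  stopifnot(inherits(fit, "sri_lmm_fit"))
  ids <- names(fit$participant_intercepts)
  val <- if (use_blup) {
    fit$grand_mean + fit$participant_intercepts +
      mean(fit$weekday_effects[as.character(fit$observed_weekdays)])
  } else {
    fit$raw_means[ids]
  }
  data.frame(
    participant_id = ids, sri_standardized = as.numeric(val),
    n_valid_pairs = unname(fit$n_valid_pairs[ids]),
    stringsAsFactors = FALSE
  )
}
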
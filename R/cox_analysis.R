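#' Cox proportional hazards analysis with spline exposures
#'
#' Cause-specific Cox models relating a regularity exposure (standardized SRI
#' or an SD-based metric) to mortality, with the exposure and all continuous
#' confounders expanded as restricted cubic splines (knots at the 10th, 50th
#' and 90th percentiles of the analysis sample unless supplied), categorical
#' confounders dummy-coded, and Efron tie handling. Provides hazard-ratio
#' curves relative to a reference (the cohort median exposure), global Wald
#' tests of the spline term, interaction (effect-modification) tests, and
#' nested-model likelihood-ratio comparisons.
#'
#' @name cox_analysis
NULL

# covariates that enter as restricted cubic splines when present
.continuous_covars <- c("age", "townsend", "pack_years", "sleep_duration",
                        "waso", "bmi", "sys_bp", "phys_activity")

#' Covariate sets for the primary model and sensitivity models 2-4
#'
#' Model 2 adds overnight sleep duration and WASO; Model 3 adds past or
#' prevalent disease at baseline; Model 4 further adds BMI, systolic BP, BP
#' medication and physical activity.
#'
#' @param set one of "primary", "model2", "model3", "model4", or "none".
#' @return character vector of covariate column names.
#' @export
covariate_set <- function(set = c("primary", "model2", "model3", "model4", "none")) {
  set <- match.arg(set)
  primary <- c("age", "sex", "ethnicity", "townsend", "retired", "shift_work",
               "sick_disabled", "income", "education", "smoking_status",
               "pack_years", "med_sedative", "med_antidepressant",
               "med_antipsychotic")
  disease <- c("prev_cancer", "prev_cvd", "prev_mental", "prev_nervous",
               "prev_diabetes")
  switch(set,
    none = character(0),
    primary = primary,
    model2 = c(primary, "sleep_duration", "waso"),
    model3 = c(primary, disease),
    model4 = c(primary, disease, "bmi", "sys_bp", "bp_med", "phys_activity")
  )
}

#' Recode outcome columns for a cause-specific analysis
#'
#' All-cause: events as recorded. Cause-specific: only deaths from the named
#' cause count as events; deaths from competing causes are censored at the
#' time of death (follow-up time unchanged).
#'
#' @param table cohort data.frame with `follow_time`, `event`, `cause`.
#' @param cause "all", or a cause label present in `cause` (e.g. "CVD",
#'   "cancer").
#' @return the table with `event` recoded.
#' @export
cause_specific_outcome <- function(table, cause = "all") {
  if (cause == "all") return(table)
  table$event <- as.integer(table$event == 1L & table$cause == cause)
  table
}

# one covariate -> design columns; continuous get their own 10/50/90-knot
# spline, falling back to a linear term when the knots collapse (e.g. a
# point mass at zero); factors are dummy-coded against their first level
covariate_columns <- function(x, name) {
  if (is.factor(x) || is.character(x)) {
    f <- droplevels(as.factor(x))
    if (nlevels(f) < 2L) return(NULL)
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(name, ".", levels(f)[-1])
    return(mm)
  }
  x <- as.numeric(x)
  if (name %in% .continuous_covars && length(unique(x)) > 10L) {
    k <- tryCatch(knot_percentiles(x, c(10, 50, 90)), error = function(e) NULL)
    if (!is.null(k)) {
      b <- rcs_design(x, rcs_spec(k))
      colnames(b) <- paste0(name, ".", colnames(b))
      return(b)
    }
  }
  if (length(unique(x)) < 2L) return(NULL)
  matrix(x, ncol = 1, dimnames = list(NULL, name))
}

# freeze the per-covariate design recipe (factor levels / rcs knots / linear)
# on the analysis sample so it can be re-applied to new or resampled rows
make_covariate_specs <- function(table, covariates) {
  specs <- list()
  for (cv in covariates) {
    x <- table[[cv]]
    if (is.null(x)) stop("covariate column not found: ", cv)
    if (is.factor(x) || is.character(x)) {
      f <- droplevels(as.factor(x))
      if (nlevels(f) < 2L) next
      specs[[cv]] <- list(type = "factor", levels = levels(f))
    } else if (cv %in% .continuous_covars && length(unique(x)) > 10L) {
      k <- tryCatch(knot_percentiles(as.numeric(x), c(10, 50, 90)),
                    error = function(e) NULL)
      specs[[cv]] <- if (is.null(k)) list(type = "linear")
                     else list(type = "rcs", spec = rcs_spec(k))
    } else {
      if (length(unique(x)) < 2L) next
      specs[[cv]] <- list(type = "linear")
    }
  }
  specs
}

apply_covariate_specs <- function(specs, table) {
  blocks <- lapply(names(specs), function(cv) {
    sp <- specs[[cv]]
    x <- table[[cv]]
    if (sp$type == "factor") {
      f <- factor(as.character(x), levels = sp$levels)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, ".", sp$levels[-1])
      mm
    } else if (sp$type == "rcs") {
      b <- rcs_design(as.numeric(x), sp$spec)
      colnames(b) <- paste0(cv, ".", colnames(b))
      b
    } else {
      matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, cv))
    }
  })
  if (!length(blocks)) {
    return(matrix(numeric(0), nrow = nrow(table), ncol = 0))
  }
  do.call(cbind, blocks)
}

#' Build the model design matrix for survival fits
#'
#' Each exposure is expanded with its own restricted-cubic-spline basis
#' (knots at the 10th/50th/90th percentiles of the analysis sample unless a
#' spec is supplied); continuous confounders likewise; categorical
#' confounders are dummy-coded.
#'
#' @param table cohort data.frame.
#' @param exposures character vector of exposure column names.
#' @param exposure_specs optional named list of [rcs_spec()] per exposure.
#' @param covariates character vector of covariate names (see
#'   [covariate_set()]).
#' @return list: `X` (design matrix), `exposure_cols` (named list of column
#'   indices per exposure), `exposure_specs` (named list of rcs_spec),
#'   `covariate_cols` (indices).
#' @export
build_design <- function(table, exposures, exposure_specs = NULL,
                         covariates = character(0)) {
  blocks <- list()
  exposure_cols <- list()
  specs <- list()
  for (ex in exposures) {
    if (!ex %in% names(table)) stop("exposure column not found: ", ex)
    spec <- exposure_specs[[ex]]
    if (is.null(spec)) spec <- rcs_spec(knot_percentiles(table[[ex]], c(10, 50, 90)))
    b <- rcs_design(table[[ex]], spec)
    colnames(b) <- paste0(ex, ".", colnames(b))
    start <- sum(vapply(blocks, ncol, integer(1)))
    exposure_cols[[ex]] <- start + seq_len(ncol(b))
    specs[[ex]] <- spec
    blocks[[length(blocks) + 1L]] <- b
  }
  for (cv in covariates) {
    if (!cv %in% names(table)) stop("covariate column not found: ", cv)
    cc <- covariate_columns(table[[cv]], cv)
    if (!is.null(cc)) blocks[[length(blocks) + 1L]] <- cc
  }
  X <- do.call(cbind, blocks)
  n_exp <- length(unlist(exposure_cols))
  list(X = X, exposure_cols = exposure_cols, exposure_specs = specs,
       covariate_cols = if (ncol(X) > n_exp) (n_exp + 1L):ncol(X) else integer(0))
}

#' Fit a cause-specific Cox model with spline exposure(s)
#'
#' Partial-likelihood fit with the Efron approximation for ties.
#'
#' @param table cohort data.frame (no missing values in analysis columns;
#'   impute upstream).
#' @param exposures exposure column name(s).
#' @param exposure_specs optional named list of [rcs_spec()] per exposure.
#' @param covariates covariate set name for [covariate_set()] or an explicit
#'   character vector of column names.
#' @param outcome "all" or a cause label; see [cause_specific_outcome()].
#' @return object of class `cox_fit`: `coef`, `vcov`, `loglik` (fitted),
#'   `loglik_null`, `n`, `n_events`, `exposure_cols`, `exposure_specs`,
#'   `covariates`, `outcome`, `ties`, `exposure_range` per exposure.
#' @export
fit_cox <- function(table, exposures = "sri_standardized", exposure_specs = NULL,
                    covariates = "primary", outcome = "all") {
  if (length(covariates) == 1L &&
      covariates %in% c("primary", "model2", "model3", "model4", "none")) {
    covariates <- covariate_set(covariates)
  }
  need <- c(exposures, covariates, "follow_time", "event")
  cc <- stats::complete.cases(table[, intersect(need, names(table)), drop = FALSE])
  if (!all(cc)) stop("missing values in analysis columns; run imputation first")
  tab <- cause_specific_outcome(table, outcome)
  if (sum(tab$event) < 1L) stop("no events for outcome: ", outcome)
  des <- build_design(tab, exposures, exposure_specs, covariates)
  fit <- survival::coxph(
    survival::Surv(tab$follow_time, tab$event) ~ des$X,
    ties = "efron"
  )
  if (any(is.na(stats::coef(fit)))) {
    bad <- colnames(des$X)[is.na(stats::coef(fit))]
    stop("collinear/degenerate design columns: ", paste(bad, collapse = ", "))
  }
  beta <- stats::coef(fit)
  names(beta) <- colnames(des$X)
  V <- stats::vcov(fit)
  dimnames(V) <- list(colnames(des$X), colnames(des$X))
  structure(list(
    coef = beta, vcov = V,
    loglik = fit$loglik[2], loglik_null = fit$loglik[1],
    n = fit$n, n_events = fit$nevent,
    exposure_cols = des$exposure_cols, exposure_specs = des$exposure_specs,
    covariates = covariates, outcome = outcome, ties = "efron",
    exposure_range = lapply(stats::setNames(exposures, exposures),
                            function(ex) range(tab[[ex]]))
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit> outcome %s: n = %d, events = %d, %d coefficients; loglik %.2f\n",
    x$outcome, x$n, x$n_events, length(x$coef), x$loglik
  ))
  invisible(x)
}

#' Hazard-ratio curve relative to a reference exposure value
#'
#' log HR(x) = [basis(x) - basis(ref)] . beta for the exposure block;
#' pointwise variance by the quadratic form with the coefficient covariance;
#' 95% CI computed on the log scale and exponentiated. HR at the reference is
#' exactly 1.
#'
#' @param fit a `cox_fit`.
#' @param reference reference exposure value (e.g. the cohort median);
#'   must lie within the fitted exposure range.
#' @param grid exposure values at which to evaluate the curve.
#' @param exposure which exposure (defaults to the first).
#' @param level confidence level.
#' @return data.frame: `exposure`, `hr`, `lo`, `hi`; attribute `reference`.
#' @export
hr_curve <- function(fit, reference, grid, exposure = names(fit$exposure_cols)[1],
                     level = 0.95) {
  stopifnot(inherits(fit, "cox_fit"))
  rng <- fit$exposure_range[[exposure]]
  if (reference < rng[1] || reference > rng[2]) {
    stop("reference outside fitted exposure range [", rng[1], ", ", rng[2], "]")
  }
  cols <- fit$exposure_cols[[exposure]]
  spec <- fit$exposure_specs[[exposure]]
  D <- rcs_design(grid, spec) -
    matrix(rcs_design(reference, spec), nrow = length(grid),
           ncol = length(cols), byrow = TRUE)
  b <- fit$coef[cols]
  V <- fit$vcov[cols, cols, drop = FALSE]
  loghr <- as.vector(D %*% b)
  se <- sqrt(pmax(rowSums((D %*% V) * D), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    exposure = grid, hr = exp(loghr),
    lo = exp(loghr - z * se), hi = exp(loghr + z * se)
  ) |> structure(reference = reference)
}

# Wald test of a coefficient block being jointly zero
wald_block_test <- function(beta, V) {
  qr_V <- qr(V)
  if (qr_V$rank < ncol(V)) stop("singular covariance block in Wald test")
  chi2 <- as.numeric(t(beta) %*% solve(V, beta))
  df <- length(beta)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Global test of the exposure spline term
#'
#' Wald test that all basis coefficients of the exposure are jointly zero;
#' df equals the number of basis columns (2 for a 3-knot spline).
#'
#' @param fit a `cox_fit`.
#' @param exposure exposure name (default: first).
#' @return list with `chi2`, `df`, `p`.
#' @export
global_spline_test <- function(fit, exposure = names(fit$exposure_cols)[1]) {
  stopifnot(inherits(fit, "cox_fit"))
  cols <- fit$exposure_cols[[exposure]]
  wald_block_test(fit$coef[cols], fit$vcov[cols, cols, drop = FALSE])
}

#' Effect-modification (interaction) test
#'
#' Adds product terms between the exposure spline basis and the modifier's
#' design columns (dummy columns for a categorical modifier; its own
#' restricted-cubic-spline basis for a continuous one) and Wald-tests the
#' product block.
#'
#' @param table cohort data.frame.
#' @param exposure exposure column name.
#' @param modifier modifier column name.
#' @param covariates covariate set name or explicit vector (the modifier is
#'   added to the main effects automatically if absent).
#' @param outcome "all" or a cause label.
#' @param exposure_spec optional [rcs_spec()] for the exposure.
#' @return list with `chi2`, `df`, `p`.
#' @export
interaction_test <- function(table, exposure, modifier, covariates = "primary",
                             outcome = "all", exposure_spec = NULL) {
  if (length(covariates) == 1L &&
      covariates %in% c("primary", "model2", "model3", "model4", "none")) {
    covariates <- covariate_set(covariates)
  }
  if (is.factor(table[[modifier]]) || is.character(table[[modifier]])) {
    lv <- table(droplevels(as.factor(table[[modifier]])))
    if (any(lv == 0L)) stop("empty modifier stratum: ", names(lv)[lv == 0][1])
  }
  covariates <- union(covariates, if (modifier %in% names(table)) modifier)
  tab <- cause_specific_outcome(table, outcome)
  specs <- if (is.null(exposure_spec)) NULL else stats::setNames(list(exposure_spec), exposure)
  des <- build_design(tab, exposure, specs, covariates)
  mod_cols <- covariate_columns(table[[modifier]], modifier)
  if (is.null(mod_cols)) stop("modifier has no variation: ", modifier)
  exb <- des$X[, des$exposure_cols[[exposure]], drop = FALSE]
  prods <- do.call(cbind, lapply(seq_len(ncol(mod_cols)), function(j) {
    p <- exb * mod_cols[, j]
    colnames(p) <- paste0(colnames(exb), ":", colnames(mod_cols)[j])
    p
  }))
  X <- cbind(des$X, prods)
  fit <- survival::coxph(survival::Surv(tab$follow_time, tab$event) ~ X,
                         ties = "efron")
  beta <- stats::coef(fit)
  pidx <- (ncol(des$X) + 1L):ncol(X)
  if (any(is.na(beta))) {
    stop("collinear design for modifier ", modifier, ": ",
         paste(colnames(X)[is.na(beta)], collapse = ", "))
  }
  V <- stats::vcov(fit)
  wald_block_test(beta[pidx], V[pidx, pidx, drop = FALSE])
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' chi-square = 2 (loglik_full - loglik_nested) with df equal to the
#' difference in number of coefficients. The nested model's design columns
#' must be a subset of the full model's, fit to the same rows and outcome.
#'
#' @param fit_nested,fit_full `cox_fit` objects.
#' @return list with `chi2`, `df`, `p`.
#' @export
likelihood_ratio_compare <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "cox_fit"), inherits(fit_full, "cox_fit"))
  if (fit_nested$n != fit_full$n || fit_nested$n_events != fit_full$n_events ||
      !identical(fit_nested$outcome, fit_full$outcome)) {
    stop("models fit to different rows or outcomes are not comparable")
  }
  if (!all(names(fit_nested$coef) %in% names(fit_full$coef))) {
    stop("models are not nested: nested model has columns absent from the full model")
  }
  df <- length(fit_full$coef) - length(fit_nested$coef)
  chi2 <- max(2 * (fit_full$loglik - fit_nested$loglik), 0)
  p <- if (df == 0L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}
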
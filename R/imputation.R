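#' Multiple imputation by predictive mean matching
#'
#' Missing confounder values are imputed by chained-equations predictive mean
#' matching (PMM): each incomplete column is regressed on the other
#' predictors, regression coefficients are drawn from their sampling
#' distribution for each imputation, and every missing case receives the
#' observed value of a donor chosen at random among the `k_donors` cases with
#' nearest predicted means. Imputed values are therefore always drawn from
#' the observed support of the column (a categorical column never receives an
#' unseen level). Estimates fit on each completed dataset are combined with
#' Rubin's rules.
#'
#' @name imputation
NULL

# numeric coding for the predictor matrix (ordinal factors -> integer scores)
numeric_code <- function(x) {
  if (is.factor(x)) as.numeric(x) else if (is.character(x)) as.numeric(factor(x)) else as.numeric(x)
}

# Bayesian-draw least squares + PMM for one target column
pmm_one_column <- function(y_obs_num, X_obs, X_mis, k_donors) {
  n <- nrow(X_obs)
  X_obs1 <- cbind(1, X_obs)
  X_mis1 <- cbind(1, X_mis)
  p <- ncol(X_obs1)
  XtX <- crossprod(X_obs1) + diag(1e-8, p)
  Xty <- crossprod(X_obs1, y_obs_num)
  R <- chol(XtX)
  betahat <- backsolve(R, forwardsolve(t(R), Xty))
  res <- y_obs_num - X_obs1 %*% betahat
  df <- max(n - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- betahat + backsolve(R, stats::rnorm(p)) * sqrt(sigma2)
  yhat_obs <- as.vector(X_obs1 %*% betahat)
  yhat_mis <- as.vector(X_mis1 %*% beta_star)
  vapply(yhat_mis, function(mu) {
    d <- abs(yhat_obs - mu)
    donors <- order(d)[seq_len(min(k_donors, n))]
    donors[sample.int(length(donors), 1)]
  }, integer(1))
}

#' Impute missing covariates by chained-equations PMM
#'
#' @param table cohort data.frame; missingness only in covariate columns
#'   (outcome columns `follow_time`, `event`, `cause` must be complete).
#' @param m number of imputations (default 10).
#' @param k_donors donor pool size (default 5).
#' @param n_iter chained-equations iterations per imputation (default 5);
#'   incomplete columns are visited in order of increasing missingness.
#' @param seed integer seed; imputation i uses sub-seed `seed + i`.
#' @param predictors columns used as predictors (default: all columns except
#'   identifiers); factors enter as integer scores.
#' @return object of class `imputation_set`: `tables` (list of m completed
#'   data.frames), `masks` (per-column missingness), `m`, `k_donors`,
#'   `n_iter`, `seed`.
#' @export
pmm_impute <- function(table, m = 10L, k_donors = 5L, n_iter = 5L, seed = 1L,
                       predictors = NULL) {
  outcome_cols <- intersect(c("follow_time", "event", "cause"), names(table))
  if (any(vapply(table[outcome_cols], anyNA, logical(1)))) {
    stop("outcome columns must be complete")
  }
  all_missing <- names(table)[vapply(table, function(x) all(is.na(x)), logical(1))]
  if (length(all_missing)) {
    stop("column(s) with all values missing: ", paste(all_missing, collapse = ", "))
  }
  masks <- lapply(table, is.na)
  incomplete <- names(table)[vapply(masks, any, logical(1))]
  if (is.null(predictors)) {
    predictors <- setdiff(names(table), c("participant_id", "cause"))
  }
  out <- structure(list(tables = vector("list", m), masks = masks, m = m,
                        k_donors = k_donors, n_iter = n_iter, seed = seed),
                   class = "imputation_set")
  if (!length(incomplete)) {
    out$tables <- replicate(m, table, simplify = FALSE)
    return(out)
  }
  # visit order: least missing first
  incomplete <- incomplete[order(vapply(masks[incomplete], mean, numeric(1)))]
  for (i in seq_len(m)) {
    set.seed(seed + i)
    comp <- table
    # initial fill: random draws from the observed values
    for (cl in incomplete) {
      mis <- masks[[cl]]
      obs_vals <- table[[cl]][!mis]
      comp[[cl]][mis] <- sample(obs_vals, sum(mis), replace = TRUE)
    }
    for (it in seq_len(n_iter)) {
      for (cl in incomplete) {
        mis <- masks[[cl]]
        pred_cols <- setdiff(predictors, cl)
        X <- vapply(pred_cols, function(pc) numeric_code(comp[[pc]]), numeric(nrow(comp)))
        keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
        X <- X[, keep, drop = FALSE]
        donor_idx <- pmm_one_column(numeric_code(table[[cl]][!mis]),
                                    X[!mis, , drop = FALSE],
                                    X[mis, , drop = FALSE], k_donors)
        comp[[cl]][mis] <- table[[cl]][!mis][donor_idx]
      }
    }
    out$tables[[i]] <- comp
  }
  out
}

#' @export
print.imputation_set <- function(x, ...) {
  miss <- vapply(x$masks, sum, integer(1))
  cat(sprintf(
    "<imputation_set> m = %d completed tables (k_donors = %d, %d iterations); %d cells imputed\n",
    x$m, x$k_donors, x$n_iter, sum(miss)
  ))
  invisible(x)
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Pooled estimate = mean of per-imputation estimates; total variance =
#' within-imputation mean + (1 + 1/m) x between-imputation variance;
#' Barnard-Rubin small-sample degrees of freedom (per component, using the
#' diagonal), reducing to the classical (m - 1)/lambda^2 when `df_com` is
#' infinite.
#'
#' @param estimates list of m coefficient vectors (or an m x p matrix, or m
#'   scalars).
#' @param variances list of m covariance matrices (or m scalar variances).
#' @param df_com complete-data degrees of freedom (default Inf).
#' @return list: `estimate`, `variance` (total, matrix for p > 1), `se`,
#'   `df`, `m`, and `single` flag when m = 1 (passthrough).
#' @export
pool_rubin <- function(estimates, variances, df_com = Inf) {
  if (is.list(estimates)) estimates <- do.call(rbind, lapply(estimates, as.numeric))
  if (is.vector(estimates)) estimates <- matrix(estimates, ncol = 1)
  m <- nrow(estimates)
  p <- ncol(estimates)
  as_mat <- function(v) if (is.matrix(v)) v else diag(as.numeric(v), p)
  if (!is.list(variances)) variances <- as.list(variances)
  if (length(variances) != m) stop("need one variance per imputation")
  if (m == 1L) {
    V <- as_mat(variances[[1]])
    est <- estimates[1, ]
    return(list(estimate = if (p == 1) est[[1]] else est,
                variance = if (p == 1) V[1, 1] else V,
                se = sqrt(diag(V)), df = rep(df_com, p), m = 1L, single = TRUE))
  }
  qbar <- colMeans(estimates)
  W <- Reduce(`+`, lapply(variances, as_mat)) / m
  Bv <- stats::cov(estimates) # between-imputation covariance (m - 1 denominator)
  Tv <- W + (1 + 1 / m) * Bv
  lambda <- pmin(pmax(((1 + 1 / m) * diag(Bv)) / diag(Tv), 1e-12), 1)
  df_old <- (m - 1) / lambda^2
  df <- if (is.infinite(df_com)) {
    df_old
  } else {
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
    df_old * df_obs / (df_old + df_obs)
  }
  list(estimate = if (p == 1) qbar[[1]] else qbar,
       variance = if (p == 1) Tv[1, 1] else Tv,
       se = sqrt(diag(Tv)), df = df, m = m, single = FALSE)
}
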
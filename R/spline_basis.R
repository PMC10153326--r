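#' Restricted cubic spline tools
#'
#' Knot placement at empirical percentiles and construction of the restricted
#' (natural) cubic spline design matrix used for every continuous exposure and
#' confounder in the survival models. K knots yield K - 1 regression columns:
#' the linear term plus K - 2 restricted cubic terms, linear beyond the
#' boundary knots. Terms follow Harrell's normalization: each cubic term is
#' divided by the squared span of the outer knots so coefficients are on
#' comparable scales.
#'
#' @name spline_basis
NULL

#' Place spline knots at empirical percentiles
#'
#' Percentiles use the linear-interpolation definition (R's quantile type 7):
#' the p-th percentile is interpolated between order statistics at position
#' (n - 1) * p/100 + 1.
#'
#' @param x numeric vector of observed values (NAs dropped).
#' @param percentiles numeric vector of percentiles in (0, 100), increasing,
#'   e.g. `c(10, 50, 90)` for exposures or `c(5, 35, 65, 95)` for the
#'   follow-up time axis.
#' @return numeric vector of knots, strictly increasing.
#' @export
knot_percentiles <- function(x, percentiles = c(10, 50, 90)) {
  x <- x[is.finite(x)]
  if (length(x) < length(percentiles)) {
    stop("too few finite values to place ", length(percentiles), " knots")
  }
  if (is.unsorted(percentiles, strictly = TRUE)) {
    stop("percentiles must be strictly increasing")
  }
  k <- unname(stats::quantile(x, probs = percentiles / 100, type = 7))
  dup <- which(diff(k) <= 0)
  if (length(dup)) {
    stop(sprintf(
      "duplicate knots: percentiles %g and %g both map to %g",
      percentiles[dup[1]], percentiles[dup[1] + 1], k[dup[1]]
    ))
  }
  k
}

#' Restricted cubic spline specification
#'
#' @param knots strictly increasing numeric vector, length >= 3.
#' @return an object of class `rcs_spec` with elements `knots` and `n_basis`
#'   (K - 1, the number of design columns including the linear term).
#' @export
rcs_spec <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3) stop("need at least 3 knots")
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  structure(list(knots = knots, n_basis = length(knots) - 1L), class = "rcs_spec")
}

#' Evaluate the restricted cubic spline design matrix
#'
#' Column 1 is x itself; columns 2..K-1 are the restricted cubic terms of the
#' truncated-power construction with linear tail constraints,
#' \deqn{b_j(x) = [ (x-t_j)_+^3 - (x-t_{K-1})_+^3 (t_K-t_j)/(t_K-t_{K-1})
#'                + (x-t_K)_+^3 (t_{K-1}-t_j)/(t_K-t_{K-1}) ] / (t_K-t_1)^2}
#' for j = 1..K-2. Evaluation is exact for any x, including beyond the
#' boundary knots where each column is linear.
#'
#' @param x numeric vector.
#' @param spec an [rcs_spec()] (or a bare knot vector).
#' @return numeric matrix with `length(x)` rows and `spec$n_basis` columns.
#' @export
rcs_design <- function(x, spec) {
  if (!inherits(spec, "rcs_spec")) spec <- rcs_spec(spec)
  t <- spec$knots
  K <- length(t)
  norm <- (t[K] - t[1])^2
  pos3 <- function(u) ifelse(u > 0, u^3, 0)
  out <- matrix(0, nrow = length(x), ncol = K - 1L)
  out[, 1L] <- x
  for (j in seq_len(K - 2L)) {
    out[, j + 1L] <- (pos3(x - t[j]) -
      pos3(x - t[K - 1L]) * (t[K] - t[j]) / (t[K] - t[K - 1L]) +
      pos3(x - t[K]) * (t[K - 1L] - t[j]) / (t[K] - t[K - 1L])) / norm
  }
  colnames(out) <- c("lin", if (K > 2L) paste0("rcs", seq_len(K - 2L)))
  out
}
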
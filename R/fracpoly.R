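#' @name fracpoly
#' @title Fractional-polynomial meta-regression of LACE estimates
#'
#' @description
#' The causal curve \eqn{h(x)} is modelled as a fractional polynomial: a sum
#' of one (degree 1) or two (degree 2) terms \eqn{x^p} with powers from a
#' small discrete set, where \eqn{p = 0} denotes \eqn{\ln x} and a repeated
#' degree-2 power contributes \eqn{x^p \ln x}. Because each LACE estimate is
#' the local slope of \eqn{h} at its stratum's mean exposure, the model is
#' fitted by inverse-variance weighted meta-regression of the LACE estimates
#' on the *derivative* of each candidate term evaluated at the stratum
#' means, with no intercept (the level of \eqn{h} is not identified; only
#' its shape is). With this parameterisation the meta-regression coefficient
#' of a term equals the coefficient of that term in \eqn{h} itself.
#'
#' The default power set is \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}; the classic
#' named shapes (linear, quadratic, cubic, logarithmic, reciprocal,
#' square-root) are the subset \{1, 2, 3, 0, -1, 0.5\}.
NULL

#' Default fractional-polynomial power set
#' @export
fp_default_powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

.check_fp_x <- function(p, x) {
  needs_positive <- p < 1 || p != round(p)
  if (needs_positive && any(x <= 0))
    stop("exposure values must be positive for power ", p,
         "; shift the exposure (e.g. --shift) before fitting", call. = FALSE)
}

#' Derivative basis of a fractional-polynomial term
#'
#' Returns \eqn{d/dx\, x^p} evaluated at `x`: `p * x^(p-1)` for `p != 0` and
#' `1/x` for `p = 0` (the logarithmic term). This is the regressor used in
#' the LACE meta-regression for power `p`.
#'
#' @param p Power (scalar).
#' @param x Exposure values (must be positive for non-integer or
#'   non-positive powers).
#' @export
fp_derivative_basis <- function(p, x) {
  stopifnot(length(p) == 1L)
  .check_fp_x(p, x)
  if (p == 0) 1 / x else p * x^(p - 1)
}

# derivative of the second term for a repeated power:
# d/dx [x^p ln x] = x^(p-1) (p ln x + 1);  p = 0: d/dx (ln x)^2 = 2 ln(x)/x
fp_repeat_basis <- function(p, x) {
  .check_fp_x(p, x)
  if (p == 0) 2 * log(x) / x else x^(p - 1) * (p * log(x) + 1)
}

# the integrated terms of h(x); columns match fp_basis_matrix
fp_term <- function(p, x, repeated = FALSE) {
  .check_fp_x(p, x)
  if (!repeated) {
    if (p == 0) log(x) else x^p
  } else {
    if (p == 0) log(x)^2 else x^p * log(x)
  }
}

# design matrix for a power specification (length 1 or 2, sorted; a repeated
# value marks the logarithmic second term)
fp_basis_matrix <- function(powers, x) {
  if (length(powers) == 1L)
    return(cbind(fp_derivative_basis(powers, x)))
  if (powers[1] == powers[2])
    cbind(fp_derivative_basis(powers[1], x), fp_repeat_basis(powers[1], x))
  else
    cbind(fp_derivative_basis(powers[1], x), fp_derivative_basis(powers[2], x))
}

fp_curve_matrix <- function(powers, x) {
  if (length(powers) == 1L)
    return(cbind(fp_term(powers, x)))
  if (powers[1] == powers[2])
    cbind(fp_term(powers[1], x), fp_term(powers[1], x, repeated = TRUE))
  else
    cbind(fp_term(powers[1], x), fp_term(powers[2], x))
}

#' Fit one fractional-polynomial model to a LACE table
#'
#' Weighted least squares (weights `1/se^2`, no intercept) of the LACE
#' estimates on the derivative basis at the stratum mean exposures. The
#' log-likelihood is that of the weighted normal model with known
#' per-stratum variances, used for model selection and the likelihood-ratio
#' non-linearity tests.
#'
#' @param lace A [compute_lace()] table.
#' @param powers One power (degree 1) or two (degree 2; equal values give
#'   the repeated-power model with an \eqn{x^p \ln x} second term).
#' @return Object of class `fracpoly_fit`: list with `degree`, `powers`,
#'   `coefficients` (equal to the coefficients of the terms of `h`),
#'   `loglik`, `fitted`, `residuals` and the source `lace` table.
#' @export
fit_fracpoly <- function(lace, powers) {
  stopifnot(inherits(lace, "lace_table"))
  powers <- sort(as.numeric(powers))
  degree <- length(powers)
  if (!degree %in% 1:2) stop("degree must be 1 or 2", call. = FALSE)
  K <- nrow(lace)
  if (K <= degree)
    stop("need more strata than coefficients (K > degree)", call. = FALSE)
  X <- fp_basis_matrix(powers, lace$xmean)
  w <- 1 / lace$se^2
  XtWX <- crossprod(X, w * X)
  if (rcond(XtWX) < 1e-12)
    stop("collinear basis columns for powers ",
         paste(powers, collapse = ", "), call. = FALSE)
  beta <- solve(XtWX, crossprod(X, w * lace$lace))
  fitted <- as.numeric(X %*% beta)
  resid <- lace$lace - fitted
  loglik <- -0.5 * sum((resid / lace$se)^2 + log(2 * pi * lace$se^2))
  structure(list(degree = degree, powers = powers,
                 coefficients = as.numeric(beta),
                 loglik = loglik, fitted = fitted, residuals = resid,
                 vcov = solve(XtWX), lace = lace),
            class = "fracpoly_fit")
}

#' @export
print.fracpoly_fit <- function(x, ...) {
  cat(sprintf("Fractional polynomial fit: degree %d, power(s) %s\n",
              x$degree, paste(x$powers, collapse = ", ")))
  cat(sprintf("  coefficient(s): %s\n",
              paste(signif(x$coefficients, 4), collapse = ", ")))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' Likelihood search over the fractional-polynomial family
#'
#' Enumerates every degree-1 power, or every unordered degree-2 pair with
#' repetition, and returns the fit with the highest log-likelihood. Ties are
#' broken deterministically in favour of the smaller power(s) (candidates
#' are enumerated in increasing order and only a strictly larger likelihood
#' displaces the incumbent).
#'
#' @inheritParams fit_fracpoly
#' @param powers Candidate power set (default [fp_default_powers]).
#' @param degree 1 or 2.
#' @return The best `fracpoly_fit`, with a `candidates` data frame attached
#'   listing every attempted model's powers and log-likelihood.
#' @export
select_best <- function(lace, powers = fp_default_powers, degree = 1L) {
  stopifnot(inherits(lace, "lace_table"))
  powers <- sort(unique(as.numeric(powers)))
  if (!length(powers)) stop("empty power set", call. = FALSE)
  degree <- as.integer(degree)
  cand <- if (degree == 1L) {
    lapply(powers, function(p) p)
  } else if (degree == 2L) {
    out <- list()
    for (i in seq_along(powers))
      for (j in i:length(powers))
        out[[length(out) + 1L]] <- c(powers[i], powers[j])
    out
  } else stop("degree must be 1 or 2", call. = FALSE)
  best <- NULL
  rows <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    fit <- tryCatch(fit_fracpoly(lace, cand[[i]]), error = function(e) NULL)
    rows[[i]] <- data.frame(
      powers = paste(cand[[i]], collapse = ","),
      loglik = if (is.null(fit)) NA_real_ else fit$loglik)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("no candidate fractional polynomial could be fitted", call. = FALSE)
  best$candidates <- do.call(rbind, rows)
  best
}

#' Evaluate the fitted causal curve
#'
#' Reconstructs \eqn{h(x) - h(x_{ref})} by integrating the fitted derivative
#' terms analytically; the curve is anchored to zero at the reference value
#' because only its shape is identified.
#'
#' @param fit A `fracpoly_fit`.
#' @param x Exposure values at which to evaluate (positive).
#' @param x_ref Reference exposure value.
#' @return Numeric vector, same length as `x`.
#' @export
fracpoly_curve <- function(fit, x, x_ref) {
  stopifnot(inherits(fit, "fracpoly_fit"), length(x_ref) == 1L)
  H <- fp_curve_matrix(fit$powers, x)
  H0 <- fp_curve_matrix(fit$powers, x_ref)
  as.numeric((H - matrix(H0, nrow(H), ncol(H), byrow = TRUE)) %*%
               fit$coefficients)
}

#' Non-linearity tests
#'
#' Four tests of the shape of the exposure-outcome relationship, computed
#' from the LACE estimates:
#' \describe{
#'   \item{fp_d1_d2}{likelihood-ratio test (chi-squared, 1 df) of the best
#'     degree-2 fractional polynomial against the best degree-1 model; a low
#'     p-value prefers degree 2.}
#'   \item{fp}{likelihood-ratio test (chi-squared, 1 df) of the best
#'     degree-1 model against the linear model (power 1); a low p-value
#'     prefers a non-linear fractional polynomial. The 1-df reference
#'     ignores the power search, a documented approximation.}
#'   \item{quad}{meta-regression trend test of the LACE estimates on the
#'     stratum mean exposures; a low p-value indicates a linear trend in the
#'     local slopes, i.e. curvature of \eqn{h}.}
#'   \item{Q}{Cochran's Q over the LACE estimates; a low p-value indicates
#'     heterogeneity of the local slopes, i.e. any departure from a straight
#'     line.}
#' }
#'
#' @param lace A [compute_lace()] table.
#' @param best_d1,best_d2 Optional pre-computed [select_best()] fits for
#'   degrees 1 and 2 (recomputed if omitted).
#' @param powers Candidate power set used when refitting.
#' @return Object of class `nonlinearity_report`: list with `p_fp_d1_d2`,
#'   `p_fp`, `p_quad`, `p_q`.
#' @export
nonlinearity_tests <- function(lace, best_d1 = NULL, best_d2 = NULL,
                               powers = fp_default_powers) {
  stopifnot(inherits(lace, "lace_table"))
  if (is.null(best_d1)) best_d1 <- select_best(lace, powers, degree = 1L)
  if (is.null(best_d2)) best_d2 <- select_best(lace, powers, degree = 2L)
  linear <- fit_fracpoly(lace, 1)
  if (best_d1$loglik < linear$loglik - 1e-8)
    stop("internal error: degree-1 search excluded the linear model",
         call. = FALSE)
  lr12 <- max(0, 2 * (best_d2$loglik - best_d1$loglik))
  lr1l <- max(0, 2 * (best_d1$loglik - linear$loglik))
  quad <- trend_test(lace$lace, lace$se, lace$xmean)
  q <- cochran_q(lace$lace, lace$se)
  structure(list(
    p_fp_d1_d2 = stats::pchisq(lr12, df = 1, lower.tail = FALSE),
    p_fp = stats::pchisq(lr1l, df = 1, lower.tail = FALSE),
    p_quad = quad$p_value,
    p_q = q$p_value),
    class = "nonlinearity_report")
}

#' @export
print.nonlinearity_report <- function(x, ...) {
  cat("Non-linearity tests (LACE estimates):\n")
  cat(sprintf("  fp_d1_d2 p = %.4g   (degree 2 vs degree 1)\n", x$p_fp_d1_d2))
  cat(sprintf("  fp       p = %.4g   (best degree 1 vs linear)\n", x$p_fp))
  cat(sprintf("  quad     p = %.4g   (trend in LACE)\n", x$p_quad))
  cat(sprintf("  Q        p = %.4g   (heterogeneity in LACE)\n", x$p_q))
  invisible(x)
}
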
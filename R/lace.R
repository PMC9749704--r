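#' Localised average causal effect (LACE) estimates
#'
#' Per-stratum instrumental-variable ratio estimates: the instrument-outcome
#' association divided by the instrument-exposure association. Under the
#' homogeneity assumption (constant instrument-exposure effect across
#' exposure levels) each ratio estimates the local slope of the causal curve
#' at that stratum's exposure level.
#'
#' The default standard error is the first-order approximation
#' `byse / |bx|`, which ignores the (typically much smaller) uncertainty in
#' the instrument-exposure association. `se_method = "delta2"` adds the
#' second-order term `by^2 * bxse^2 / bx^4` under the square root.
#'
#' @param summary An [stratified_summary()] object.
#' @param se_method `"first_order"` (default) or `"delta2"`.
#' @return Object of class `lace_table`: data frame with columns
#'   `stratum, lace, se, xmean, xmin, xmax`, carrying the source metadata.
#' @examples
#' s <- ldl_cad_example()
#' compute_lace(s)
#' @export
compute_lace <- function(summary, se_method = c("first_order", "delta2")) {
  stopifnot(inherits(summary, "mr_summary"))
  se_method <- match.arg(se_method)
  zero_bx <- which(summary$bx == 0)
  if (length(zero_bx))
    stop("instrument-exposure association is zero in stratum ",
         summary$stratum[zero_bx[1]], call. = FALSE)
  lace <- summary$by / summary$bx
  se <- summary$byse / abs(summary$bx)
  if (se_method == "delta2")
    se <- sqrt(summary$byse^2 / summary$bx^2 +
                 summary$by^2 * summary$bxse^2 / summary$bx^4)
  out <- data.frame(stratum = summary$stratum, lace = lace, se = se,
                    xmean = summary$xmean, xmin = summary$xmin,
                    xmax = summary$xmax)
  structure(out,
            class = c("lace_table", "data.frame"),
            outcome_type = attr(summary, "outcome_type"),
            se_method = se_method,
            stratum_sizes = attr(summary, "stratum_sizes"))
}

#' @export
print.lace_table <- function(x, ...) {
  cat(sprintf("LACE estimates (%d strata, %s SE)\n",
              nrow(x), attr(x, "se_method")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cochran's Q heterogeneity test
#'
#' Fixed-effect inverse-variance heterogeneity statistic
#' \eqn{Q = \sum_k w_k (e_k - \bar e_w)^2} with \eqn{w_k = 1/se_k^2}, referred
#' to a chi-squared distribution with `K - 1` degrees of freedom.
#'
#' @param estimates Numeric vector of estimates.
#' @param ses Their standard errors (all positive).
#' @return List with `q_stat`, `df`, `p_value`.
#' @export
cochran_q <- function(estimates, ses) {
  if (length(estimates) < 2L) stop("Q undefined for K<2", call. = FALSE)
  if (length(ses) != length(estimates) || any(ses <= 0))
    stop("ses must match estimates and be positive", call. = FALSE)
  w <- 1 / ses^2
  m <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - m)^2)
  df <- length(estimates) - 1L
  list(q_stat = q, df = df,
       p_value = stats::pchisq(q, df = df, lower.tail = FALSE))
}

#' Trend test by weighted meta-regression
#'
#' Weighted least-squares fit of the estimates on an intercept and `x_means`
#' with known-variance weights `1/se^2`; returns the slope, its standard
#' error from the weighted normal model, and a two-sided normal p-value. A
#' small p-value indicates a linear trend in the estimates across exposure
#' levels.
#'
#' @inheritParams cochran_q
#' @param x_means Exposure mean per stratum.
#' @return List with `slope`, `se`, `p_value`.
#' @export
trend_test <- function(estimates, ses, x_means) {
  K <- length(estimates)
  if (K < 3L)
    stop("trend test needs at least 3 strata", call. = FALSE)
  if (length(ses) != K || length(x_means) != K || any(ses <= 0))
    stop("ses and x_means must match estimates; ses positive", call. = FALSE)
  w <- 1 / ses^2
  X <- cbind(1, x_means)
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * estimates))
  V <- solve(XtWX)                 # known variances: no residual scale
  slope <- unname(beta[2, 1])
  se <- sqrt(V[2, 2])
  list(slope = slope, se = se,
       p_value = 2 * stats::pnorm(-abs(slope / se)))
}

#' Instrument homogeneity diagnostics
#'
#' The stratified approach assumes the instrument-exposure association is the
#' same in every stratum. This applies Cochran's Q and the trend test to the
#' per-stratum `bx` estimates: a low Q p-value indicates heterogeneity in the
#' genetic associations, and a low trend p-value a systematic linear trend
#' across exposure levels (both would cast doubt on the LACE interpretation).
#'
#' @param summary An [stratified_summary()] object.
#' @return Object of class `homogeneity_report`: list with `q_stat`, `q_df`,
#'   `q_pvalue`, `trend_slope`, `trend_se`, `trend_pvalue`.
#' @export
assess_homogeneity <- function(summary) {
  stopifnot(inherits(summary, "mr_summary"))
  q <- cochran_q(summary$bx, summary$bxse)
  tr <- trend_test(summary$bx, summary$bxse, summary$xmean)
  structure(list(q_stat = q$q_stat, q_df = q$df, q_pvalue = q$p_value,
                 trend_slope = tr$slope, trend_se = tr$se,
                 trend_pvalue = tr$p_value),
            class = "homogeneity_report")
}

#' @export
print.homogeneity_report <- function(x, ...) {
  cat("Instrument homogeneity diagnostics (per-stratum bx):\n")
  cat(sprintf("  Q = %.4g on %d df, p = %.4g\n", x$q_stat, x$q_df, x$q_pvalue))
  cat(sprintf("  trend slope = %.4g (SE %.4g), p = %.4g\n",
              x$trend_slope, x$trend_se, x$trend_pvalue))
  invisible(x)
}
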
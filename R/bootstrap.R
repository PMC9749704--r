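#' @name bootstrap
#' @title Bootstrap uncertainty for the fitted causal curve
#' @description
#' The stratified-summary method quantifies uncertainty with a parametric
#' bootstrap: LACE estimates are repeatedly redrawn from independent normal
#' distributions centred at the estimates with SD equal to their standard
#' errors, the selected model is refitted to each draw (powers held fixed),
#' and percentile intervals are read off the draws. A conventional
#' nonparametric bootstrap over individuals is provided as the
#' individual-level oracle for equivalence experiments.
NULL

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

default_x_grid <- function(lace, n = 101L) {
  seq(min(lace$xmin), max(lace$xmax), length.out = n)
}

default_x_ref <- function(lace) {
  sizes <- attr(lace, "stratum_sizes")
  if (is.null(sizes)) mean(lace$xmean)
  else stats::weighted.mean(lace$xmean, sizes)
}

new_curve_estimate <- function(x, estimate, lower, upper, n_boot, seed,
                               ci_level) {
  df <- data.frame(x = x, estimate = estimate,
                   ci_lower = lower, ci_upper = upper)
  mc_flag <- any(df$ci_lower > df$estimate + 1e-12 |
                   df$ci_upper < df$estimate - 1e-12)
  structure(df, class = c("curve_estimate", "data.frame"),
            n_boot = n_boot, seed = seed, ci_level = ci_level,
            mc_violation = mc_flag)
}

#' Parametric bootstrap for a fitted stage-two model
#'
#' Draws `lace*_k ~ N(lace_k, se_k)` independently `n_boot` times, refits
#' the supplied model to each draw with its structure held fixed (the
#' fractional-polynomial powers, or the piecewise knots), and returns the
#' coefficient draws plus a pointwise percentile confidence band for the
#' curve. Deterministic given `(seed, n_boot)`.
#'
#' @param lace A [compute_lace()] table.
#' @param model A `fracpoly_fit` or `piecewise_fit` for this `lace` table.
#' @param n_boot Number of draws (>= 100; default 1000).
#' @param seed Integer seed (required, so every interval is reproducible).
#' @param ci_level Confidence level (default 0.95).
#' @param x_grid Grid for the curve band; default 101 points spanning the
#'   reported percentile range.
#' @param x_ref Reference exposure; default as in [build_piecewise()].
#' @param reselect Re-run the degree-restricted power search inside every
#'   draw (sensitivity analysis; default `FALSE`, i.e. model-selection
#'   uncertainty is excluded).
#' @param powers Power set used when `reselect = TRUE`.
#' @return Object of class `mr_bootstrap`: list with `coef_draws` (matrix,
#'   one column per coefficient; `NULL` for piecewise), `coef_est`,
#'   `coef_ci`, `curve` (a `curve_estimate` data frame), `n_boot`, `seed`,
#'   `ci_level`, `n_discarded`.
#' @export
parametric_bootstrap <- function(lace, model, n_boot = 1000L, seed,
                                 ci_level = 0.95, x_grid = NULL,
                                 x_ref = NULL, reselect = FALSE,
                                 powers = fp_default_powers) {
  stopifnot(inherits(lace, "lace_table"))
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required", call. = FALSE)
  K <- nrow(lace)
  if (is.null(x_ref)) x_ref <- default_x_ref(lace)
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  draws <- with_seed(seed,
                     matrix(stats::rnorm(K * n_boot, lace$lace, lace$se),
                            nrow = K, ncol = n_boot))
  n_discarded <- 0L

  if (inherits(model, "fracpoly_fit")) {
    if (is.null(x_grid)) x_grid <- default_x_grid(lace)
    if (reselect) {
      coef_curves <- matrix(NA_real_, length(x_grid), n_boot)
      coef_draws <- matrix(NA_real_, n_boot, model$degree)
      for (b in seq_len(n_boot)) {
        lb <- lace; lb$lace <- draws[, b]
        fit_b <- tryCatch(select_best(lb, powers, degree = model$degree),
                          error = function(e) NULL)
        if (is.null(fit_b)) { n_discarded <- n_discarded + 1L; next }
        coef_curves[, b] <- fracpoly_curve(fit_b, x_grid, x_ref)
        coef_draws[b, seq_along(fit_b$coefficients)] <- fit_b$coefficients
      }
      keep <- !is.na(coef_curves[1, ])
      if (n_discarded > 0.01 * n_boot)
        stop("more than 1% of bootstrap refits failed", call. = FALSE)
      curve_draws <- coef_curves[, keep, drop = FALSE]
      coef_draws <- coef_draws[keep, , drop = FALSE]
    } else {
      # fixed powers and fixed weights: refitting is a fixed linear map
      X <- fp_basis_matrix(model$powers, lace$xmean)
      w <- 1 / lace$se^2
      M <- solve(crossprod(X, w * X), t(X * w))      # p x K
      coef_draws <- t(M %*% draws)                   # n_boot x p
      H <- fp_curve_matrix(model$powers, x_grid)
      H0 <- fp_curve_matrix(model$powers, x_ref)
      Hc <- H - matrix(H0, nrow(H), ncol(H), byrow = TRUE)
      curve_draws <- Hc %*% t(coef_draws)            # grid x n_boot
    }
    est <- fracpoly_curve(model, x_grid, x_ref)
    ci <- apply(curve_draws, 1, stats::quantile, probs = probs,
                type = 7, names = FALSE)
    coef_ci <- apply(coef_draws, 2, stats::quantile, probs = probs,
                     type = 7, names = FALSE)
    out <- list(coef_draws = coef_draws,
                coef_est = model$coefficients,
                coef_ci = t(coef_ci),
                curve = new_curve_estimate(x_grid, est, ci[1, ], ci[2, ],
                                           n_boot, seed, ci_level))
  } else if (inherits(model, "piecewise_fit")) {
    kn <- model$knots
    if (is.null(x_grid))
      x_grid <- seq(kn[1], kn[length(kn)], length.out = 101L)
    dkn <- diff(kn)
    cum <- apply(draws * dkn, 2, cumsum)             # K x n_boot
    heights <- rbind(0, cum)                         # (K+1) x n_boot
    seg_ref <- min(findInterval(model$x_ref, kn, rightmost.closed = TRUE),
                   length(kn) - 1L)
    ref_val <- heights[seg_ref, ] +
      draws[seg_ref, ] * (model$x_ref - kn[seg_ref])
    heights <- sweep(heights, 2, ref_val)
    seg <- pmin(findInterval(x_grid, kn, rightmost.closed = TRUE),
                length(kn) - 1L)
    curve_draws <- heights[seg, , drop = FALSE] +
      draws[seg, , drop = FALSE] * (x_grid - kn[seg])
    est <- evaluate_piecewise(model, x_grid)
    ci <- apply(curve_draws, 1, stats::quantile, probs = probs,
                type = 7, names = FALSE)
    out <- list(coef_draws = NULL, coef_est = model$slopes, coef_ci = NULL,
                curve = new_curve_estimate(x_grid, est, ci[1, ], ci[2, ],
                                           n_boot, seed, ci_level))
  } else stop("model must be a fracpoly_fit or piecewise_fit", call. = FALSE)

  out$n_boot <- n_boot; out$seed <- seed; out$ci_level <- ci_level
  out$n_discarded <- n_discarded
  class(out) <- "mr_bootstrap"
  out
}

#' @export
print.mr_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d draws, seed %s, %.0f%% percentile CIs\n",
              x$n_boot, format(x$seed), 100 * x$ci_level))
  if (!is.null(x$coef_ci)) {
    for (j in seq_along(x$coef_est))
      cat(sprintf("  coef %d: %.4g (%.4g, %.4g)\n", j, x$coef_est[j],
                  x$coef_ci[j, 1], x$coef_ci[j, 2]))
  }
  if (x$n_discarded > 0)
    cat(sprintf("  %d draws discarded\n", x$n_discarded))
  invisible(x)
}

# closed-form per-stratum simple regressions (no covariates, continuous
# outcome); matches lm() coefficients and SEs exactly, used in the
# resampling loop where lm() would dominate the runtime
fast_stratum_summary <- function(g, x, y, K) {
  gx <- x - mean(x); gg <- g - mean(g)
  bx_all <- sum(gg * gx) / sum(gg^2)
  r <- gx - bx_all * gg                    # residual exposure (centred)
  idx <- assign_strata(r, K)
  fast_fixed_strata_summary(g, x, y, idx, K)
}

# closed-form per-stratum regressions given stratum labels
fast_fixed_strata_summary <- function(g, x, y, idx, K) {
  ns <- tabulate(idx, K)
  sg <- rowsum_fast(g, idx, K); sx <- rowsum_fast(x, idx, K)
  sy <- rowsum_fast(y, idx, K)
  sgg <- rowsum_fast(g * g, idx, K); sgx <- rowsum_fast(g * x, idx, K)
  sgy <- rowsum_fast(g * y, idx, K); sxx <- rowsum_fast(x * x, idx, K)
  syy <- rowsum_fast(y * y, idx, K)
  Sgg <- sgg - sg^2 / ns
  Sgx <- sgx - sg * sx / ns
  Sgy <- sgy - sg * sy / ns
  Sxx <- sxx - sx^2 / ns
  Syy <- syy - sy^2 / ns
  bx <- Sgx / Sgg
  by <- Sgy / Sgg
  bxse <- sqrt(pmax(Sxx - bx^2 * Sgg, 0) / (ns - 2) / Sgg)
  byse <- sqrt(pmax(Syy - by^2 * Sgg, 0) / (ns - 2) / Sgg)
  list(bx = bx, bxse = bxse, by = by, byse = byse,
       xmean = sx / ns, sizes = ns, strata = idx)
}

rowsum_fast <- function(v, idx, K) {
  as.numeric(rowsum(v, idx, reorder = TRUE))
}

#' Nonparametric bootstrap over individuals (oracle path)
#'
#' The individual-level implementation of bootstrap uncertainty: resample
#' individuals with replacement, recompute the stratified summaries and LACE
#' estimates, refit the model (powers held fixed), and return the
#' coefficient draws. Used to verify that the parametric bootstrap on
#' summarised data is equivalent; not the recommended analysis path.
#'
#' By default (`restratify = FALSE`) the residual-exposure stratification
#' from the original data is held fixed and individuals are resampled within
#' their stratum, so both bootstrap flavours use identical stratification --
#' the comparison the equivalence experiments call for. With
#' `restratify = TRUE` each resample is drawn from the whole sample and the
#' full pipeline (residual regression, stratification, summaries) is redone;
#' this adds stratification noise and heavy-tailed ratio draws in the
#' extreme strata, and is provided as a sensitivity variant.
#'
#' Resamples in which a binary-outcome stratum contains a single class are
#' redrawn (counted; error if more than 5% of draws needed redrawing).
#'
#' @param data An [individual_data()] object (no covariates for the fast
#'   resampling path; covariates fall back to the full pipeline).
#' @param K Number of strata.
#' @param model A `fracpoly_fit` whose powers are refitted per resample.
#' @param n_boot Number of resamples.
#' @param seed Integer seed.
#' @param ci_level Confidence level for the percentile intervals.
#' @param restratify Redo stratification inside every resample (see above).
#' @return Object of class `mr_bootstrap` with `coef_draws`, `coef_ci`
#'   (percentile), `n_redrawn`.
#' @export
nonparametric_bootstrap_oracle <- function(data, K, model, n_boot = 500L,
                                           seed, ci_level = 0.95,
                                           restratify = FALSE) {
  stopifnot(inherits(data, "mr_individual"), inherits(model, "fracpoly_fit"))
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required", call. = FALSE)
  n <- nrow(data)
  n_boot <- as.integer(n_boot)
  binary <- attr(data, "outcome_type") == "binary"
  has_cov <- length(attr(data, "covariate_names")) > 0
  p <- length(model$coefficients)
  coef_draws <- matrix(NA_real_, n_boot, p)
  n_redrawn <- 0L
  strata0 <- assign_strata(compute_residual_exposure(data), K)
  stratum_rows <- split(seq_len(n), strata0)
  resample_ids <- function() {
    if (restratify) sample.int(n, n, replace = TRUE)
    else unlist(lapply(stratum_rows,
                       function(rows) rows[sample.int(length(rows),
                                                      length(rows),
                                                      replace = TRUE)]),
                use.names = FALSE)
  }
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- resample_ids()
        lt <- tryCatch({
          if (!binary && !has_cov && restratify) {
            s <- fast_stratum_summary(data$g[idx], data$x[idx], data$y[idx], K)
            data.frame(lace = s$by / s$bx, se = s$byse / abs(s$bx),
                       xmean = s$xmean)
          } else if (!binary && !has_cov) {
            s <- fast_fixed_strata_summary(data$g[idx], data$x[idx],
                                           data$y[idx], strata0[idx], K)
            data.frame(lace = s$by / s$bx, se = s$byse / abs(s$bx),
                       xmean = s$xmean)
          } else {
            db <- individual_data(data$g[idx], data$x[idx], data$y[idx],
                                  covariates = if (has_cov)
                                    as.data.frame(data)[idx,
                                      attr(data, "covariate_names"),
                                      drop = FALSE] else NULL,
                                  outcome_type = attr(data, "outcome_type"))
            sm <- if (restratify) {
              create_summary_data(db, K = K, quiet = TRUE)
            } else {
              stratum_associations(db, strata0[idx], K)
            }
            lc <- compute_lace(sm)
            data.frame(lace = lc$lace, se = lc$se, xmean = lc$xmean)
          }
        }, error = function(e) NULL)
        if (!is.null(lt)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 0.05 * n_boot)
          stop("more than 5% of resamples required redrawing", call. = FALSE)
      }
      X <- fp_basis_matrix(model$powers, lt$xmean)
      w <- 1 / lt$se^2
      coef_draws[b, ] <- solve(crossprod(X, w * X),
                               crossprod(X, w * lt$lace))
    }
  })
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  coef_ci <- t(apply(coef_draws, 2, stats::quantile, probs = probs,
                     type = 7, names = FALSE))
  structure(list(coef_draws = coef_draws, coef_est = model$coefficients,
                 coef_ci = coef_ci, curve = NULL, n_boot = n_boot,
                 seed = seed, ci_level = ci_level, n_discarded = 0L,
                 n_redrawn = n_redrawn),
            class = "mr_bootstrap")
}
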
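test_that("parametric bootstrap contracts: determinism, degeneracy, CI shape", {
  lc <- make_lace(c(0.3, 0.5, 0.4, 0.6, 0.5), rep(0.1, 5),
                  xmean = c(2, 3, 4, 5, 6))
  fit <- fit_fracpoly(lc, 1)

  b1 <- parametric_bootstrap(lc, fit, n_boot = 200, seed = 99)
  b2 <- parametric_bootstrap(lc, fit, n_boot = 200, seed = 99)
  expect_identical(b1$coef_draws, b2$coef_draws)
  expect_identical(as.data.frame(b1$curve), as.data.frame(b2$curve))

  # near-degenerate noise: every draw identical, zero-width intervals
  lc0 <- make_lace(c(0.3, 0.5, 0.4, 0.6, 0.5), rep(1e-12, 5),
                   xmean = c(2, 3, 4, 5, 6))
  fit0 <- fit_fracpoly(lc0, 1)
  b0 <- parametric_bootstrap(lc0, fit0, n_boot = 200, seed = 1)
  expect_lt(max(b0$curve$ci_upper - b0$curve$ci_lower), 1e-9)

  # pointwise CI brackets the estimate; zero width at the reference
  x_ref <- 4
  b3 <- parametric_bootstrap(lc, fit, n_boot = 2000, seed = 3, x_ref = x_ref,
                             x_grid = c(2, 3, x_ref, 5, 6))
  expect_true(all(b3$curve$ci_lower <= b3$curve$estimate + 1e-10))
  expect_true(all(b3$curve$ci_upper >= b3$curve$estimate - 1e-10))
  at_ref <- b3$curve[b3$curve$x == x_ref, ]
  expect_equal(at_ref$estimate, 0)
  expect_equal(at_ref$ci_upper - at_ref$ci_lower, 0)

  expect_error(parametric_bootstrap(lc, fit, n_boot = 50, seed = 1),
               "at least 100")
  expect_error(parametric_bootstrap(lc, fit, n_boot = 200), "seed")
})

test_that("bootstrap SE of the linear coefficient matches the analytic WLS SE", {
  lc <- make_lace(rnorm(10, 0.5, 0.05), rep(0.2, 10), xmean = 1:10)
  fit <- fit_fracpoly(lc, 1)
  analytic_se <- sqrt(fit$vcov[1, 1])    # (X'WX)^{-1}, known variances
  b <- parametric_bootstrap(lc, fit, n_boot = 5000, seed = 17)
  ratio <- sd(b$coef_draws[, 1]) / analytic_se
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
})

test_that("CI width is monotone in the LACE noise level", {
  widths <- sapply(c(0.5, 1, 2), function(mult) {
    lc <- make_lace(c(0.3, 0.5, 0.4, 0.6, 0.5), mult * rep(0.1, 5),
                    xmean = c(2, 3, 4, 5, 6))
    fit <- fit_fracpoly(lc, 1)
    b <- parametric_bootstrap(lc, fit, n_boot = 1000, seed = 5)
    diff(b$coef_ci[1, ])
  })
  expect_true(all(diff(widths) > 0))
})

test_that("piecewise curves get bootstrap bands too", {
  lc <- make_lace(c(1, -1), c(0.2, 0.2), xmean = c(0.5, 1.5),
                  xmin = c(0, 1), xmax = c(1, 2))
  pw <- build_piecewise(lc, x_ref = 0)
  b <- parametric_bootstrap(lc, pw, n_boot = 500, seed = 21)
  expect_equal(b$curve$estimate, evaluate_piecewise(pw, b$curve$x),
               tolerance = 1e-12)
  expect_true(all(b$curve$ci_lower <= b$curve$estimate + 1e-10))
  expect_true(all(b$curve$ci_upper >= b$curve$estimate - 1e-10))
})

test_that("summarised and individual-level point estimates coincide", {
  d <- generate_mr_data(sim_scenario(n = 4000, shape = "linear", seed = 43))
  s <- create_summary_data(d, K = 10, quiet = TRUE)
  lc <- compute_lace(s)
  fit <- fit_fracpoly(lc, 1)

  # the fast resampling path on the full (unresampled) data reduces to the
  # same WLS on the same LACE estimates
  fs <- fast_stratum_summary(d$g, d$x, d$y, K = 10)
  lace_fast <- fs$by / fs$bx
  se_fast <- fs$byse / abs(fs$bx)
  expect_equal(lace_fast, lc$lace, tolerance = 1e-10)
  expect_equal(se_fast, lc$se, tolerance = 1e-10)
  w <- 1 / se_fast^2
  expect_equal(sum(w * lace_fast) / sum(w), fit$coefficients,
               tolerance = 1e-10)
})

test_that("nonparametric oracle is reproducible and agrees with parametric", {
  d <- generate_mr_data(sim_scenario(n = 5000, shape = "linear", seed = 47))
  s <- create_summary_data(d, K = 10, quiet = TRUE)
  lc <- compute_lace(s)
  fit <- fit_fracpoly(lc, 1)

  o1 <- nonparametric_bootstrap_oracle(d, 10, fit, n_boot = 100, seed = 7)
  o2 <- nonparametric_bootstrap_oracle(d, 10, fit, n_boot = 100, seed = 7)
  expect_identical(o1$coef_draws, o2$coef_draws)

  # identical stratification (the default): SEs agree within 20%
  o <- nonparametric_bootstrap_oracle(d, 10, fit, n_boot = 500, seed = 8)
  p <- parametric_bootstrap(lc, fit, n_boot = 500, seed = 9)
  se_np <- sd(o$coef_draws[, 1])
  se_pb <- sd(p$coef_draws[, 1])
  expect_lt(abs(se_np / se_pb - 1), 0.2)

  # full restratification adds variability but still runs
  o2 <- nonparametric_bootstrap_oracle(d, 10, fit, n_boot = 100, seed = 8,
                                       restratify = TRUE)
  expect_false(anyNA(o2$coef_draws))
})
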
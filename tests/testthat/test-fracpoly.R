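test_that("derivative basis is the calculus derivative of x^p", {
  expect_equal(fp_derivative_basis(1, c(0.5, 3, 7)), rep(1, 3))
  expect_equal(fp_derivative_basis(2, 3), 6)
  expect_equal(fp_derivative_basis(0, 4), 0.25)
  expect_equal(fp_derivative_basis(-1, 2), -0.25)      # d/dx 1/x = -1/x^2
  expect_equal(fp_derivative_basis(0.5, 4), 0.5 * 4^(-0.5))
  expect_error(fp_derivative_basis(0.5, c(1, -2)), "positive")
  expect_error(fp_derivative_basis(0, 0), "positive")

  # numerical check against finite differences for every default power
  x <- 2.7; hstep <- 1e-6
  for (p in fp_default_powers) {
    fd <- (fp_term(p, x + hstep) - fp_term(p, x - hstep)) / (2 * hstep)
    expect_equal(fp_derivative_basis(p, x), fd, tolerance = 1e-6)
    fd2 <- (fp_term(p, x + hstep, TRUE) - fp_term(p, x - hstep, TRUE)) /
      (2 * hstep)
    expect_equal(fp_repeat_basis(p, x), fd2, tolerance = 1e-6)
  }
})

test_that("fit_fracpoly solves the weighted normal model", {
  # constant response, constant basis: exact fit with coefficient 0.32
  lc <- make_lace(rep(0.32, 6), rep(0.1, 6), xmean = 1:6)
  fit <- fit_fracpoly(lc, 1)
  expect_equal(fit$coefficients, 0.32, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 6), tolerance = 1e-12)

  # lace = 2x is the derivative of x^2: power 2, coefficient 1
  xm <- c(1, 2, 4, 5, 8)
  lc2 <- make_lace(2 * xm, rep(0.2, 5), xmean = xm)
  fit2 <- fit_fracpoly(lc2, 2)
  expect_equal(fit2$coefficients, 1, tolerance = 1e-12)
  expect_equal(fit2$fitted, 2 * xm, tolerance = 1e-12)

  # loglik equals the independent log-density oracle
  set.seed(23)
  for (i in 1:20) {
    lc3 <- random_lace(10)
    powers <- sample(list(1, 2, c(0, 2), c(1, 1), c(-1, 0.5)), 1)[[1]]
    fit3 <- fit_fracpoly(lc3, powers)
    expect_equal(fit3$loglik, oracle_loglik(fit3$residuals, lc3$se),
                 tolerance = 1e-10)
    # and the WLS solution equals brute-force normal equations
    X <- fp_basis_matrix(sort(powers), lc3$xmean)
    expect_equal(fit3$coefficients,
                 as.numeric(oracle_wls(X, lc3$lace, 1 / lc3$se^2)),
                 tolerance = 1e-10)
  }

  expect_error(fit_fracpoly(make_lace(c(1, 2), c(1, 1), c(1, 2)), c(1, 2)),
               "K > degree")
})

test_that("select_best enumerates the family and recovers exact patterns", {
  xm <- c(1, 2, 3.5, 5, 7, 9, 11, 12.5, 14, 16)

  # noise-free linear pattern (constant lace): power 1 wins
  fit <- select_best(make_lace(rep(0.7, 10), rep(0.1, 10), xm), degree = 1)
  expect_equal(fit$powers, 1)

  # lace proportional to 1/x: logarithmic outcome curve, power 0
  fit0 <- select_best(make_lace(3 / xm, rep(0.1, 10), xm), degree = 1)
  expect_equal(fit0$powers, 0)
  expect_equal(fit0$coefficients, 3, tolerance = 1e-8)

  # enumeration size: 8 powers, degree 2 with repetition -> 36 candidates
  fit2 <- select_best(random_lace(10), degree = 2)
  expect_equal(nrow(fit2$candidates), 36L)
  fit1 <- select_best(random_lace(10), degree = 1)
  expect_equal(nrow(fit1$candidates), 8L)

  # exact recovery of every power in the default set
  for (p in fp_default_powers) {
    truth <- 1.4 * fp_derivative_basis(p, xm)
    best <- select_best(make_lace(truth, rep(0.05, 10), xm), degree = 1)
    expect_equal(best$powers, p)
    expect_equal(best$coefficients, 1.4, tolerance = 1e-8)
  }
})

test_that("non-linearity tests behave at the exact-linear truth", {
  lc <- make_lace(rep(0.5, 8), rep(0.1, 8), xmean = (1:8) + 0.5)
  rep0 <- nonlinearity_tests(lc)
  expect_equal(rep0$p_fp, 1)
  expect_equal(rep0$p_quad, 1)
  expect_equal(rep0$p_q, 1)

  # p_q path shares the Cochran Q oracle
  lc2 <- make_lace(c(0, 1, 0.5), c(1, 1, 1), xmean = c(1, 2, 3))
  rep2 <- nonlinearity_tests(lc2)
  expect_equal(rep2$p_q, cochran_q(lc2$lace, lc2$se)$p_value)
  expect_equal(rep2$p_quad,
               trend_test(lc2$lace, lc2$se, lc2$xmean)$p_value)
  expect_true(all(unlist(rep2) >= 0 & unlist(rep2) <= 1))
})

test_that("fp test has power against a quadratic truth at default settings", {
  # regression guard: a 500-replicate oracle run at the default quadratic
  # scenario (n = 5000) estimated the fp-test power as 0.508 (MC SE 0.022);
  # the threshold is frozen at 0.44 (estimate minus 3 MC SEs)
  set.seed(29)
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    d <- generate_mr_data(sim_scenario(n = 5000, shape = "quadratic"))
    lc <- compute_lace(create_summary_data(d, quiet = TRUE))
    if (nonlinearity_tests(lc)$p_fp < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.44)
})

test_that("parameter recovery: linear truth beta = 0.32 is unbiased", {
  set.seed(31)
  coefs <- replicate(200, {
    d <- generate_mr_data(sim_scenario(n = 5000, shape = "linear"))
    lc <- compute_lace(create_summary_data(d, quiet = TRUE))
    fit_fracpoly(lc, 1)$coefficients
  })
  mc_se <- sd(coefs) / sqrt(length(coefs))
  expect_lt(abs(mean(coefs) - 0.32), 2 * mc_se)
})
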
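test_that("residual exposure is the OLS residual and orthogonal to g", {
  # perfect fit: x = g exactly
  d <- individual_data(g = c(0, 1, 2, 3), x = c(0, 1, 2, 3), y = rnorm(4))
  expect_equal(compute_residual_exposure(d), rep(0, 4), tolerance = 1e-12)

  # two points: exact interpolation x = 1 + 2g
  d2 <- individual_data(g = c(0, 1, 0, 1), x = c(1, 3, 1, 3), y = rnorm(4))
  expect_equal(compute_residual_exposure(d2), rep(0, 4), tolerance = 1e-12)

  # orthogonality on generated data
  set.seed(11)
  d3 <- generate_mr_data(sim_scenario(n = 1000, shape = "linear", seed = 11))
  r <- compute_residual_exposure(d3)
  expect_lt(abs(cor(r, d3$g)), 1e-10)

  d4 <- individual_data(g = rep(1, 10), x = rnorm(10), y = rnorm(10))
  expect_error(compute_residual_exposure(d4), "zero variance")
})

test_that("assign_strata ranks stably into near-equal groups", {
  # stratum = ceiling(rank / 2) when K = n/2
  expect_identical(assign_strata(c(5, 1, 3, 2, 4, 6, 8, 7, 10, 9), K = 5),
                   c(3L, 1L, 2L, 1L, 2L, 3L, 4L, 4L, 5L, 5L))
  expect_identical(assign_strata(1:10, K = 2), rep(1:2, each = 5))

  # group sizes from integer division, brute-forced over several n
  for (n in c(100, 103, 107, 119)) {
    idx <- assign_strata(rnorm(n), K = 10)
    sizes <- tabulate(idx, 10)
    expect_equal(sort(sizes), sort(c(rep(n %/% 10, 10 - n %% 10),
                                     rep(n %/% 10 + 1, n %% 10))))
    expect_equal(sum(sizes), n)            # union = full sample
  }

  # ties broken by input order (stable)
  idx <- assign_strata(rep(0, 6), K = 3)
  expect_identical(idx, rep(1:3, each = 2L))

  expect_error(assign_strata(rnorm(10), K = 6), "too few observations")
})

test_that("stratum associations recover exact and sampled effects", {
  # exact linear outcome within strata: y = 2g + 1
  set.seed(21)
  g <- rnorm(200); x <- rnorm(200) + 5; y <- 2 * g + 1
  d <- individual_data(g, x, y)
  s <- suppressWarnings(   # lm warns on the deliberately perfect fit
    stratum_associations(d, assign_strata(compute_residual_exposure(d), 4)))
  expect_equal(s$by, rep(2, 4), tolerance = 1e-10)

  # percentile rule: type-7 quantiles, 10/90 interior, 20/80 extreme
  expect_equal(unname(stratum_percentiles(1:100, k = 2, K = 4)),
               quantile(1:100, c(0.10, 0.90), type = 7, names = FALSE))
  expect_equal(unname(stratum_percentiles(1:100, k = 1, K = 4)),
               quantile(1:100, c(0.20, 0.80), type = 7, names = FALSE))
  expect_equal(unname(stratum_percentiles(1:100, k = 4, K = 4)),
               quantile(1:100, c(0.20, 0.80), type = 7, names = FALSE))

  # homogeneous instrument effect 0.25: every bx within 4 SE
  d2 <- generate_mr_data(sim_scenario(n = 10000, shape = "null", seed = 31))
  s2 <- create_summary_data(d2, K = 10, quiet = TRUE)
  expect_true(all(abs(s2$bx - 0.25) < 4 * s2$bxse))
})

test_that("binary strata use logistic ML matching an independent IRLS fit", {
  set.seed(41)
  d <- generate_mr_data(sim_scenario(n = 3000, shape = "null",
                                     outcome_type = "binary", seed = 41))
  strata <- assign_strata(compute_residual_exposure(d), 5)
  s <- stratum_associations(d, strata, 5)
  for (k in c(1, 3, 5)) {
    sel <- strata == k
    beta <- oracle_logistic(d$g[sel], d$y[sel])
    expect_equal(s$by[k], beta[2], tolerance = 1e-8)
  }

  # a stratum with one outcome class is reported by number
  d2 <- individual_data(g = rnorm(40), x = sort(rnorm(40)),
                        y = rep(c(0, 1), each = 20), outcome_type = "binary")
  expect_error(stratum_associations(d2, rep(1:2, each = 20), 2),
               "stratum 1")
})

test_that("create_summary_data composes the stages and round-trips", {
  d <- generate_mr_data(sim_scenario(n = 5000, shape = "null", seed = 51))
  s <- create_summary_data(d, quiet = TRUE)         # K defaults to 10
  expect_equal(nrow(s), 10)
  expect_true(all(diff(s$xmean) > 0))
  expect_true(all(s$bxse > 0 & s$byse > 0))
  expect_true(all(s$xmin < s$xmean & s$xmean < s$xmax))

  path <- tempfile(fileext = ".csv")
  write_summary(s, path)
  s2 <- read_summary(path)
  for (col in c("bx", "bxse", "by", "byse", "xmean", "xmin", "xmax"))
    expect_equal(s2[[col]], s[[col]], tolerance = 1e-12)

  # dropped rows are counted
  g <- rnorm(500); x <- rnorm(500) + 9; y <- rnorm(500)
  x[c(3, 7)] <- NA
  di <- individual_data(g, x, y)
  expect_equal(attr(di, "n_dropped"), 2L)
  expect_message(create_summary_data(di, K = 5), "dropped 2")
})
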
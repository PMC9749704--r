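# Independent oracles: deliberately naive implementations (explicit loops,
# no shared code with R/) used to cross-check the package's linear algebra.

# two-pass Cochran Q
oracle_q <- function(est, se) {
  w <- numeric(length(est))
  for (i in seq_along(est)) w[i] <- 1 / se[i]^2
  m <- 0
  for (i in seq_along(est)) m <- m + w[i] * est[i]
  m <- m / sum(w)
  q <- 0
  for (i in seq_along(est)) q <- q + w[i] * (est[i] - m)^2
  q
}

# weighted least squares by explicitly assembled normal equations
oracle_wls <- function(X, y, w) {
  X <- as.matrix(X)
  p <- ncol(X)
  A <- matrix(0, p, p); b <- numeric(p)
  for (i in seq_len(nrow(X))) {
    xi <- X[i, ]
    A <- A + w[i] * tcrossprod(xi)
    b <- b + w[i] * xi * y[i]
  }
  solve(A, b)
}

# weighted-normal log density with known per-observation SDs
oracle_loglik <- function(resid, se) {
  sum(stats::dnorm(resid, mean = 0, sd = se, log = TRUE))
}

# logistic regression by hand-rolled Newton-Raphson (IRLS)
oracle_logistic <- function(X, y, tol = 1e-12, maxit = 50) {
  X <- cbind(1, as.matrix(X))
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(crossprod(X, W * X), crossprod(X, y - mu))
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# build a lace_table directly (bypasses stage one)
make_lace <- function(lace, se, xmean,
                      xmin = xmean - 0.4, xmax = xmean + 0.4,
                      sizes = NULL) {
  structure(data.frame(stratum = seq_along(lace), lace = lace, se = se,
                       xmean = xmean, xmin = xmin, xmax = xmax),
            class = c("lace_table", "data.frame"),
            outcome_type = "continuous", se_method = "first_order",
            stratum_sizes = sizes)
}

random_lace <- function(K = 10) {
  xmean <- sort(stats::runif(K, 1, 12))
  make_lace(lace = stats::rnorm(K), se = stats::runif(K, 0.1, 1),
            xmean = xmean)
}
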
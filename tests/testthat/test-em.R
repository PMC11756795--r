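test_that("E-step posterior weights match the conjugate gamma posterior", {
  d <- make_toy(6, 2, c(1, -1), seed = 1)
  # force specific residuals by choosing beta = truth and checking the formula
  fit <- list(beta = c(1, -1), sigma2 = 2, nu = 5)
  w <- e_step(d, fit)
  r <- d$y - d$X %*% fit$beta
  expect_equal(w$tau_hat, as.numeric((5 + 1) / (5 + r^2 / 2)), tolerance = 1e-12)

  # zero residual: tau = (nu + 1)/nu
  d0 <- ptlr_dataset(matrix(c(1, 2), 2, 1), c(0.5, 1.0))
  w0 <- e_step(d0, list(beta = 0.5, sigma2 = 1, nu = 5))
  expect_equal(w0$tau_hat, c(1.2, 1.2))

  # r^2/sigma2 = 5 with nu = 5 gives 6/10
  dA <- ptlr_dataset(matrix(0, 2, 1), c(sqrt(5), sqrt(5)))
  wA <- e_step(dA, list(beta = 0, sigma2 = 1, nu = 5))
  expect_equal(wA$tau_hat, c(0.6, 0.6))

  # numerical-integration oracle for E[tau | r] under the gamma-normal hierarchy
  post_mean <- function(r, s2, nu) {
    num <- integrate(function(t) t * sqrt(t) * exp(-t * r^2 / (2 * s2)) *
                       dgamma(t, nu / 2, nu / 2), 0, Inf, rel.tol = 1e-10)$value
    den <- integrate(function(t) sqrt(t) * exp(-t * r^2 / (2 * s2)) *
                       dgamma(t, nu / 2, nu / 2), 0, Inf, rel.tol = 1e-10)$value
    num / den
  }
  for (r in c(0.3, 1, 3)) {
    dr <- ptlr_dataset(matrix(0, 2, 1), c(r, r))
    wr <- e_step(dr, list(beta = 0, sigma2 = 1.5, nu = 4))
    expect_equal(wr$tau_hat[1], post_mean(r, 1.5, 4), tolerance = 1e-6)
  }
})

test_that("E-step weights decrease in |residual| and stay in (0, (nu+1)/nu]", {
  rs <- seq(0, 20, by = 0.5)
  d <- ptlr_dataset(matrix(0, length(rs), 1), rs)
  w <- e_step(d, list(beta = 0, sigma2 = 1, nu = 7))
  expect_true(all(diff(w$tau_hat) < 0 | rs[-1] == 0))
  expect_true(all(w$tau_hat > 0))
  expect_true(all(w$tau_hat <= (7 + 1) / 7 + 1e-12))
  expect_equal(w$tau_hat[1], (7 + 1) / 7)
})

test_that("beta M-step solves the weighted lasso (closed forms and sign-pattern oracle)", {
  # lambda = 0, p = 1, unit weights: weighted least-squares slope
  set.seed(2)
  x <- rnorm(20); y <- 2 * x + rnorm(20)
  d <- ptlr_dataset(matrix(x), y)
  w1 <- list(tau_hat = rep(1, 20))
  b <- m_step_beta(d, w1, sigma2 = 1, lambda = 0)
  expect_equal(as.numeric(b), sum(x * y) / sum(x^2), tolerance = 1e-10)

  # lambda above the null threshold gives the zero vector
  d5 <- make_toy(20, 5, c(1, -1, 0.5, 0, 0), seed = 3)
  tau <- runif(20, 0.5, 1.2)
  s2 <- 1.7
  lmax <- max(abs(crossprod(d5$X, tau * d5$y))) / s2
  b0 <- m_step_beta(d5, list(tau_hat = tau), s2, lmax * 1.0001)
  expect_equal(as.numeric(b0), rep(0, 5))

  # random instances against the exhaustive sign-pattern oracle
  for (seed in 1:4) {
    dd <- make_toy(20, 5, c(1.5, -1, 0, 0, 0.3), seed = seed)
    set.seed(seed + 50)
    tau <- runif(20, 0.3, 1.2)
    s2 <- runif(1, 0.5, 2)
    lambda <- 0.15 * max(abs(crossprod(dd$X, tau * dd$y))) / s2
    b <- m_step_beta(dd, list(tau_hat = tau), s2, lambda)
    oracle <- lasso_sign_oracle(dd$X, dd$y, tau / s2, lambda)
    expect_equal(as.numeric(b), as.numeric(oracle), tolerance = 1e-6)
    expect_lt(attr(b, "kkt_violation"), 1e-6)
  }
})

test_that("sigma2 M-step is the weighted mean square and maximizes the expected likelihood", {
  d <- ptlr_dataset(matrix(0, 2, 1), c(1, -1))
  expect_equal(m_step_sigma2(d, list(tau_hat = c(1, 1)), beta = 0), 1)
  d2 <- ptlr_dataset(matrix(0, 2, 1), c(1, 2))
  expect_equal(m_step_sigma2(d2, list(tau_hat = c(2, 0.5)), beta = 0), 2)
  # oracle: 1-D maximization of E[L1] in sigma2
  dd <- make_toy(30, 2, c(1, -0.5), seed = 9)
  tau <- runif(30, 0.4, 1.3)
  beta <- c(0.9, -0.6)
  r <- dd$y - dd$X %*% beta
  q <- function(s2) sum(0.5 * log(tau) - 0.5 * log(2 * pi * s2) - tau * r^2 / (2 * s2))
  opt <- optimize(q, c(1e-4, 20), maximum = TRUE)$maximum
  expect_equal(m_step_sigma2(dd, list(tau_hat = tau), beta), opt, tolerance = 1e-4)
  # all-zero residuals are degenerate
  dz <- ptlr_dataset(matrix(c(1, 2), 2, 1), c(2, 4))
  expect_error(m_step_sigma2(dz, list(tau_hat = c(1, 1)), beta = 2), "degenerate")
})

test_that("nu M-step solves the expected-likelihood score and matches a grid oracle", {
  # oracle: grid maximization of E[L2](nu) given E-step expectations
  set.seed(11)
  r <- rt(500, df = 6)
  d <- ptlr_dataset(matrix(0, 500, 1), r)
  w <- e_step(d, list(beta = 0, sigma2 = 1, nu = 6))
  el2 <- function(nu) {
    sum((nu / 2 - 1) * w$log_tau_hat - nu / 2 * w$tau_hat +
          nu / 2 * log(nu / 2) - lgamma(nu / 2))
  }
  grid <- seq(1, 100, by = 0.01)
  nu_grid <- grid[which.max(vapply(grid, el2, 0))]
  nu_hat <- m_step_nu(w, c(1, 100))
  expect_equal(nu_hat, nu_grid, tolerance = 0.02)

  # parameter recovery from latent weights at the truth
  set.seed(12)
  r <- rt(10000, df = 5)
  dr <- ptlr_dataset(matrix(0, 10000, 1), r)
  wr <- e_step(dr, list(beta = 0, sigma2 = 1, nu = 5))
  expect_lt(abs(m_step_nu(wr, c(1, 100)) - 5), 0.5)

  # near-Gaussian weights push the solution to the upper bound
  wg <- list(tau_hat = rep(1, 100), log_tau_hat = rep(-1e-6, 100))
  expect_equal(m_step_nu(wg, c(1, 50)), 50)
  expect_error(m_step_nu(wr, c(-1, 5)), "nu_bounds")
})
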
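#' E-step: posterior moments of the latent precision multipliers
#'
#' Under the gamma-normal hierarchy of the t model, each observation carries a
#' latent multiplier `tau_i ~ Gamma(nu/2, nu/2)` such that
#' `y_i | tau_i ~ N(x_i' beta, sigma2 / tau_i)`. Conditionally on the data and
#' the current parameters the multiplier is again gamma distributed, giving the
#' closed forms
#' `E[tau_i] = (nu + 1) / (nu + r_i^2 / sigma2)` and
#' `E[log tau_i] = digamma((nu + 1)/2) - log((nu + r_i^2/sigma2)/2)`,
#' with `r_i` the current residual. Observations with large residuals receive
#' small weights, which is where the robustness of the t fit comes from.
#'
#' @param data a [ptlr_dataset()].
#' @param fit a list or `ptlr_fit` with elements `beta`, `sigma2`, `nu`.
#' @param offset optional per-observation offset.
#' @return list with `tau_hat` and `log_tau_hat`, both length `data$n`.
#' @export
e_step <- function(data, fit, offset = NULL) {
  beta <- fit$beta
  sigma2 <- fit$sigma2[1]
  nu <- fit$nu[1]
  stopifnot(is.finite(sigma2), sigma2 > 0, is.finite(nu), nu > 0,
            all(is.finite(beta)))
  r <- data$y - as.numeric(data$X %*% beta)
  if (!is.null(offset)) r <- r - offset
  d <- r^2 / sigma2
  list(tau_hat = (nu + 1) / (nu + d),
       log_tau_hat = digamma((nu + 1) / 2) - log((nu + d) / 2))
}

#' M-step for the coefficients: weighted lasso
#'
#' Minimizes `(1/(2 sigma2)) * sum_i tau_i (y_i - x_i' beta)^2 + lambda ||beta||_1`
#' by cyclic coordinate descent with soft thresholding, warm-started from
#' `beta_init`. The returned solution carries its KKT certificate (maximal
#' subgradient violation) as an attribute.
#'
#' @param data a [ptlr_dataset()].
#' @param weights E-step output (or any list with positive `tau_hat`).
#' @param sigma2 current squared scale.
#' @param lambda nonnegative penalty level.
#' @param beta_init warm start (defaults to zero).
#' @param offset optional per-observation offset.
#' @return coefficient vector with attribute `kkt_violation`.
#' @export
m_step_beta <- function(data, weights, sigma2, lambda, beta_init = NULL,
                        offset = NULL) {
  tau <- weights$tau_hat
  stopifnot(all(tau > 0), sigma2 > 0, lambda >= 0, length(tau) == data$n)
  if (is.null(beta_init)) beta_init <- numeric(data$p)
  z <- data$y
  if (!is.null(offset)) z <- z - offset
  res <- .cd_lasso_cpp(data$X, z, tau / sigma2, lambda, beta_init,
                       rep(1L, data$p), 1e-10, 10000L)
  if (!is.finite(res$kkt_violation)) {
    stop("coordinate descent failed to converge (working set did not stabilize)")
  }
  structure(as.numeric(res$beta), kkt_violation = res$kkt_violation)
}

#' M-step for the squared scale
#'
#' `sigma2 = (1/n) sum_i tau_i (y_i - x_i' beta)^2`, the maximizer of the
#' expected complete-data likelihood in the scale for fixed coefficients.
#'
#' @inheritParams m_step_beta
#' @param beta current coefficient vector.
#' @return positive scalar.
#' @export
m_step_sigma2 <- function(data, weights, beta, offset = NULL) {
  r <- data$y - as.numeric(data$X %*% beta)
  if (!is.null(offset)) r <- r - offset
  s2 <- mean(weights$tau_hat * r^2)
  if (s2 == 0) stop("degenerate fit: all residuals are zero")
  s2
}

#' M-step for the degrees of freedom
#'
#' Solves the stationarity condition of the expected complete-data likelihood
#' in `nu`:
#' `log(nu/2) + 1 - digamma(nu/2) + mean(log_tau_hat - tau_hat) = 0`.
#' The score is strictly decreasing in `nu`, so when it has no root inside
#' `nu_bounds` the maximizing boundary is returned (the upper bound for
#' near-Gaussian weight patterns).
#'
#' @param weights E-step output with `tau_hat` and `log_tau_hat`.
#' @param nu_bounds positive interval `c(lower, upper)`.
#' @return scalar degrees of freedom inside `nu_bounds`.
#' @export
m_step_nu <- function(weights, nu_bounds = c(1, 100)) {
  if (length(nu_bounds) != 2 || nu_bounds[1] <= 0 || nu_bounds[1] >= nu_bounds[2]) {
    stop("nu_bounds must be a positive interval with lower < upper")
  }
  cc <- mean(weights$log_tau_hat - weights$tau_hat)
  score <- function(nu) log(nu / 2) + 1 - digamma(nu / 2) + cc
  if (score(nu_bounds[1]) <= 0) return(nu_bounds[1])
  if (score(nu_bounds[2]) >= 0) return(nu_bounds[2])
  uniroot(score, nu_bounds, tol = 1e-10)$root
}
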
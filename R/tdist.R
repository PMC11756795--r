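#' Log-density of the scaled Student t distribution
#'
#' Density of `t(mu, sigma2, nu)`: location `mu`, squared scale `sigma2` and
#' degrees of freedom `nu`. As `nu` grows the density approaches the normal
#' with variance `sigma2`.
#'
#' @param y,mu observation and location (vectorized).
#' @param sigma2 squared scale, `> 0`.
#' @param nu degrees of freedom, `> 0`.
#' @return log density value(s).
#' @examples
#' t_log_density(0, 0, 1, 5)      # log dt(0, df = 5)
#' @export
t_log_density <- function(y, mu, sigma2, nu) {
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  if (any(nu <= 0)) stop("nu must be positive")
  r2 <- (y - mu)^2 / sigma2
  lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(pi * nu * sigma2) -
    (nu + 1) / 2 * log1p(r2 / nu)
}

#' Observed-data log-likelihood
#'
#' Sum over observations of the log t (or normal, for `nu = Inf`) density of
#' the residuals `y - X beta - offset`.
#'
#' @param data a [ptlr_dataset()].
#' @param beta coefficient vector of length `data$p`.
#' @param sigma2 squared scale.
#' @param nu degrees of freedom; `Inf` gives the normal log-likelihood.
#' @param offset optional per-observation offset subtracted from `y`.
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(data, beta, sigma2, nu, offset = NULL) {
  if (length(beta) != data$p) {
    stop("beta has length ", length(beta), " but data has p = ", data$p)
  }
  r <- data$y - as.numeric(data$X %*% beta)
  if (!is.null(offset)) r <- r - offset
  if (is.infinite(nu)) {
    sum(dnorm(r, sd = sqrt(sigma2), log = TRUE))
  } else {
    .loglik_cpp(r, sigma2, nu, TRUE)
  }
}
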
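# Shared fixtures and independent oracles for the unit tests.

# Small random regression dataset with controllable error tails.
make_toy <- function(n, p, beta, seed, sd = 1, df = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  eps <- if (is.null(df)) rnorm(n, sd = sd) else rt(n, df = df) * sd
  ptlr_dataset(X, as.numeric(X %*% beta) + eps)
}

# Exhaustive sign-pattern oracle for the weighted lasso
#   min (1/2) sum w_i (z_i - x_i'b)^2 + lambda ||b||_1.
# For every sign pattern s in {-1,0,1}^p solve the stationarity system on the
# active set and keep the candidates whose signs and KKT conditions check out;
# return the one with the lowest objective. Only feasible for tiny p.
lasso_sign_oracle <- function(X, z, w, lambda) {
  p <- ncol(X)
  W <- diag(w)
  obj <- function(b) 0.5 * sum(w * (z - X %*% b)^2) + lambda * sum(abs(b))
  best <- NULL; best_val <- Inf
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (k in seq_len(nrow(patterns))) {
    s <- patterns[k, ]
    A <- which(s != 0)
    b <- numeric(p)
    if (length(A) > 0) {
      XA <- X[, A, drop = FALSE]
      M <- crossprod(XA, W) %*% XA
      rhs <- crossprod(XA, w * z) - lambda * s[A]
      bA <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(bA) || any(sign(bA) != s[A])) next
      b[A] <- bA
    }
    g <- as.numeric(crossprod(X, w * (z - X %*% b)))
    if (any(abs(g[setdiff(seq_len(p), A)]) > lambda + 1e-8)) next
    v <- obj(b)
    if (v < best_val) { best_val <- v; best <- b }
  }
  best
}

# Observed t log-likelihood computed independently via stats::dt on the
# standardized scale (scale-family transformation of the unit t density).
t_loglik_oracle <- function(r, sigma2, nu) {
  s <- sqrt(sigma2)
  sum(dt(r / s, df = nu, log = TRUE) - log(s))
}
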
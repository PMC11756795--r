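# Fitting front ends: single-lambda fits, lambda paths and cross-validation,
# for both the t family (PtLR) and the Gaussian family (PNLR). Both run
# through the same C++ EM/coordinate-descent engine; the Gaussian family is
# the engine with unit latent weights and no degrees-of-freedom update.

# Prepare the design for fitting: optional unpenalized intercept column,
# optional column scaling, exclusion of constant columns and of columns
# outside a fixed support. Returns the working matrix plus what is needed to
# map coefficients back to the original scale.
prepare_design <- function(X, config, fix_support = NULL) {
  n <- nrow(X); p <- ncol(X)
  scl <- rep(1, p)
  if (config$standardize) {
    s <- apply(X, 2, sd)
    scl[s > 0] <- s[s > 0]
    X <- sweep(X, 2, scl, "/")
  }
  drop <- apply(X, 2, function(col) max(col) - min(col)) == 0
  if (!is.null(fix_support)) {
    if (any(fix_support < 1 | fix_support > p)) stop("fix_support out of range")
    drop[setdiff(seq_len(p), fix_support)] <- TRUE
  }
  if (any(drop)) X[, drop] <- 0  # zeroed columns are skipped by the solver
  penalized <- rep(1L, p)
  if (config$fit_intercept) {
    X <- cbind(1, X)
    penalized <- c(0L, penalized)
  }
  list(X = X, penalized = penalized, scl = scl, p = p,
       has_intercept = config$fit_intercept)
}

# Map engine-scale coefficients back: split off the intercept, undo scaling.
finish_beta <- function(b, design) {
  if (design$has_intercept) {
    list(intercept = b[1], beta = b[-1] / design$scl)
  } else {
    list(intercept = 0, beta = b / design$scl)
  }
}

# Initial latent weights used for the lambda grid: beta = 0,
# sigma2 = mean(z^2), nu = nu_init. The lasso subproblem weights are the tau
# themselves (penalty on the weighted-RSS scale).
initial_weights <- function(z, family, nu_init) {
  s2 <- max(mean(z^2), 1e-10)
  if (family == "t") {
    tau <- (nu_init + 1) / (nu_init + z^2 / s2)
  } else {
    tau <- rep(1, length(z))
  }
  list(w = tau, sigma2 = s2)
}

# Log-spaced lambda path from lambda_max (null solution under initial weights)
# down to lambda_min_ratio * lambda_max.
default_lambda_grid <- function(X, z, family, config) {
  iw <- initial_weights(z, family, config$nu_init)
  lmax <- max(abs(crossprod(X, iw$w * z)))
  lmax <- max(lmax, 1e-8)
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$nlambda))
}

new_ptlr_fit <- function(beta, intercept, sigma2, nu, lambda, loglik,
                         penalized_obj, n_iter, converged, kkt_violation,
                         family, n, p, trace = NULL) {
  structure(
    list(beta = as.numeric(beta), intercept = intercept,
         sigma2 = as.numeric(sigma2), nu = as.numeric(nu),
         lambda = lambda, loglik = loglik, penalized_obj = penalized_obj,
         n_iter = n_iter, converged = converged,
         kkt_violation = kkt_violation, family = family, n = n, p = p,
         trace = trace),
    class = "ptlr_fit"
  )
}

# Core path fit on a prepared (possibly stacked) design. grp is a 0-based
# integer group id per row; each group keeps its own (sigma2, nu).
em_path <- function(X, z, grp, G, lambdas, family, config,
                    beta0 = NULL, sigma20 = NULL, nu0 = NULL,
                    penalized = NULL, trace = FALSE, warm = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(beta0)) beta0 <- numeric(p)
  if (is.null(sigma20)) {
    sigma20 <- vapply(split(z, grp), function(zz) max(mean(zz^2), 1e-10), 0)
  }
  if (is.null(nu0)) nu0 <- rep(config$nu_init, G)
  if (is.null(penalized)) penalized <- rep(1L, p)
  .em_fit_cpp(X, z, numeric(n), as.integer(grp), as.integer(G),
              as.numeric(lambdas), family == "t",
              config$nu_bounds[1], config$nu_bounds[2], config$estimate_nu,
              beta0, sigma20, nu0, as.integer(penalized),
              config$tol, config$max_iter, config$cd_tol, config$cd_max_sweeps,
              trace,
              if (is.null(warm)) NULL else warm$beta,
              if (is.null(warm)) NULL else warm$sigma2,
              if (is.null(warm)) NULL else warm$nu)
}

#' Fit a penalized t-regression (PtLR) at a fixed penalty level
#'
#' Maximizes the penalized observed-data log-likelihood
#' `L(beta, sigma2, nu) - lambda * ||beta||_1` with t-distributed errors, by
#' alternating the closed-form E-step with coordinate-descent and 1-D M-step
#' updates until the L1 change of the full parameter vector drops below
#' `config$tol`. With `family = "gaussian"` the same engine fits the
#' normal-error lasso (PNLR) and `nu` is reported as `Inf`.
#'
#' The t fit is initialized from a Gaussian-lasso fit at the same `lambda`
#' (coefficients and residual scale), with the degrees of freedom starting at
#' `config$nu_init`.
#'
#' @param data a [ptlr_dataset()].
#' @param lambda nonnegative penalty level. The penalty is applied on the
#'   weighted residual-sum-of-squares scale of the working lasso subproblem
#'   (the standard lasso convention; for the Gaussian family this is exactly
#'   `min 0.5 * sum((y - X b)^2) + lambda * ||b||_1`), so `lambda` scales
#'   with the sample size.
#' @param config an [em_config()].
#' @param offset optional per-observation offset: the model becomes
#'   `y - offset = X beta + error`, which is how the transfer steps reuse this
#'   routine.
#' @param family `"t"` or `"gaussian"`.
#' @param fix_support optional integer vector; coefficients outside it are
#'   constrained to zero.
#' @param trace record the penalized objective at every EM iteration.
#' @return A `ptlr_fit` with the fitted `beta`, `sigma2`, `nu`, the observed
#'   log-likelihood, the penalized objective, iteration count, convergence
#'   flag and the KKT violation of the final coefficient update.
#' @examples
#' set.seed(1)
#' d <- ptlr_dataset(matrix(rnorm(300), 100, 3), rnorm(100))
#' fit_ptlr(d, lambda = 5)
#' @export
fit_ptlr <- function(data, lambda, config = em_config(), offset = NULL,
                     family = c("t", "gaussian"), fix_support = NULL,
                     trace = FALSE) {
  family <- match.arg(family)
  stopifnot(lambda >= 0)
  design <- prepare_design(data$X, config, fix_support)
  z <- data$y
  if (!is.null(offset)) {
    if (length(offset) != data$n) stop("offset must have length n")
    z <- z - offset
  }
  grp <- integer(data$n)

  beta0 <- NULL; sigma20 <- NULL
  if (family == "t") {
    g <- em_path(design$X, z, grp, 1L, lambda, "gaussian", config,
                 penalized = design$penalized)
    if (g$n_fitted >= 1) {
      beta0 <- as.numeric(g$beta[, 1])
      sigma20 <- as.numeric(g$sigma2[, 1])
    }
  }
  res <- em_path(design$X, z, grp, 1L, lambda, family, config,
                 beta0 = beta0, sigma20 = sigma20,
                 penalized = design$penalized, trace = trace)
  if (res$n_fitted < 1) stop("EM fit collapsed at lambda = ", signif(lambda, 4))
  if (!res$converged[1]) {
    warning("EM did not converge in ", config$max_iter, " iterations")
  }
  fb <- finish_beta(res$beta[, 1], design)
  new_ptlr_fit(fb$beta, fb$intercept, res$sigma2[, 1],
               if (family == "t") res$nu[, 1] else Inf,
               lambda, res$loglik[1], res$penalized_obj[1],
               res$n_iter[1], res$converged[1], res$kkt_violation[1],
               family, data$n, data$p,
               trace = if (trace) res$trace[[1]] else NULL)
}

#' Fit the Gaussian-error lasso (PNLR)
#'
#' Convenience wrapper: [fit_ptlr()] with `family = "gaussian"`.
#'
#' @inheritParams fit_ptlr
#' @return A `ptlr_fit` with `nu = Inf`.
#' @export
fit_pnlr <- function(data, lambda, config = em_config(), offset = NULL) {
  fit_ptlr(data, lambda, config, offset, family = "gaussian")
}

# Internal CV engine shared by single-dataset and joint (stacked) fits.
# Folds are formed over `target_rows` only; source rows always stay in the
# training part. The CV score of a lambda is the mean held-out per-observation
# log-likelihood, evaluated with the target-group (sigma2, nu) of the
# training-fold fit at that lambda.
cv_em <- function(X, z, grp, G, target_rows, family, config,
                  penalized = NULL, lambdas = NULL) {
  n <- nrow(X)
  if (is.null(lambdas)) lambdas <- config$lambda_grid
  if (is.null(lambdas)) lambdas <- default_lambda_grid(X, z, family, config)
  nL <- length(lambdas)
  k <- config$cv_folds
  if (length(target_rows) < 2 * k) {
    stop("too few target observations (", length(target_rows), ") for ",
         k, "-fold cross-validation")
  }
  foldid <- make_folds(length(target_rows), k, config$seed)

  # the full-data path is fitted first and used to warm-start every fold fit
  # at the matching lambda; each fold fit still iterates to the same
  # convergence criterion on its own training objective
  full <- em_path(X, z, grp, G, lambdas, family, config, penalized = penalized)
  warm <- list(beta = full$beta, sigma2 = full$sigma2, nu = full$nu)

  scores <- matrix(NA_real_, nL, k)
  for (f in seq_len(k)) {
    va <- target_rows[foldid == f]
    tr <- setdiff(seq_len(n), va)
    res <- em_path(X[tr, , drop = FALSE], z[tr], grp[tr], G, lambdas, family,
                   config, penalized = penalized, warm = warm)
    nf <- res$n_fitted
    if (nf < 1) next
    for (L in seq_len(nf)) {
      b <- res$beta[, L]
      r_va <- z[va] - as.numeric(X[va, , drop = FALSE] %*% b)
      s2 <- res$sigma2[1, L]   # group 0 = target
      nu <- res$nu[1, L]
      scores[L, f] <- .loglik_cpp(r_va, s2, if (family == "t") nu else 1,
                                  family == "t") / length(va)
    }
  }
  cv_score <- rowMeans(scores)
  cv_score[apply(scores, 1, anyNA)] <- -Inf

  ok <- seq_len(full$n_fitted)
  if (length(ok) == 0) stop("penalized fit collapsed on the full lambda path")
  cand <- cv_score[ok]
  best <- ok[which.max(cand)]  # ties resolve to the larger lambda
  list(lambda = lambdas[best], index = best, full = full,
       cv_table = data.frame(lambda = lambdas, cv_loglik = cv_score,
                             nonzero = colSums(full$beta != 0, na.rm = TRUE)))
}

# Extract a ptlr_fit for column `idx` of an em_path/cv result on a prepared design.
fit_from_path <- function(res, idx, lambda, family, design, n, p) {
  fb <- finish_beta(res$beta[, idx], design)
  new_ptlr_fit(fb$beta, fb$intercept, res$sigma2[, idx],
               if (family == "t") res$nu[, idx] else Inf,
               lambda, res$loglik[idx], res$penalized_obj[idx],
               res$n_iter[idx], res$converged[idx], res$kkt_violation[idx],
               family, n, p)
}

#' Select the penalty level by cross-validation
#'
#' Fits the penalty path on each training fold (warm starts down the path),
#' scores every `lambda` by the mean held-out per-observation log-likelihood
#' under the fold's fitted `(sigma2, nu)`, picks the maximizing `lambda`
#' (ties go to the sparser model), and refits on the full data.
#'
#' @inheritParams fit_ptlr
#' @return A list of class `ptlr_cv` with `lambda`, the full-data `fit` at
#'   that `lambda`, and `cv_table` (per-lambda score and support size).
#' @export
cv_select_lambda <- function(data, config = em_config(),
                             family = c("t", "gaussian"), offset = NULL) {
  family <- match.arg(family)
  design <- prepare_design(data$X, config)
  z <- data$y
  if (!is.null(offset)) z <- z - offset
  cv <- cv_em(design$X, z, integer(data$n), 1L, seq_len(data$n), family,
              config, penalized = design$penalized)
  fit <- fit_from_path(cv$full, cv$index, cv$lambda, family, design,
                       data$n, data$p)
  structure(list(lambda = cv$lambda, fit = fit, cv_table = cv$cv_table,
                 family = family),
            class = "ptlr_cv")
}

#' @export
print.ptlr_fit <- function(x, ...) {
  fam <- if (x$family == "t") sprintf("t (nu = %.2f)", x$nu[1]) else "gaussian"
  cat(sprintf("<ptlr_fit: %s family, lambda = %.4g>\n", fam, x$lambda))
  cat(sprintf("  nonzero coefficients: %d / %d\n", sum(x$beta != 0), x$p))
  cat(sprintf("  sigma2 = %s\n", paste(signif(x$sigma2, 4), collapse = ", ")))
  cat(sprintf("  loglik = %.4f (penalized %.4f), %d EM iterations%s\n",
              x$loglik, x$penalized_obj, x$n_iter,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' @export
print.ptlr_cv <- function(x, ...) {
  cat(sprintf("<ptlr_cv: %s family, %d lambdas, selected lambda = %.4g>\n",
              x$family, nrow(x$cv_table), x$lambda))
  print(x$fit)
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object a `ptlr_fit`.
#' @param newx matrix of predictors.
#' @param ... unused.
#' @return fitted values `intercept + newx %*% beta`.
#' @export
predict.ptlr_fit <- function(object, newx, ...) {
  object$intercept + as.numeric(newx %*% object$beta)
}
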
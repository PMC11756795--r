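# Synthetic-data generator for benchmarking the transfer estimators.
#
# The design: a target dataset (n0 = 150) and S = 10 source datasets
# (n_s = 100) with p = 500 AR(1)-correlated Gaussian predictors (rho = 0.7).
# The target coefficients are 0.5 on the first k = 16 positions and zero
# elsewhere. Transferable sources perturb the target coefficients by -h/100 on
# a random 50-subset of the null positions {17..p}; non-transferable sources
# additionally shift all k signal positions, so they mislead a fit that
# borrows from them. Errors come from one of four families: standard normal,
# t with 5 degrees of freedom, a 10%-contaminated normal, or a skew-t.

#' Simulation configuration
#'
#' @param n0 target sample size.
#' @param ns per-source sample size.
#' @param S number of source datasets.
#' @param p number of predictors.
#' @param rho AR(1) correlation of the predictors.
#' @param k number of nonzero target coefficients (the first `k` positions).
#' @param beta_val value of the nonzero target coefficients.
#' @param h heterogeneity level; sources are shifted by `h/100` per perturbed
#'   coordinate.
#' @param n_transferable number of transferable sources (chosen at random
#'   among the `S`).
#' @param H_size size of each source's random perturbation set inside
#'   `{k+1, ..., p}`.
#' @param error_family `"N"`, `"t"`, `"CN"` or `"St"`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n0 = 150L, ns = 100L, S = 10L, p = 500L, rho = 0.7,
                       k = 16L, beta_val = 0.5, h = 10,
                       n_transferable = 10L, H_size = 50L,
                       error_family = c("N", "t", "CN", "St")) {
  error_family <- match.arg(error_family)
  stopifnot(n0 >= 2, ns >= 2, S >= 0, p >= 1, abs(rho) < 1,
            k >= 1, k < p, H_size >= 0, H_size <= p - k,
            n_transferable >= 0, n_transferable <= S, h >= 0)
  structure(list(n0 = as.integer(n0), ns = as.integer(ns), S = as.integer(S),
                 p = as.integer(p), rho = rho, k = as.integer(k),
                 beta_val = beta_val, h = h,
                 n_transferable = as.integer(n_transferable),
                 H_size = as.integer(H_size), error_family = error_family),
            class = "sim_config")
}

#' AR(1) covariance matrix
#'
#' `Sigma[i, j] = rho^|i - j|`; symmetric positive definite for `|rho| < 1`.
#'
#' @param p dimension.
#' @param rho correlation parameter in `(-1, 1)`.
#' @return `p x p` covariance matrix.
#' @export
make_ar1_cov <- function(p, rho) {
  stopifnot(p >= 1)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  rho^abs(outer(seq_len(p), seq_len(p), "-"))
}

# Draw n rows from N(0, Sigma(rho)) using the AR(1) recursion
# X_1 = Z_1, X_j = rho X_{j-1} + sqrt(1 - rho^2) Z_j, which has exactly the
# rho^|i-j| covariance without factorizing a p x p matrix.
gen_ar1_X <- function(n, p, rho) {
  Z <- matrix(rnorm(n * p), n, p)
  if (p == 1 || rho == 0) return(Z)
  X <- Z
  a <- sqrt(1 - rho^2)
  for (j in 2:p) X[, j] <- rho * X[, j - 1] + a * Z[, j]
  X
}

#' Generate the true coefficient vectors
#'
#' Draws the transferable index set (a uniform random subset of the sources)
#' and each source's perturbation set `H_s` (uniform `H_size`-subset of the
#' null coordinates `{k+1, ..., p}`), then applies the coefficient rule:
#' transferable sources are `beta0 - (h/100) * 1{j in H_s}`, non-transferable
#' sources are `beta0 - (h/100) * 1{j in H_s or j <= k}`.
#'
#' Consumes the current RNG stream; seed the session (or use
#' [gen_multidata()]) for reproducibility.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_truth` with `beta0`, `betas` (list of `S`
#'   vectors), `transferable_set` and `H_sets`.
#' @export
gen_coefficients <- function(config) {
  p <- config$p; k <- config$k
  beta0 <- c(rep(config$beta_val, k), rep(0, p - k))
  transferable <- sort(sample(config$S)[seq_len(config$n_transferable)])
  shift <- config$h / 100
  H_sets <- vector("list", config$S)
  betas <- vector("list", config$S)
  for (s in seq_len(config$S)) {
    H <- sort(sample((k + 1):p, config$H_size))
    H_sets[[s]] <- H
    idx <- if (s %in% transferable) H else c(seq_len(k), H)
    b <- beta0
    b[idx] <- b[idx] - shift
    betas[[s]] <- b
  }
  structure(list(beta0 = beta0, betas = betas,
                 transferable_set = transferable, H_sets = H_sets),
            class = "sim_truth")
}

#' Draw random errors from one of the four benchmark families
#'
#' `"N"`: standard normal. `"t"`: t with 5 degrees of freedom (variance 5/3).
#' `"CN"`: contaminated normal `0.9 N(0,1) + 0.1 N(0,10)` with per-draw
#' component selection (variance 1.9). `"St"`: Azzalini skew-t with location
#' 0, scale 1, 5 degrees of freedom and slant 1.
#'
#' @param family error family code.
#' @param n number of draws.
#' @param df degrees of freedom for the t-based families.
#' @return numeric vector of length `n`.
#' @export
gen_errors <- function(family, n, df = 5) {
  switch(family,
    N = rnorm(n),
    t = rt(n, df = df),
    CN = {
      contaminated <- runif(n) < 0.1
      ifelse(contaminated, rnorm(n, sd = sqrt(10)), rnorm(n))
    },
    St = {
      # skew-normal via the additive representation, divided by sqrt(chi^2/df)
      alpha <- 1
      delta <- alpha / sqrt(1 + alpha^2)
      sn <- delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n)
      sn / sqrt(rchisq(n, df = df) / df)
    },
    stop("unknown error family: ", family)
  )
}

#' Generate a full target + sources bundle
#'
#' Draws the coefficient truth with [gen_coefficients()], then for each of the
#' `S + 1` datasets draws AR(1)-correlated Gaussian predictors and responses
#' `y = X beta + e` with errors from the configured family.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; when given, the whole bundle is a
#'   deterministic function of `(config, seed)` and the caller's RNG state is
#'   left untouched.
#' @return list with `target` (a [ptlr_dataset()]), `sources` (list of
#'   datasets) and `truth` (a `sim_truth`).
#' @export
gen_multidata <- function(config, seed = NULL) {
  gen <- function() {
    truth <- gen_coefficients(config)
    draw <- function(n, beta, role, id = NA_integer_) {
      X <- gen_ar1_X(n, config$p, config$rho)
      y <- as.numeric(X %*% beta) + gen_errors(config$error_family, n)
      ptlr_dataset(X, y, role = role, id = id)
    }
    target <- draw(config$n0, truth$beta0, "target")
    sources <- lapply(seq_len(config$S), function(s) {
      draw(config$ns, truth$betas[[s]], "source", s)
    })
    list(target = target, sources = sources, truth = truth)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Variable-selection precision and recall
#'
#' Precision is the fraction of selected (nonzero) coefficients that are truly
#' nonzero; recall is the fraction of truly nonzero coefficients that are
#' selected. An empty selection has precision 0 by convention (so that
#' averages over replications are always defined).
#'
#' @param beta_hat estimated coefficient vector.
#' @param beta_true true coefficient vector of the same length.
#' @return named vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(beta_hat, beta_true) {
  stopifnot(length(beta_hat) == length(beta_true))
  true_set <- which(beta_true != 0)
  if (length(true_set) == 0) stop("beta_true has no nonzero entries; recall undefined")
  sel <- which(beta_hat != 0)
  hit <- length(intersect(sel, true_set))
  c(precision = if (length(sel) == 0) 0 else hit / length(sel),
    recall = hit / length(true_set))
}

#' Cross-validated mean prediction error on the target
#'
#' Splits the target into `folds` folds (seeded); for each fold the supplied
#' method is retrained on the held-in part (any transfer machinery included,
#' with the source datasets unchanged) and scored by the mean squared
#' prediction error on the held-out part. Returns the average over folds.
#'
#' @param target the target [ptlr_dataset()].
#' @param method a function `function(train_target)` returning either a
#'   coefficient vector or an object with a `beta_TL`/`beta` element.
#' @param folds number of folds.
#' @param seed fold-split seed.
#' @return mean prediction error (scalar).
#' @export
prediction_error_cv <- function(target, method, folds = 5L, seed = 1L) {
  if (target$n < folds) stop("target smaller than the number of folds")
  foldid <- make_folds(target$n, folds, seed)
  errs <- vapply(seq_len(folds), function(f) {
    tr <- dataset_rows(target, which(foldid != f))
    va <- dataset_rows(target, which(foldid == f))
    out <- tryCatch(method(tr), error = function(e) {
      stop("method failed in fold ", f, ": ", conditionMessage(e))
    })
    beta <- if (is.numeric(out)) out
            else if (!is.null(out$beta_TL)) out$beta_TL
            else out$beta
    mean((va$y - as.numeric(va$X %*% beta))^2)
  }, 0)
  mean(errs)
}

sim_methods <- c("PtLR", "PNLR", "TransPtLR", "TransPNLR",
                 "NaiveTransPtLR", "NaiveTransPNLR")

# Fit one method on a generated bundle; returns the coefficient vector the
# method reports for the target.
fit_method <- function(method, target, sources, em, trans_em, threshold_t,
                       seed) {
  fam <- if (grepl("PtLR$", method)) "t" else "gaussian"
  if (method %in% c("PtLR", "PNLR")) {
    cfg <- em; cfg$seed <- seed
    return(cv_select_lambda(target, cfg, family = fam)$fit$beta)
  }
  tem <- trans_em; tem$seed <- seed
  tc <- transfer_config(threshold_t = threshold_t, seed = seed, em = tem,
                        family = fam)
  if (startsWith(method, "Naive")) {
    naive_transfer(target, sources, tc)$beta_TL
  } else {
    trans_fit(target, sources, tc)$beta_TL
  }
}

#' Run a simulation experiment grid
#'
#' For every combination of heterogeneity level, number of transferable
#' sources and error family, generates `reps` independent bundles and runs
#' the requested methods, recording the estimation error
#' `||beta_hat - beta0||_2^2`, the selection precision and recall, and
#' (optionally) the cross-validated mean prediction error. Every cell and
#' replication gets its own child seed, so any row of the result can be
#' regenerated independently.
#'
#' @param h_values,T_values,families grid of heterogeneity levels, numbers of
#'   transferable sources and error families.
#' @param methods subset of
#'   `c("PtLR", "PNLR", "TransPtLR", "TransPNLR", "NaiveTransPtLR",
#'   "NaiveTransPNLR")`.
#' @param reps replications per cell.
#' @param seed root seed.
#' @param threshold_t detection threshold for the Trans methods.
#' @param sim base [sim_config()]; `h`, `n_transferable` and `error_family`
#'   are overridden by the grid.
#' @param em [em_config()] for the target-only fits.
#' @param trans_em [em_config()] for every sub-fit of the transfer pipelines.
#' @param prediction also compute the 5-fold mean prediction error (slow:
#'   retrains every method five times per replication).
#' @return data.frame with one row per cell x replication x method; failed
#'   fits are recorded in the `error` column and their metrics set to `NA`.
#' @export
run_experiment <- function(h_values = 10, T_values = 10, families = "N",
                           methods = sim_methods, reps = 1L, seed = 1L,
                           threshold_t = 0.1, sim = sim_config(),
                           em = em_config(),
                           trans_em = em_config(nlambda = 20L,
                                                lambda_min_ratio = 0.01),
                           prediction = FALSE) {
  stopifnot(reps >= 1, all(methods %in% sim_methods))
  grid <- expand.grid(h = h_values, n_transferable = T_values,
                      family = families, rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, nrow(grid)))
  rows <- vector("list", nrow(grid) * length(methods))
  ri <- 0L
  for (g in seq_len(nrow(grid))) {
    cfg <- sim
    cfg$h <- grid$h[g]
    cfg$n_transferable <- as.integer(grid$n_transferable[g])
    cfg$error_family <- grid$family[g]
    bundle <- gen_multidata(cfg, seed = seeds[g])
    for (m in methods) {
      ri <- ri + 1L
      row <- data.frame(h = cfg$h, n_transferable = cfg$n_transferable,
                        family = cfg$error_family, rep = grid$rep[g],
                        seed = seeds[g], method = m,
                        estimation_error = NA_real_, precision = NA_real_,
                        recall = NA_real_, mpe = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
      res <- tryCatch({
        beta <- fit_method(m, bundle$target, bundle$sources, em, trans_em,
                           threshold_t, seeds[g])
        pr <- precision_recall(beta, bundle$truth$beta0)
        list(ee = sum((beta - bundle$truth$beta0)^2),
             precision = pr["precision"], recall = pr["recall"])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$estimation_error <- res$ee
        row$precision <- res$precision
        row$recall <- res$recall
        if (prediction) {
          mth <- m; srcs <- bundle$sources
          row$mpe <- tryCatch(
            prediction_error_cv(bundle$target, function(tr) {
              fit_method(mth, tr, srcs, em, trans_em, threshold_t, seeds[g])
            }, folds = 5L, seed = seeds[g]),
            error = function(e) NA_real_)
        }
      }
      rows[[ri]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate an experiment table
#'
#' Mean of each metric per cell and method, with the replication count.
#'
#' @param results output of [run_experiment()].
#' @return data.frame of cell-level means.
#' @export
aggregate_experiment <- function(results) {
  ok <- results[is.na(results$error), ]
  agg <- aggregate(ok[, c("estimation_error", "precision", "recall", "mpe")],
                   by = ok[, c("h", "n_transferable", "family", "method")],
                   FUN = function(v) mean(v, na.rm = TRUE))
  cnt <- aggregate(list(n_reps = ok$rep),
                   by = ok[, c("h", "n_transferable", "family", "method")],
                   FUN = length)
  merge(agg, cnt)
}
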
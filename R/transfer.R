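# Three-step transfer learning and transferable-source detection.
#
# Step 1 fits each candidate source on its own data; step 2 measures, on the
# target data, the l1-sparse contrast delta between a source's coefficients
# and the target's; step 3 jointly fits target and sources with each source's
# contrast subtracted out, sharing beta across datasets while every dataset
# keeps its own scale and degrees of freedom. Detection splits the target in
# half, runs the three steps per source on the training half, and admits the
# sources whose validation log-likelihood does not degrade beyond a threshold.

#' Transfer-learning configuration
#'
#' @param threshold_t nonnegative detection threshold: source `s` is kept when
#'   its validation statistic satisfies
#'   `T_s <= threshold_t * max(|L0|, 0.01)`, `L0` being the validation
#'   log-likelihood of the target-only fit. Negative statistics (the source
#'   improves validation fit) always pass.
#' @param split_fraction fraction of the target assigned to the training half
#'   of the detection split.
#' @param seed seed for the detection split.
#' @param em an [em_config()] used for every sub-fit. The default uses a
#'   15-value penalty path down to `0.01 * lambda_max` and an EM iteration
#'   cap of 50: transfer runs dozens of cross-validated fits, and the shorter
#'   warm-started path keeps them affordable without moving the selected
#'   models (past iteration 50 the coefficients change below 1e-5).
#' @param family `"t"` (Trans-PtLR) or `"gaussian"` (Trans-PNLR).
#' @return list of class `transfer_config`.
#' @export
transfer_config <- function(threshold_t = 0.1, split_fraction = 0.5,
                            seed = 1L,
                            em = em_config(nlambda = 15L, lambda_min_ratio = 0.01,
                                           max_iter = 50L, seed = seed),
                            family = c("t", "gaussian")) {
  family <- match.arg(family)
  stopifnot(threshold_t >= 0, split_fraction > 0, split_fraction < 1)
  if (em$fit_intercept || em$standardize) {
    stop("intercept/standardization are not supported inside transfer fits; ",
         "standardize the data beforehand")
  }
  structure(list(threshold_t = threshold_t, split_fraction = split_fraction,
                 seed = as.integer(seed), em = em, family = family),
            class = "transfer_config")
}

check_sources <- function(target, sources) {
  for (s in seq_along(sources)) {
    if (sources[[s]]$p != target$p) {
      stop("source ", s, " has p = ", sources[[s]]$p,
           " but target has p = ", target$p)
    }
  }
}

#' Step 1: fit each source dataset on its own data
#'
#' Cross-validated penalized fit (t or Gaussian family per `config$family`)
#' of every source dataset.
#'
#' @param sources list of [ptlr_dataset()] objects.
#' @param config a [transfer_config()].
#' @return list of `ptlr_fit` objects, one per source.
#' @export
fit_source_models <- function(sources, config = transfer_config()) {
  lapply(seq_along(sources), function(s) {
    tryCatch(
      cv_select_lambda(sources[[s]], config$em, family = config$family)$fit,
      error = function(e) stop("source ", s, ": ", conditionMessage(e))
    )
  })
}

#' Step 2: estimate the source-target coefficient contrast
#'
#' Fits `delta = argmax L(beta_s + delta; target) - lambda_delta ||delta||_1`
#' as a penalized regression of the target responses with the per-observation
#' offset `X beta_s`, so that the fitted coefficients are the sparse contrast
#' between the source model and the target model.
#'
#' @param target the target [ptlr_dataset()].
#' @param beta_s coefficient vector of a fitted source model (length `p`).
#' @param config a [transfer_config()].
#' @param source_id identifier stored in the result.
#' @return list of class `source_offset` with `source_id`, `delta_hat`,
#'   `lambda_delta` and the underlying `fit`.
#' @export
estimate_offset <- function(target, beta_s, config = transfer_config(),
                            source_id = NA_integer_) {
  if (length(beta_s) != target$p) {
    stop("beta_s has length ", length(beta_s), " but target has p = ", target$p)
  }
  off <- as.numeric(target$X %*% beta_s)
  cv <- cv_select_lambda(target, config$em, family = config$family, offset = off)
  structure(list(source_id = as.integer(source_id), delta_hat = cv$fit$beta,
                 lambda_delta = cv$lambda, fit = cv$fit),
            class = "source_offset")
}

#' Step 3: joint estimation over the target and transferable sources
#'
#' Maximizes `L(beta; target) + sum_s L(beta - delta_s; source s) -
#' lambda ||beta||_1` over `beta`, where each dataset keeps its own
#' `(sigma2, nu)` updated in the M-step. Source rows enter the stacked design
#' with the offset `-X_s delta_s`, and `lambda` is selected by
#' cross-validation over target observations only (sources always stay in the
#' training part).
#'
#' @param target the target [ptlr_dataset()].
#' @param sources list of source datasets.
#' @param offsets list of `source_offset` objects aligned with `sources`.
#' @param config a [transfer_config()].
#' @return a `ptlr_fit` whose `sigma2` and `nu` are vectors (target first,
#'   then one entry per source).
#' @export
joint_estimate <- function(target, sources, offsets, config = transfer_config()) {
  if (target$n < 2) stop("empty target")
  if (length(sources) != length(offsets)) {
    stop("offsets must align one-to-one with sources")
  }
  check_sources(target, sources)
  if (length(sources) == 0) {
    cv <- cv_select_lambda(target, config$em, family = config$family)
    return(cv$fit)
  }
  X <- do.call(rbind, c(list(target$X), lapply(sources, `[[`, "X")))
  # y - offset with offset = -X_s delta_s  <=>  z = y + X_s delta_s
  z <- c(target$y,
         unlist(lapply(seq_along(sources), function(s) {
           sources[[s]]$y + as.numeric(sources[[s]]$X %*% offsets[[s]]$delta_hat)
         })))
  grp <- rep(0:length(sources), c(target$n, vapply(sources, `[[`, 0L, "n")))
  cv <- cv_em(X, z, grp, length(sources) + 1L, seq_len(target$n),
              config$family, config$em)
  design <- list(scl = rep(1, target$p), has_intercept = FALSE)
  fit_from_path(cv$full, cv$index, cv$lambda, config$family, design,
                nrow(X), target$p)
}

new_transfer_result <- function(beta_TL, detected_set, stats, offsets,
                                source_fits, target_only_fit, joint_fit,
                                family) {
  structure(list(beta_TL = beta_TL, detected_set = detected_set,
                 stats = stats, offsets = offsets, source_fits = source_fits,
                 target_only_fit = target_only_fit, joint_fit = joint_fit,
                 family = family),
            class = "transfer_result")
}

#' Transfer learning with a known transferable set
#'
#' Runs the three-step estimator on the sources indexed by `T_set`. With an
#' empty set the result reduces exactly to the cross-validated target-only
#' fit.
#'
#' @param target the target [ptlr_dataset()].
#' @param sources list of source datasets.
#' @param T_set integer subset of `seq_along(sources)`.
#' @param config a [transfer_config()].
#' @param source_fits optional precomputed step-1 fits for all of `sources`
#'   (reused by the detection pipeline to avoid refitting).
#' @return a `transfer_result` with the joint estimate `beta_TL`, the
#'   per-source contrasts and the step-1 fits.
#' @export
transfer_fit_known <- function(target, sources, T_set,
                               config = transfer_config(),
                               source_fits = NULL) {
  T_set <- as.integer(T_set)
  if (length(T_set) > 0 &&
      (any(is.na(T_set)) || any(T_set < 1) || any(T_set > length(sources)))) {
    stop("T_set must index into the source list")
  }
  check_sources(target, sources)
  if (length(T_set) == 0) {
    cv <- cv_select_lambda(target, config$em, family = config$family)
    return(new_transfer_result(cv$fit$beta, integer(0), NULL, list(), list(),
                               cv$fit, cv$fit, config$family))
  }
  used <- sources[T_set]
  if (is.null(source_fits)) {
    fits <- fit_source_models(used, config)
  } else {
    fits <- source_fits[T_set]
  }
  offs <- lapply(seq_along(used), function(k) {
    estimate_offset(target, fits[[k]]$beta, config, source_id = T_set[k])
  })
  joint <- joint_estimate(target, used, offs, config)
  new_transfer_result(joint$beta, T_set, NULL, offs, fits, NULL, joint,
                      config$family)
}

# Profile (sigma2, nu) on training residuals with beta fixed, then evaluate
# the observed log-likelihood of the validation residuals.  Re-estimating the
# nuisance parameters on the training half keeps the likelihood scales of all
# candidates comparable without touching validation data.
validation_loglik <- function(beta, d_tr, d_va, config, sigma2_init, nu_init) {
  t_fam <- config$family == "t"
  r_tr <- d_tr$y - as.numeric(d_tr$X %*% beta)
  prof <- .profile_nuisance_cpp(r_tr, t_fam,
                                config$em$nu_bounds[1], config$em$nu_bounds[2],
                                config$em$estimate_nu,
                                sigma2_init, nu_init,
                                config$em$tol, config$em$max_iter)
  r_va <- d_va$y - as.numeric(d_va$X %*% beta)
  .loglik_cpp(r_va, prof$sigma2, if (t_fam) prof$nu else 1, t_fam)
}

#' Detect the transferable sources by sample splitting
#'
#' Splits the target into a training and a validation half (seeded
#' permutation; the training half gets the extra observation when `n` is
#' odd). A target-only model is fitted on the training half; for each source
#' the three-step transfer estimator is run with the training half as target.
#' Every candidate is scored on the validation half by
#' `T_s = L(beta_0; valid) - L(beta_s; valid)`, with `(sigma2, nu)`
#' re-estimated on the training half for each candidate's fixed coefficients.
#' Sources with `T_s <= threshold_t * max(|L(beta_0; valid)|, 0.01)` are
#' declared transferable.
#'
#' @inheritParams transfer_fit_known
#' @return list with `detected` (integer vector) and `stats` (one row per
#'   source: statistic, bound, decision, validation log-likelihoods).
#' @export
detect_transferable <- function(target, sources, config = transfer_config(),
                                source_fits = NULL) {
  if (target$n < 4) stop("target too small to split (n = ", target$n, ")")
  check_sources(target, sources)
  perm <- with_seed(config$seed, sample(target$n))
  n_tr <- ceiling(target$n * config$split_fraction)
  d_tr <- dataset_rows(target, perm[seq_len(n_tr)])
  d_va <- dataset_rows(target, perm[-seq_len(n_tr)])

  cv0 <- cv_select_lambda(d_tr, config$em, family = config$family)
  nu_init0 <- if (config$family == "t") cv0$fit$nu[1] else config$em$nu_init
  L0 <- validation_loglik(cv0$fit$beta, d_tr, d_va, config,
                          cv0$fit$sigma2[1], nu_init0)
  bound <- config$threshold_t * max(abs(L0), 0.01)

  if (is.null(source_fits)) source_fits <- fit_source_models(sources, config)
  Ls <- numeric(length(sources))
  for (s in seq_along(sources)) {
    cand <- transfer_fit_known(d_tr, sources, s, config,
                               source_fits = source_fits)
    Ls[s] <- validation_loglik(cand$beta_TL, d_tr, d_va, config,
                               cand$joint_fit$sigma2[1],
                               if (config$family == "t") cand$joint_fit$nu[1]
                               else config$em$nu_init)
  }
  That <- L0 - Ls
  stats <- data.frame(source = seq_along(sources), T_hat = That,
                      bound = bound, detected = That <= bound,
                      loglik_valid = Ls, loglik0_valid = L0)
  list(detected = which(That <= bound), stats = stats,
       source_fits = source_fits)
}

#' Trans-PtLR / Trans-PNLR: detection followed by transfer
#'
#' Runs [detect_transferable()], then [transfer_fit_known()] on the full
#' target with the detected set (step-1 source fits are reused). With an
#' empty detected set the result is the cross-validated target-only fit.
#'
#' @inheritParams transfer_fit_known
#' @return a `transfer_result`; `stats` holds the per-source detection table.
#' @examples
#' sim <- gen_multidata(sim_config(n0 = 40, p = 8, k = 3, S = 2, ns = 30,
#'                                 H_size = 2, n_transferable = 2), seed = 7)
#' \donttest{
#' res <- trans_fit(sim$target, sim$sources,
#'                  transfer_config(em = em_config(nlambda = 8, cv_folds = 3)))
#' res$detected_set
#' }
#' @export
trans_fit <- function(target, sources, config = transfer_config()) {
  det <- detect_transferable(target, sources, config)
  res <- transfer_fit_known(target, sources, det$detected, config,
                            source_fits = det$source_fits)
  res$stats <- det$stats
  res
}

#' Naive transfer: use every source without detection
#'
#' The three-step estimator applied to all sources; the classical "naive"
#' comparator that is vulnerable to negative transfer when some sources are
#' unrelated to the target.
#'
#' @inheritParams transfer_fit_known
#' @return a `transfer_result`.
#' @export
naive_transfer <- function(target, sources, config = transfer_config()) {
  if (length(sources) < 1) stop("naive transfer needs at least one source")
  transfer_fit_known(target, sources, seq_along(sources), config)
}

#' @export
print.transfer_result <- function(x, ...) {
  fam <- if (x$family == "t") "t" else "gaussian"
  cat(sprintf("<transfer_result: %s family>\n", fam))
  cat(sprintf("  transferable set: %s\n",
              if (length(x$detected_set) == 0) "(empty)"
              else paste(x$detected_set, collapse = ", ")))
  cat(sprintf("  nonzero coefficients in beta_TL: %d / %d\n",
              sum(x$beta_TL != 0), length(x$beta_TL)))
  if (!is.null(x$stats)) {
    cat("  detection statistics:\n")
    print(x$stats[, c("source", "T_hat", "bound", "detected")],
          row.names = FALSE)
  }
  invisible(x)
}
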
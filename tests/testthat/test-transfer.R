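# Transfer tests use a reduced design (smaller p, S and sample sizes than the
# benchmark defaults) so the full three-step machinery runs in seconds; the
# qualitative behavior being tested does not depend on the problem size.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n0 = 80, ns = 60, S = 2, p = 40, k = 5, beta_val = 0.5,
         H_size = 8, n_transferable = 2),
    list(...))
  do.call(sim_config, args)
}
fast_em <- function(seed = 1) {
  em_config(nlambda = 8, lambda_min_ratio = 0.03, max_iter = 25, tol = 1e-3,
            cv_folds = 3, seed = seed)
}

test_that("with no usable sources the transfer estimator is exactly the target-only fit", {
  b <- gen_multidata(small_cfg(error_family = "t"), seed = 201)
  tc <- transfer_config(seed = 201, em = fast_em(201))
  res <- transfer_fit_known(b$target, b$sources, integer(0), tc)
  cv <- cv_select_lambda(b$target, tc$em, family = "t")
  expect_identical(res$beta_TL, cv$fit$beta)
  expect_length(res$detected_set, 0)
  # empty source list end-to-end
  res2 <- transfer_fit_known(b$target, list(), integer(0), tc)
  expect_identical(res2$beta_TL, cv$fit$beta)
  expect_error(transfer_fit_known(b$target, b$sources, 5, tc), "index")
})

test_that("step 1 fits every source on its own data", {
  b <- gen_multidata(small_cfg(error_family = "N"), seed = 202)
  tc <- transfer_config(seed = 202, em = fast_em(202), family = "gaussian")
  expect_identical(fit_source_models(list(), tc), list())
  fits <- fit_source_models(b$sources, tc)
  expect_length(fits, 2)
  # a source that is the target's own data reproduces the target-only fit
  self <- ptlr_dataset(b$target$X, b$target$y, role = "source", id = 1)
  f_self <- fit_source_models(list(self), tc)[[1]]
  cv <- cv_select_lambda(b$target, tc$em, family = "gaussian")
  expect_equal(f_self$beta, cv$fit$beta, tolerance = 1e-10)
})

test_that("the offset step reduces to the target-only fit when beta_s = 0", {
  b <- gen_multidata(small_cfg(error_family = "t"), seed = 203)
  tc <- transfer_config(seed = 203, em = fast_em(203))
  off <- estimate_offset(b$target, rep(0, 40), tc, source_id = 1)
  cv <- cv_select_lambda(b$target, tc$em, family = "t")
  expect_identical(off$delta_hat, cv$fit$beta)
  expect_error(estimate_offset(b$target, rep(0, 10), tc), "length")
})

test_that("joint estimation with no sources collapses to the target-only fit", {
  b <- gen_multidata(small_cfg(error_family = "t"), seed = 204)
  tc <- transfer_config(seed = 204, em = fast_em(204))
  j <- joint_estimate(b$target, list(), list(), tc)
  cv <- cv_select_lambda(b$target, tc$em, family = "t")
  expect_identical(j$beta, cv$fit$beta)
  expect_error(joint_estimate(b$target, b$sources, list(), tc), "align")
})

test_that("a duplicated dataset in the joint fit acts like doubling the data", {
  # one source = exact copy of the target with a zero contrast: the stacked
  # two-group engine must match the single-group engine on the doubled data
  b <- gen_multidata(small_cfg(error_family = "t"), seed = 205)
  X <- b$target$X; y <- b$target$y
  X2 <- rbind(X, X); z2 <- c(y, y)
  cfg <- fast_em(205)
  lam <- transptlr:::default_lambda_grid(X2, z2, "t", cfg)[4]
  r_split <- transptlr:::em_path(X2, z2, rep(0:1, each = 80), 2L, lam, "t", cfg)
  r_doubled <- transptlr:::em_path(X2, z2, rep(0L, 160), 1L, lam, "t", cfg)
  # both runs stop at the configured 1e-3 parameter tolerance
  expect_equal(r_split$beta[, 1], r_doubled$beta[, 1], tolerance = 1e-3)
  expect_equal(r_split$sigma2[1, 1], r_doubled$sigma2[1, 1], tolerance = 1e-3)
})

test_that("detection is monotone in the threshold and reuses one split", {
  b <- gen_multidata(small_cfg(error_family = "t", h = 20,
                               n_transferable = 1), seed = 206)
  stats_at <- function(t) {
    tc <- transfer_config(threshold_t = t, seed = 206, em = fast_em(206))
    detect_transferable(b$target, b$sources, tc)
  }
  d0 <- stats_at(0)
  d1 <- stats_at(0.1)
  d2 <- stats_at(0.15)
  # identical split and fits => identical statistics, different cut-offs
  expect_equal(d0$stats$T_hat, d1$stats$T_hat)
  expect_true(all(d0$detected %in% d1$detected))
  expect_true(all(d1$detected %in% d2$detected))
  # the threshold rule: admitted iff T_hat <= t * max(|L0|, 0.01)
  bound <- 0.1 * max(abs(d1$stats$loglik0_valid[1]), 0.01)
  expect_equal(d1$stats$bound, rep(bound, 2))
  expect_setequal(d1$detected, which(d1$stats$T_hat <= bound))
  expect_error(detect_transferable(
    ptlr_dataset(matrix(rnorm(6), 3, 2), rnorm(3)), b$sources,
    transfer_config(seed = 1)), "small")
})

test_that("the full pipeline records detection statistics and runs both families", {
  b <- gen_multidata(small_cfg(error_family = "t"), seed = 207)
  for (fam in c("t", "gaussian")) {
    tc <- transfer_config(seed = 207, em = fast_em(207), family = fam)
    res <- trans_fit(b$target, b$sources, tc)
    expect_s3_class(res, "transfer_result")
    expect_equal(nrow(res$stats), 2)
    expect_true(all(res$detected_set %in% 1:2))
    expect_length(res$beta_TL, 40)
    expect_true(all(is.finite(res$beta_TL)))
  }
})

test_that("naive transfer equals the known-set estimator on all sources", {
  b <- gen_multidata(small_cfg(error_family = "N"), seed = 208)
  tc <- transfer_config(seed = 208, em = fast_em(208), family = "gaussian")
  nv <- naive_transfer(b$target, b$sources, tc)
  kn <- transfer_fit_known(b$target, b$sources, 1:2, tc)
  expect_identical(nv$beta_TL, kn$beta_TL)
  expect_error(naive_transfer(b$target, list(), tc), "source")
  # single transferable source: naive == known({1})
  nv1 <- naive_transfer(b$target, b$sources[1], tc)
  kn1 <- transfer_fit_known(b$target, b$sources[1], 1, tc)
  expect_identical(nv1$beta_TL, kn1$beta_TL)
})

test_that("borrowing from a same-distribution source does not hurt on average", {
  # positive-transfer property at a reduced design, averaged over seeds
  ee_t <- numeric(6); ee_tl <- numeric(6)
  for (k in 1:6) {
    cfg <- small_cfg(error_family = "t", n_transferable = 2, h = 10)
    b <- gen_multidata(cfg, seed = 300 + k)
    tc <- transfer_config(seed = 300 + k, em = fast_em(300 + k))
    cv <- cv_select_lambda(b$target, tc$em, family = "t")
    res <- transfer_fit_known(b$target, b$sources, 1:2, tc)
    ee_t[k] <- sum((cv$fit$beta - b$truth$beta0)^2)
    ee_tl[k] <- sum((res$beta_TL - b$truth$beta0)^2)
  }
  expect_lt(mean(ee_tl), mean(ee_t))
})
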
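# transptlr

Robust transfer learning for high-dimensional linear regression with
t-distributed errors.

## The problem

A target dataset — say, expression of one gene in a brain tissue, regressed
on hundreds of other genes — is often too small to estimate a sparse
high-dimensional model well, while related datasets (other tissues) are
larger but systematically different. Pooling everything biases the target
model; ignoring the sources wastes information. On top of that, expression
residuals are heavy-tailed and contaminated by outliers, which breaks
least-squares-based methods.

`transptlr` addresses both issues:

* **PtLR** — l1-penalized linear regression with t-distributed errors,
  $y_i = x_i^\top\beta + \varepsilon_i$, $\varepsilon_i \sim t(0, \sigma^2, \nu)$,
  fitted by an EM algorithm on the gamma-normal hierarchy
  ($y_i \mid \tau_i \sim N(x_i^\top\beta, \sigma^2/\tau_i)$,
  $\tau_i \sim \Gamma(\nu/2, \nu/2)$). Outlying observations receive small
  posterior weights $\hat\tau_i = (\nu+1)/(\nu + r_i^2/\sigma^2)$, which is
  where the robustness comes from. The degrees of freedom $\nu$ are
  estimated from the data.
* **Trans-PtLR** — a three-step transfer estimator: fit each source, measure
  its sparse contrast $\hat\delta^{(s)}$ to the target, then jointly fit
  target and offset-corrected sources with a shared $\beta$ and per-dataset
  $(\sigma^2, \nu)$. A cross-validation detector decides *which* sources to
  borrow from, guarding against negative transfer:
  $\hat T_s = L(\hat\beta^0;\text{valid}) - L(\hat\beta^s;\text{valid})$,
  admitting $s$ when $\hat T_s \le t\cdot\max(|L(\hat\beta^0;\text{valid})|, 0.01)$.
* **PNLR / Trans-PNLR** — the Gaussian-error counterparts (the identical
  engine with unit weights; PNLR is the standard lasso), for comparison.
* A simulation engine reproducing the benchmark design (AR(1)-correlated
  predictors, sparse signals, four error families including contaminated
  normal and skew-t) with seeded, replication-level reproducibility.

## Worked example

```r
library(transptlr)

# a benchmark bundle: target (150 x 500) + 10 transferable sources, t5 errors
sim <- gen_multidata(sim_config(error_family = "t"), seed = 42)

# target-only robust fit, penalty chosen by 5-fold CV
cv <- cv_select_lambda(sim$target, em_config(seed = 5), family = "t")
cv
#> <ptlr_cv: t family, 50 lambdas, selected lambda = 28.22>
#> <ptlr_fit: t (nu = 5.78) family, lambda = 28.22>
#>   nonzero coefficients: 22 / 500
#>   sigma2 = 1.333
#>   loglik = -261.3517 (penalized -413.3886), 39 EM iterations

precision_recall(cv$fit$beta, sim$truth$beta0)
#> precision    recall
#> 0.7272727 1.0000000

# full pipeline: detect transferable sources, then transfer
res <- trans_fit(sim$target, sim$sources,
                 transfer_config(seed = 5, family = "t"))
res$detected_set
#> [1]  1  2  3  4  5  6  7  8  9 10
precision_recall(res$beta_TL, sim$truth$beta0)
#> precision    recall
#>         1         1
```

The target-only robust fit recovers all 16 true predictors (recall 1) but
drags in 6 spurious ones (precision 0.73); after borrowing from the ten
detected sources the joint estimate keeps exactly the true support
(precision 1). The fitted degrees of freedom (5.8) sit near the generating
value of 5, and `sigma2` near the t5 scale.

A command-line interface wrapping the same functions ships in
`inst/cli/transptlr` (subcommands `fit`, `transfer`, `simulate`,
`benchmark`), reading CSV datasets and writing JSON/CSV reports.

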
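// EM engine for l1-penalized linear regression with t (or normal) errors.
//
// The t model is handled through its gamma-normal hierarchy: conditionally on a
// latent precision multiplier tau_i ~ Gamma(nu/2, nu/2), the response is normal
// with variance sigma^2 / tau_i.  The E-step gives closed-form posterior means
// of tau_i; the M-step is a tau-weighted lasso in beta (KKT-screened cyclic
// coordinate descent with soft thresholding), a weighted mean of squared
// residuals for sigma^2, and a 1-D conditional maximization of the observed
// log-likelihood for nu (ECME-style, which converges far faster in nu than the
// Q-based score update and is still monotone).  Multiple datasets may be
// stacked (a group index per row); each group keeps its own (sigma^2, nu)
// while beta is shared, which is what the joint transfer-learning fit needs.
//
// Penalty convention: the beta subproblem is
//   min (1/2) sum_i tau_i (z_i - x_i'beta)^2 + lambda ||beta||_1,
// i.e. the l1 penalty is measured on the weighted residual-sum-of-squares
// scale (the standard lasso convention; for the Gaussian family this is
// exactly the usual lasso, with lambda scaling with n because the quadratic
// term is a sum).  Relative to a penalty on the log-likelihood scale this
// makes the effective shrinkage lambda/sigma^2 self-calibrating: a penalty
// fixed on the likelihood scale loses all regularizing power as sigma^2
// shrinks, and in p >> n designs that feedback makes the penalized
// t-likelihood unbounded (interpolating m of n points sends it to +infinity
// once m/(n-m) > nu), so no stable fit would exist at any lambda.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SIGMA2_FLOOR = 1e-10;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One coordinate-descent pass over the indices in `set`.
// Residual r and coefficients b are kept in sync; returns max |change|.
static double cd_sweep(const arma::mat& X, const arma::vec& w,
                       const arma::vec& xtw, arma::vec& r, arma::vec& b,
                       double lambda, const arma::uvec& penalized,
                       const std::vector<arma::uword>& set) {
  const arma::uword n = X.n_rows;
  double maxd = 0.0;
  for (arma::uword j : set) {
    if (xtw(j) <= 1e-12) continue;
    const double* xj = X.colptr(j);
    double g = 0.0;
    for (arma::uword i = 0; i < n; ++i) g += w(i) * xj[i] * r(i);
    g += xtw(j) * b(j);
    double bnew = penalized(j) ? soft_threshold(g, lambda) / xtw(j) : g / xtw(j);
    double d = bnew - b(j);
    if (d != 0.0) {
      for (arma::uword i = 0; i < n; ++i) r(i) -= d * xj[i];
      b(j) = bnew;
      double ad = std::abs(d);
      if (ad > maxd) maxd = ad;
    }
  }
  return maxd;
}

// Weighted lasso by working-set coordinate descent: iterate CD on the current
// working set to convergence, then scan the full KKT gradient (one BLAS gemv)
// for violating coordinates; repeat until no coordinate violates.
// Returns the maximal KKT violation at the solution.
static double cd_lasso(const arma::mat& X, const arma::vec& w,
                       const arma::vec& xtw, arma::vec& r, arma::vec& b,
                       double lambda, const arma::uvec& penalized,
                       double cd_tol, int max_sweeps, bool grow = true) {
  const arma::uword p = X.n_cols;
  std::vector<arma::uword> working;
  working.reserve(p);
  for (arma::uword j = 0; j < p; ++j) {
    if (b(j) != 0.0 || !penalized(j)) working.push_back(j);
  }
  if (!grow) {
    // cheap mid-EM update: polish the current working set only; the full KKT
    // scan is re-run before convergence is accepted and at the final iterate
    for (int s = 0; s < max_sweeps; ++s) {
      if (cd_sweep(X, w, xtw, r, b, lambda, penalized, working) < cd_tol) break;
    }
    return -1.0;
  }
  for (int round = 0; round < 100; ++round) {
    for (int s = 0; s < max_sweeps; ++s) {
      if (cd_sweep(X, w, xtw, r, b, lambda, penalized, working) < cd_tol) break;
    }
    arma::vec g = X.t() * (w % r);  // full KKT scan
    bool grew = false;
    for (arma::uword j = 0; j < p; ++j) {
      if (b(j) == 0.0 && penalized(j) && xtw(j) > 1e-12 &&
          std::abs(g(j)) > lambda * (1.0 + 1e-12) + 1e-12) {
        working.push_back(j);
        grew = true;
      }
    }
    if (!grew) {
      double viol = 0.0;
      for (arma::uword j = 0; j < p; ++j) {
        if (xtw(j) <= 1e-12) continue;
        double v;
        if (!penalized(j)) v = std::abs(g(j));
        else if (b(j) == 0.0) v = std::max(0.0, std::abs(g(j)) - lambda);
        else v = std::abs(g(j) - lambda * ((b(j) > 0) ? 1.0 : -1.0));
        if (v > viol) viol = v;
      }
      return viol;
    }
  }
  return arma::datum::inf;  // working set failed to stabilize
}

// Observed-data log-likelihood of residuals r(idx) for one group.
static double group_loglik(const arma::vec& r, const arma::uvec& idx,
                           double sigma2, double nu, bool t_family) {
  const arma::vec ri = r.elem(idx);
  const double n = (double)idx.n_elem;
  if (t_family) {
    const double cst = R::lgammafn((nu + 1.0) / 2.0) - R::lgammafn(nu / 2.0)
      - 0.5 * std::log(M_PI * nu * sigma2);
    return n * cst
      - 0.5 * (nu + 1.0) * arma::accu(arma::log1p(arma::square(ri) / (nu * sigma2)));
  }
  const double cst = -0.5 * std::log(2.0 * M_PI * sigma2);
  return n * cst - arma::dot(ri, ri) / (2.0 * sigma2);
}

// d/dnu of the observed log-likelihood for one group (d = r^2/sigma2 fixed).
static double nu_obs_score(const arma::vec& d, double nu) {
  const double n = (double)d.n_elem;
  double s = n * (0.5 * R::digamma((nu + 1.0) / 2.0)
                  - 0.5 * R::digamma(nu / 2.0) - 0.5 / nu);
  s -= 0.5 * arma::accu(arma::log1p(d / nu));
  s += 0.5 * (nu + 1.0) * arma::accu(d / (nu * (nu + d)));
  return s;
}

// Conditional maximization of the observed log-likelihood over nu in [lo, hi]
// by safeguarded root-finding (Illinois variant) on the score; a score with no
// sign change returns the maximizing boundary (score > 0 everywhere => hi).
static double nu_cml(const arma::vec& r, const arma::uvec& idx, double sigma2,
                     double lo, double hi) {
  const arma::vec d = arma::square(r.elem(idx)) / sigma2;
  double fa = nu_obs_score(d, lo), fb = nu_obs_score(d, hi);
  if (fa <= 0.0) return lo;
  if (fb >= 0.0) return hi;
  double a = lo, b = hi;
  int side = 0;
  for (int it = 0; it < 100 && (b - a) > 1e-10 * (1.0 + b); ++it) {
    double m = (a * fb - b * fa) / (fb - fa);
    if (!(m > a && m < b)) m = 0.5 * (a + b);
    double fm = nu_obs_score(d, m);
    if (fm > 0.0) {
      a = m; fa = fm;
      if (side == 1) fb *= 0.5;
      side = 1;
    } else {
      b = m; fb = fm;
      if (side == -1) fa *= 0.5;
      side = -1;
    }
  }
  return 0.5 * (a + b);
}

// [[Rcpp::export(name = ".cd_lasso_cpp")]]
List cd_lasso_cpp(const arma::mat& X, const arma::vec& z, const arma::vec& w,
                  double lambda, arma::vec beta_init,
                  const arma::uvec& penalized, double cd_tol, int max_sweeps) {
  arma::vec b = beta_init;
  arma::vec r = z - X * b;
  arma::vec xtw = arma::square(X).t() * w;
  double viol = cd_lasso(X, w, xtw, r, b, lambda, penalized, cd_tol, max_sweeps);
  return List::create(_["beta"] = b, _["residual"] = r,
                      _["kkt_violation"] = viol);
}

// EM fit over a decreasing lambda path with warm starts.
// grp is 0-based group id per row; G groups; each group has its own
// (sigma2, nu).  Early path exit: if a group's scale collapses
// (near-interpolation) or the active set saturates the sample size, the
// remaining lambdas are reported as unfitted (NA).
// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(const arma::mat& X, const arma::vec& y, const arma::vec& offset,
                const arma::ivec& grp, int G,
                const arma::vec& lambdas, bool t_family,
                double nu_lo, double nu_hi, bool estimate_nu,
                arma::vec beta0, arma::vec sigma20, arma::vec nu0,
                const arma::uvec& penalized,
                double tol, int max_iter, double cd_tol, int cd_max_sweeps,
                bool trace,
                Rcpp::Nullable<Rcpp::NumericMatrix> beta_warm = R_NilValue,
                Rcpp::Nullable<Rcpp::NumericMatrix> sigma2_warm = R_NilValue,
                Rcpp::Nullable<Rcpp::NumericMatrix> nu_warm = R_NilValue) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword nL = lambdas.n_elem;

  std::vector<arma::uvec> gidx(G);
  {
    std::vector<std::vector<arma::uword>> tmp(G);
    for (arma::uword i = 0; i < n; ++i) tmp[grp(i)].push_back(i);
    for (int g = 0; g < G; ++g) gidx[g] = arma::uvec(tmp[g]);
  }

  const arma::mat X2t = arma::square(X).t();  // for xtw = X2t * tau
  arma::vec z = y - offset;
  arma::vec b = beta0;
  arma::vec sigma2 = sigma20, nu = nu0;
  arma::vec r = z - X * b;

  arma::mat beta_out(p, nL, arma::fill::value(NA_REAL));
  arma::mat sigma2_out(G, nL, arma::fill::value(NA_REAL));
  arma::mat nu_out(G, nL, arma::fill::value(NA_REAL));
  arma::vec loglik_out(nL, arma::fill::value(NA_REAL));
  arma::vec penobj_out(nL, arma::fill::value(NA_REAL));
  arma::ivec iters_out(nL, arma::fill::zeros);
  LogicalVector conv_out(nL, false);
  arma::vec kkt_out(nL, arma::fill::value(NA_REAL));
  List traces(trace ? (int)nL : 0);
  int n_done = 0;

  arma::vec tau(n, arma::fill::ones);
  bool path_dead = false;

  // per-lambda warm starts (e.g. from a full-data path when fitting CV folds)
  const bool use_warm = beta_warm.isNotNull();
  arma::mat bw, s2w, nuw;
  if (use_warm) {
    bw = Rcpp::as<arma::mat>(beta_warm.get());
    s2w = Rcpp::as<arma::mat>(sigma2_warm.get());
    nuw = Rcpp::as<arma::mat>(nu_warm.get());
  }

  for (arma::uword L = 0; L < nL && !path_dead; ++L) {
    const double lambda = lambdas(L);
    if (use_warm && L < bw.n_cols && bw.col(L).is_finite()) {
      b = bw.col(L);
      sigma2 = arma::clamp(s2w.col(L), SIGMA2_FLOOR, arma::datum::inf);
      if (t_family) nu = arma::clamp(nuw.col(L), nu_lo, nu_hi);
      r = z - X * b;
    }
    bool converged = false;
    int iter = 0;
    double kkt_last = NA_REAL;
    std::vector<double> tr;  // per iteration: loglik, ||beta||_1, sigma2_prev(0)

    for (iter = 1; iter <= max_iter; ++iter) {
      arma::vec b_old = b, s2_old = sigma2, nu_old = nu;

      // E-step: posterior means of tau at the current theta. The lasso
      // weights additionally rescale each group by sigma2(0)/sigma2(g) so
      // that datasets contribute in likelihood proportion while the penalty
      // stays calibrated to the target group's scale.
      arma::vec w = tau;
      for (int g = 0; g < G; ++g) {
        const arma::uvec& idx = gidx[g];
        if (t_family) {
          arma::vec dg = arma::square(r.elem(idx)) / sigma2(g);
          tau.elem(idx) = (nu(g) + 1.0) / (nu(g) + dg);
        }
        w.elem(idx) = tau.elem(idx) * (sigma2(0) / sigma2(g));
      }

      // M-step (beta): weighted lasso, warm-started; the full activation
      // scan runs periodically, the other iterations polish the working set
      arma::vec xtw = X2t * w;
      bool grow = (iter == 1) || (iter % 3 == 0);
      kkt_last = cd_lasso(X, w, xtw, r, b, lambda, penalized,
                          cd_tol, cd_max_sweeps, grow);

      // M-step (sigma2) and CM-step (nu) per group
      for (int g = 0; g < G; ++g) {
        const arma::uvec& idx = gidx[g];
        const arma::vec rg = r.elem(idx);
        sigma2(g) = std::max(arma::dot(tau.elem(idx), arma::square(rg))
                             / idx.n_elem, SIGMA2_FLOOR);
        if (t_family && estimate_nu) {
          nu(g) = nu_cml(r, idx, sigma2(g), nu_lo, nu_hi);
        }
      }

      if (trace) {
        double ll = 0.0;
        for (int g = 0; g < G; ++g) {
          ll += group_loglik(r, gidx[g], sigma2(g), nu(g), t_family);
        }
        double pen = 0.0;
        for (arma::uword j = 0; j < p; ++j) if (penalized(j)) pen += std::abs(b(j));
        tr.push_back(ll);
        tr.push_back(pen);
        tr.push_back(s2_old(0));
      }

      double change = arma::accu(arma::abs(b - b_old))
        + arma::accu(arma::abs(sigma2 - s2_old)) + arma::accu(arma::abs(nu - nu_old));
      if (change < tol) {
        if (!grow) {
          // confirm against the full KKT scan before accepting convergence
          arma::vec b_pre = b;
          kkt_last = cd_lasso(X, w, xtw, r, b, lambda, penalized,
                              cd_tol, cd_max_sweeps, true);
          if (arma::accu(arma::abs(b - b_pre)) >= tol) continue;
        }
        converged = true;
        break;
      }
    }
    if (iter > max_iter) iter = max_iter;

    // certify the final iterate even when the cap was hit on a polish step
    if (kkt_last < 0) {
      arma::vec w = tau;
      for (int g = 0; g < G; ++g) {
        w.elem(gidx[g]) *= sigma2(0) / sigma2(g);
      }
      arma::vec xtw = X2t * w;
      kkt_last = cd_lasso(X, w, xtw, r, b, lambda, penalized,
                          cd_tol, cd_max_sweeps, true);
    }

    double ll = 0.0;
    for (int g = 0; g < G; ++g) {
      ll += group_loglik(r, gidx[g], sigma2(g), nu(g), t_family);
    }
    double pen = 0.0;
    arma::uword n_active = 0;
    for (arma::uword j = 0; j < p; ++j) {
      if (penalized(j)) pen += std::abs(b(j));
      if (b(j) != 0.0) ++n_active;
    }

    beta_out.col(L) = b;
    sigma2_out.col(L) = sigma2;
    nu_out.col(L) = nu;
    loglik_out(L) = ll;
    // penalized objective on the log-likelihood scale: the converged penalty
    // weight is lambda / sigma2 of the target group
    penobj_out(L) = ll - lambda / sigma2(0) * pen;
    iters_out(L) = iter;
    conv_out[L] = converged;
    kkt_out(L) = kkt_last;
    if (trace) {
      NumericMatrix tm(3, tr.size() / 3);
      std::copy(tr.begin(), tr.end(), tm.begin());
      NumericMatrix tmt = Rcpp::transpose(tm);
      colnames(tmt) = CharacterVector::create("loglik", "l1", "sigma2_prev");
      traces[L] = tmt;
    }
    ++n_done;

    // stop descending the path once the fit starts to interpolate
    if (sigma2.min() <= 1e-6 || n_active >= (arma::uword)(0.95 * n)) path_dead = true;
  }

  return List::create(
    _["beta"] = beta_out, _["sigma2"] = sigma2_out, _["nu"] = nu_out,
    _["loglik"] = loglik_out, _["penalized_obj"] = penobj_out,
    _["n_iter"] = iters_out, _["converged"] = conv_out,
    _["kkt_violation"] = kkt_out, _["n_fitted"] = n_done,
    _["trace"] = traces);
}

// Maximize the observed log-likelihood over (sigma2, nu) with the mean fixed,
// by EM/ECME on the same hierarchy (beta held constant => r fixed).
// [[Rcpp::export(name = ".profile_nuisance_cpp")]]
List profile_nuisance_cpp(const arma::vec& r, bool t_family,
                          double nu_lo, double nu_hi, bool estimate_nu,
                          double sigma2_init, double nu_init,
                          double tol, int max_iter) {
  const arma::uword n = r.n_elem;
  arma::uvec idx = arma::regspace<arma::uvec>(0, n - 1);
  double sigma2 = std::max(sigma2_init, SIGMA2_FLOOR), nu = nu_init;
  if (!t_family) {
    sigma2 = std::max(arma::dot(r, r) / n, SIGMA2_FLOOR);
    return List::create(_["sigma2"] = sigma2, _["nu"] = NA_REAL,
                        _["loglik"] = group_loglik(r, idx, sigma2, 1.0, false));
  }
  const arma::vec r2 = arma::square(r);
  for (int it = 0; it < max_iter; ++it) {
    arma::vec tau = (nu + 1.0) / (nu + r2 / sigma2);
    double s2_new = std::max(arma::dot(tau, r2) / n, SIGMA2_FLOOR);
    double nu_new = estimate_nu ? nu_cml(r, idx, s2_new, nu_lo, nu_hi) : nu;
    double change = std::abs(s2_new - sigma2) + std::abs(nu_new - nu);
    sigma2 = s2_new; nu = nu_new;
    if (change < tol) break;
  }
  return List::create(_["sigma2"] = sigma2, _["nu"] = nu,
                      _["loglik"] = group_loglik(r, idx, sigma2, nu, true));
}

// [[Rcpp::export(name = ".loglik_cpp")]]
double loglik_cpp(const arma::vec& r, double sigma2, double nu, bool t_family) {
  arma::uvec idx = arma::regspace<arma::uvec>(0, r.n_elem - 1);
  return group_loglik(r, idx, sigma2, nu, t_family);
}
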
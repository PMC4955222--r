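// Weighted Breslow partial-likelihood engine for competing-risks regression.
//
// All routines share one risk-set representation.  Subjects are passed sorted
// by ascending observed time.  A subject k contributes to the risk set at an
// event time t in one of two ways:
//   * "normal":   T_k >= t, weight 1 (both cause-specific and Fine-Gray);
//   * "extended": ext[k] == 1 and T_k < t, weight G(t-) / G(T_k-)
//     (Fine-Gray: subjects with a competing event stay at risk after their
//      event, down-weighted by the censoring survivor function G).
// For cause-specific models ext is all zero and the G vectors are all one.
// Ties are handled by the Breslow approximation: all events at a tied time
// see the same risk-set sums.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Walk state shared by the exported routines.  Removal from the normal set /
// insertion into the extended set happens once per subject, so a full pass is
// O(n * p) for p tracked columns.
struct RiskWalk {
  const arma::vec& time;
  const arma::ivec& d;
  const arma::ivec& ext;
  const arma::vec& gdenom;  // G(T_k-) for extended subjects, 1 otherwise
  const arma::vec& gminus;  // G(T_i-) at subject i's own time
  const arma::vec& a;       // exp(eta_k)
  arma::uword rm;           // next subject to drop from the normal set

  RiskWalk(const arma::vec& time_, const arma::ivec& d_, const arma::ivec& ext_,
           const arma::vec& gdenom_, const arma::vec& gminus_, const arma::vec& a_)
      : time(time_), d(d_), ext(ext_), gdenom(gdenom_), gminus(gminus_), a(a_), rm(0) {}
};

}  // namespace

// Partial log-likelihood at a given linear predictor.
// [[Rcpp::export]]
double cpp_pl_loglik(const arma::vec& time, const arma::ivec& d,
                     const arma::ivec& ext, const arma::vec& gdenom,
                     const arma::vec& gminus, const arma::vec& eta) {
  const arma::uword n = time.n_elem;
  arma::vec a = arma::exp(eta);
  double r0 = arma::accu(a), e0 = 0.0, ll = 0.0;
  arma::uword rm = 0;
  for (arma::uword i = 0; i < n; ++i) {
    while (time[rm] < time[i]) {
      r0 -= a[rm];
      if (ext[rm] == 1) e0 += a[rm] / gdenom[rm];
      ++rm;
    }
    if (d[i] == 1) {
      double s0 = r0 + gminus[i] * e0;
      ll += eta[i] - std::log(s0);
    }
  }
  return ll;
}

// Componentwise score U_j and Fisher information I_j for every candidate,
// from the feature-major (p x n) layout Xt so each subject's feature vector
// is contiguous.
static void score_info_t(const arma::vec& time, const arma::ivec& d,
                         const arma::ivec& ext, const arma::vec& gdenom,
                         const arma::vec& gminus, const arma::vec& eta,
                         const arma::mat& Xt, arma::vec& U, arma::vec& I,
                         double& ll) {
  const arma::uword n = time.n_elem, p = Xt.n_rows;
  arma::vec a = arma::exp(eta);
  double r0 = arma::accu(a), e0 = 0.0;
  arma::vec r1(p, arma::fill::zeros), r2(p, arma::fill::zeros);
  arma::vec e1(p, arma::fill::zeros), e2(p, arma::fill::zeros);
  for (arma::uword k = 0; k < n; ++k) {
    const double ak = a[k];
    const double* xk = Xt.colptr(k);
    double* r1p = r1.memptr();
    double* r2p = r2.memptr();
    for (arma::uword j = 0; j < p; ++j) {
      r1p[j] += ak * xk[j];
      r2p[j] += ak * xk[j] * xk[j];
    }
  }
  U.zeros(p);
  I.zeros(p);
  ll = 0.0;
  arma::uword rm = 0;
  for (arma::uword i = 0; i < n; ++i) {
    while (time[rm] < time[i]) {
      const double ak = a[rm];
      const double* xk = Xt.colptr(rm);
      const bool is_ext = ext[rm] == 1;
      const double vk = is_ext ? ak / gdenom[rm] : 0.0;
      double* r1p = r1.memptr();
      double* r2p = r2.memptr();
      double* e1p = e1.memptr();
      double* e2p = e2.memptr();
      for (arma::uword j = 0; j < p; ++j) {
        const double x = xk[j];
        r1p[j] -= ak * x;
        r2p[j] -= ak * x * x;
        if (is_ext) {
          e1p[j] += vk * x;
          e2p[j] += vk * x * x;
        }
      }
      r0 -= ak;
      if (is_ext) e0 += vk;
      ++rm;
    }
    if (d[i] == 1) {
      const double g = gminus[i];
      const double s0 = r0 + g * e0;
      const double* xi = Xt.colptr(i);
      const double* r1p = r1.memptr();
      const double* r2p = r2.memptr();
      const double* e1p = e1.memptr();
      const double* e2p = e2.memptr();
      double* Up = U.memptr();
      double* Ip = I.memptr();
      for (arma::uword j = 0; j < p; ++j) {
        const double s1 = (r1p[j] + g * e1p[j]) / s0;
        const double s2 = (r2p[j] + g * e2p[j]) / s0;
        Up[j] += xi[j] - s1;
        Ip[j] += s2 - s1 * s1;
      }
      ll += eta[i] - std::log(s0);
    }
  }
}

// [[Rcpp::export]]
List cpp_score_info(const arma::vec& time, const arma::ivec& d,
                    const arma::ivec& ext, const arma::vec& gdenom,
                    const arma::vec& gminus, const arma::vec& eta,
                    const arma::mat& X) {
  arma::vec U, I;
  double ll;
  arma::mat Xt = X.t();
  score_info_t(time, d, ext, gdenom, gminus, eta, Xt, U, I, ll);
  return List::create(_["U"] = U, _["I"] = I, _["loglik"] = ll);
}

// Multivariate score vector and observed information matrix for a small
// design Z (mandatory covariates / low-dimensional regression fits).
static void grad_hess(const arma::vec& time, const arma::ivec& d,
                      const arma::ivec& ext, const arma::vec& gdenom,
                      const arma::vec& gminus, const arma::vec& eta,
                      const arma::mat& Z, arma::vec& U, arma::mat& H,
                      double& ll) {
  const arma::uword n = time.n_elem, q = Z.n_cols;
  arma::vec a = arma::exp(eta);
  double r0 = arma::accu(a), e0 = 0.0;
  arma::vec r1 = Z.t() * a;
  arma::mat r2 = Z.t() * (Z.each_col() % a);
  arma::vec e1(q, arma::fill::zeros);
  arma::mat e2(q, q, arma::fill::zeros);
  U.zeros(q);
  H.zeros(q, q);
  ll = 0.0;
  arma::uword rm = 0;
  for (arma::uword i = 0; i < n; ++i) {
    while (time[rm] < time[i]) {
      const double ak = a[rm];
      arma::vec zk = Z.row(rm).t();
      r0 -= ak;
      r1 -= ak * zk;
      r2 -= ak * (zk * zk.t());
      if (ext[rm] == 1) {
        const double vk = ak / gdenom[rm];
        e0 += vk;
        e1 += vk * zk;
        e2 += vk * (zk * zk.t());
      }
      ++rm;
    }
    if (d[i] == 1) {
      const double g = gminus[i];
      const double s0 = r0 + g * e0;
      arma::vec s1 = (r1 + g * e1) / s0;
      arma::mat s2 = (r2 + g * e2) / s0;
      U += Z.row(i).t() - s1;
      H += s2 - s1 * s1.t();
      ll += eta[i] - std::log(s0);
    }
  }
}

// [[Rcpp::export]]
List cpp_grad_hess(const arma::vec& time, const arma::ivec& d,
                   const arma::ivec& ext, const arma::vec& gdenom,
                   const arma::vec& gminus, const arma::vec& eta,
                   const arma::mat& Z) {
  arma::vec U;
  arma::mat H;
  double ll;
  grad_hess(time, d, ext, gdenom, gminus, eta, Z, U, H, ll);
  return List::create(_["U"] = U, _["H"] = H, _["loglik"] = ll);
}

// Newton-Raphson maximizer of the (weighted) Breslow partial likelihood with
// step-halving.  offset carries contributions held fixed during the fit.
// [[Rcpp::export]]
List cpp_newton(const arma::vec& time, const arma::ivec& d,
                const arma::ivec& ext, const arma::vec& gdenom,
                const arma::vec& gminus, const arma::vec& offset,
                const arma::mat& Z, const int maxit, const double tol) {
  const arma::uword q = Z.n_cols;
  arma::vec beta(q, arma::fill::zeros), U;
  arma::mat H;
  double ll = 0.0;
  bool converged = false, singular = false;
  int iter = 0;
  if (arma::accu(d) == 0) {
    return List::create(_["beta"] = beta, _["loglik"] = 0.0,
                        _["imat"] = arma::mat(q, q, arma::fill::zeros),
                        _["converged"] = false, _["singular"] = true,
                        _["iter"] = 0);
  }
  arma::vec eta = offset + Z * beta;
  grad_hess(time, d, ext, gdenom, gminus, eta, Z, U, H, ll);
  for (iter = 1; iter <= maxit; ++iter) {
    arma::vec step;
    if (!arma::solve(step, H, U, arma::solve_opts::no_approx)) {
      singular = true;
      break;
    }
    double fac = 1.0, ll_new = -arma::datum::inf;
    arma::vec beta_new;
    for (int h = 0; h < 20; ++h) {
      beta_new = beta + fac * step;
      ll_new = cpp_pl_loglik(time, d, ext, gdenom, gminus, offset + Z * beta_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) break;
      fac *= 0.5;
    }
    double delta = std::fabs(ll_new - ll) / (std::fabs(ll) + 0.1);
    beta = beta_new;
    ll = ll_new;
    grad_hess(time, d, ext, gdenom, gminus, offset + Z * beta, Z, U, H, ll);
    if (delta < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["beta"] = beta, _["loglik"] = ll, _["imat"] = H,
                      _["converged"] = converged, _["singular"] = singular,
                      _["iter"] = iter);
}

// Componentwise likelihood-based boosting.  Each step updates the single
// candidate maximizing the penalized score statistic U_j^2 / (I_j + lambda)
// by the shrunken estimate U_j / (I_j + lambda), then refreshes the mandatory
// covariates by one Newton step with the candidate contribution as offset
// (mand_full_refit = true re-converges them instead).
// [[Rcpp::export]]
List cpp_boost(const arma::vec& time, const arma::ivec& d,
               const arma::ivec& ext, const arma::vec& gdenom,
               const arma::vec& gminus, const arma::vec& offset,
               const arma::mat& Z, const arma::mat& X, const int nsteps,
               const double lambda, const bool mand_full_refit) {
  const arma::uword q = Z.n_cols, p = X.n_cols;
  arma::vec beta_m(q, arma::fill::zeros), beta_c(p, arma::fill::zeros);
  arma::vec eta_cand = offset;  // offset + X * beta_c
  // initial unpenalized fit of the mandatory covariates
  if (q > 0) {
    List f0 = cpp_newton(time, d, ext, gdenom, gminus, eta_cand, Z, 50, 1e-9);
    beta_m = as<arma::vec>(f0["beta"]);
  }
  arma::mat mand_path(q, nsteps + 1);
  if (q > 0) mand_path.col(0) = beta_m;
  arma::vec eta = eta_cand + (q > 0 ? arma::vec(Z * beta_m) : arma::vec(time.n_elem, arma::fill::zeros));
  arma::vec ll_path(nsteps + 1);
  ll_path[0] = cpp_pl_loglik(time, d, ext, gdenom, gminus, eta);
  arma::ivec trace_feature(nsteps);
  arma::vec trace_delta(nsteps);
  arma::mat Xt = X.t();
  arma::vec U, I;
  double ll_si;
  for (int s = 0; s < nsteps; ++s) {
    score_info_t(time, d, ext, gdenom, gminus, eta, Xt, U, I, ll_si);
    if (!U.is_finite() || !I.is_finite()) {
      stop("non-finite score/information at boosting step %d", s + 1);
    }
    arma::vec crit = arma::square(U) / (I + lambda);
    arma::uword j = crit.index_max();  // first maximum: lowest index wins ties
    double delta = U[j] / (I[j] + lambda);
    beta_c[j] += delta;
    eta_cand += delta * X.col(j);
    eta += delta * X.col(j);
    trace_feature[s] = static_cast<int>(j) + 1;  // 1-based for R
    trace_delta[s] = delta;
    if (q > 0) {
      if (mand_full_refit) {
        List fm = cpp_newton(time, d, ext, gdenom, gminus, eta_cand, Z, 50, 1e-9);
        beta_m = as<arma::vec>(fm["beta"]);
      } else {
        arma::vec Um;
        arma::mat Hm;
        double llm;
        grad_hess(time, d, ext, gdenom, gminus, eta, Z, Um, Hm, llm);
        arma::vec step;
        if (arma::solve(step, Hm, Um, arma::solve_opts::no_approx)) {
          double fac = 1.0;
          for (int h = 0; h < 10; ++h) {
            double ll_try = cpp_pl_loglik(time, d, ext, gdenom, gminus,
                                          eta_cand + Z * (beta_m + fac * step));
            if (std::isfinite(ll_try) && ll_try >= llm - 1e-12) {
              beta_m += fac * step;
              break;
            }
            fac *= 0.5;
          }
        }
      }
      eta = eta_cand + Z * beta_m;
      mand_path.col(s + 1) = beta_m;
    }
    ll_path[s + 1] = cpp_pl_loglik(time, d, ext, gdenom, gminus, eta);
  }
  return List::create(_["beta_candidate"] = beta_c, _["beta_mandatory"] = beta_m,
                      _["trace_feature"] = trace_feature,
                      _["trace_delta"] = trace_delta,
                      _["mandatory_path"] = mand_path,
                      _["loglik_path"] = ll_path);
}

// Per-feature Wald p-values from fits of (mandatory covariates + one feature).
// Non-converged or singular fits report p = 1.
// [[Rcpp::export]]
List cpp_univariate_pvalues(const arma::vec& time, const arma::ivec& d,
                            const arma::ivec& ext, const arma::vec& gdenom,
                            const arma::vec& gminus, const arma::vec& offset,
                            const arma::mat& Z, const arma::mat& X,
                            const int maxit, const double tol) {
  const arma::uword p = X.n_cols, q = Z.n_cols;
  arma::vec pval(p, arma::fill::ones), coef(p, arma::fill::zeros);
  arma::ivec ok(p, arma::fill::zeros);
  arma::mat D(time.n_elem, q + 1);
  if (q > 0) D.cols(0, q - 1) = Z;
  for (arma::uword j = 0; j < p; ++j) {
    D.col(q) = X.col(j);
    List f = cpp_newton(time, d, ext, gdenom, gminus, offset, D, maxit, tol);
    bool conv = as<bool>(f["converged"]);
    if (!conv) continue;
    arma::mat H = as<arma::mat>(f["imat"]);
    arma::mat V;
    if (!arma::inv(V, H)) continue;
    double se = std::sqrt(V(q, q));
    if (!std::isfinite(se) || se <= 0) continue;
    arma::vec b = as<arma::vec>(f["beta"]);
    double z = b[q] / se;
    coef[j] = b[q];
    pval[j] = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
    ok[j] = 1;
  }
  return List::create(_["pvalue"] = pval, _["coef"] = coef, _["converged"] = ok);
}

// Breslow-type baseline hazard increments d / S0(t) at unique event times.
// [[Rcpp::export]]
List cpp_breslow_baseline(const arma::vec& time, const arma::ivec& d,
                          const arma::ivec& ext, const arma::vec& gdenom,
                          const arma::vec& gminus, const arma::vec& eta) {
  const arma::uword n = time.n_elem;
  arma::vec a = arma::exp(eta);
  double r0 = arma::accu(a), e0 = 0.0;
  arma::uword rm = 0;
  std::vector<double> times, dhaz;
  for (arma::uword i = 0; i < n; ++i) {
    while (time[rm] < time[i]) {
      r0 -= a[rm];
      if (ext[rm] == 1) e0 += a[rm] / gdenom[rm];
      ++rm;
    }
    if (d[i] == 1) {
      double s0 = r0 + gminus[i] * e0;
      if (!times.empty() && times.back() == time[i]) {
        dhaz.back() += 1.0 / s0;
      } else {
        times.push_back(time[i]);
        dhaz.push_back(1.0 / s0);
      }
    }
  }
  return List::create(_["time"] = times, _["dhaz"] = dhaz);
}
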
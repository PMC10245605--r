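// Newton-Raphson Cox partial-likelihood fitter with Efron tie handling.
// Built for the Monte-Carlo inner loop: many small fits (p <= ~10) where
// per-call overhead matters, so the likelihood pass works on flat
// preallocated buffers with explicit loops over the (small) number of
// covariates.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

// One pass over time-sorted data: log partial likelihood, score and
// observed information at `beta`. `ord` sorts time ascending; the sweep
// runs descending so the risk set accumulates. grad/info may be NULL when
// only the log likelihood is needed.
double cox_pass(const double *beta, const double *time, const int *status,
                const double *X /* n x p, column-major */, int n, int p,
                const int *ord, double *grad, double *info,
                std::vector<double> &work) {
  double loglik = 0.0;
  if (grad) std::fill(grad, grad + p, 0.0);
  if (info) std::fill(info, info + p * p, 0.0);

  // workspace layout: eta(n), w(n), S1(p), S2(p*p), S1D(p), S2D(p*p), a(p)
  work.assign(2 * n + 3 * p + 2 * p * p, 0.0);
  double *eta = work.data();
  double *w = eta + n;
  double *S1 = w + n;
  double *S2 = S1 + p;
  double *S1D = S2 + p * p;
  double *S2D = S1D + p;
  double *a = S2D + p * p;

  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int k = 0; k < p; ++k) e += X[i + k * n] * beta[k];
    if (e > 700.0) e = 700.0;
    if (e < -700.0) e = -700.0;
    eta[i] = e;
    w[i] = std::exp(e);
  }

  double S0 = 0.0;
  int j = n; // position in ord, descending time
  while (j > 0) {
    int k0 = j;
    const double t = time[ord[j - 1]];
    while (k0 > 0 && time[ord[k0 - 1]] == t) --k0;

    double S0D = 0.0, sum_eta_D = 0.0;
    std::fill(S1D, S1D + p, 0.0);
    std::fill(S2D, S2D + p * p, 0.0);
    int d = 0;
    for (int m = k0; m < j; ++m) {
      const int i = ord[m];
      const double wi = w[i];
      S0 += wi;
      for (int k = 0; k < p; ++k) {
        const double xk = X[i + k * n];
        S1[k] += wi * xk;
        for (int l = k; l < p; ++l) S2[k + l * p] += wi * xk * X[i + l * n];
      }
      if (status[i] == 1) {
        ++d;
        S0D += wi;
        sum_eta_D += eta[i];
        for (int k = 0; k < p; ++k) {
          const double xk = X[i + k * n];
          S1D[k] += wi * xk;
          if (grad) grad[k] += xk;
          for (int l = k; l < p; ++l)
            S2D[k + l * p] += wi * xk * X[i + l * n];
        }
      }
    }

    if (d > 0) {
      loglik += sum_eta_D;
      for (int r = 0; r < d; ++r) {
        const double f = static_cast<double>(r) / d;
        const double den = S0 - f * S0D;
        loglik -= std::log(den);
        if (grad) {
          for (int k = 0; k < p; ++k) {
            a[k] = (S1[k] - f * S1D[k]) / den;
            grad[k] -= a[k];
          }
          for (int k = 0; k < p; ++k)
            for (int l = k; l < p; ++l)
              info[k + l * p] +=
                  (S2[k + l * p] - f * S2D[k + l * p]) / den - a[k] * a[l];
        }
      }
    }
    j = k0;
  }
  if (info) // mirror the upper triangle
    for (int k = 0; k < p; ++k)
      for (int l = 0; l < k; ++l) info[k + l * p] = info[l + k * p];
  return loglik;
}

} // namespace

// [[Rcpp::export(name = ".cox_fit_cpp")]]
List cox_fit_cpp(NumericVector time, IntegerVector status, NumericMatrix Xr,
                 int iter_max = 30, double eps = 1e-9) {
  const int n = time.size(), p = Xr.ncol();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  const double *tp = time.begin();
  std::stable_sort(ord.begin(), ord.end(),
                   [tp](int a, int b) { return tp[a] < tp[b]; });

  int nevent = 0;
  for (int i = 0; i < n; ++i) nevent += status[i];

  std::vector<double> work;
  arma::vec beta = arma::zeros(p);
  arma::vec grad(p);
  arma::mat info(p, p);
  double loglik =
      cox_pass(beta.memptr(), tp, status.begin(), Xr.begin(), n, p,
               ord.data(), p ? grad.memptr() : nullptr,
               p ? info.memptr() : nullptr, work);
  const double loglik_null = loglik;
  const arma::vec score0 = grad;

  bool converged = (p == 0);
  int iter = 0;
  if (p > 0 && nevent > 0) {
    for (iter = 1; iter <= iter_max; ++iter) {
      arma::vec step;
      const bool ok = arma::solve(step, arma::symmatu(info), grad,
                                  arma::solve_opts::likely_sympd +
                                      arma::solve_opts::no_approx);
      if (!ok) break;
      arma::vec cand = beta + step;
      double lnew = cox_pass(cand.memptr(), tp, status.begin(), Xr.begin(),
                             n, p, ord.data(), nullptr, nullptr, work);
      int halves = 0;
      while ((!std::isfinite(lnew) || lnew < loglik) && halves < 8) {
        step *= 0.5;
        cand = beta + step;
        lnew = cox_pass(cand.memptr(), tp, status.begin(), Xr.begin(), n, p,
                        ord.data(), nullptr, nullptr, work);
        ++halves;
      }
      const double change = lnew - loglik;
      beta = cand;
      loglik = cox_pass(beta.memptr(), tp, status.begin(), Xr.begin(), n, p,
                        ord.data(), grad.memptr(), info.memptr(), work);
      if (std::isfinite(change) && std::fabs(change) < eps &&
          arma::abs(grad).max() < 1e-5) {
        converged = true;
        break;
      }
      if (arma::abs(beta).max() > 25.0) break; // monotone likelihood guard
    }
  }

  arma::mat var(p, p, arma::fill::value(NA_REAL));
  arma::vec se(p, arma::fill::value(NA_REAL));
  if (p > 0 && nevent > 0) {
    arma::mat vtmp;
    if (arma::inv_sympd(vtmp, arma::symmatu(info))) {
      var = vtmp;
      se = arma::sqrt(vtmp.diag());
    }
  }

  return List::create(
      _["coef"] = beta, _["se"] = se, _["var"] = var, _["loglik"] = loglik,
      _["loglik_null"] = loglik_null, _["score0"] = score0, _["iter"] = iter,
      _["converged"] = converged, _["n"] = n, _["nevent"] = nevent);
}
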
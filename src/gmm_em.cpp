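#include <Rcpp.h>
using namespace Rcpp;

// EM for a univariate Gaussian mixture, unbinned likelihood (one term per
// observation, never a histogram fit). Component densities are computed
// directly with precomputed coefficients; in efficiency units (x in ~[0,1],
// sigma floored well above machine scale) the mixture density cannot
// underflow except for extreme outliers, which are floored.

static const double SQRT2PI = 2.5066282746310002;
static const double DENS_FLOOR = 1e-300;

// [[Rcpp::export]]
List em_gmm_cpp(NumericVector x, NumericVector mu0, NumericVector sigma0,
                NumericVector w0, int max_iter, double tol,
                double sigma_floor) {
  const int n = x.size();
  const int k = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sg(sigma0.begin(), sigma0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> coef(k), inv2s2(k);
  std::vector<double> resp(static_cast<size_t>(n) * k);
  std::vector<double> nk(k), sx(k), sv(k);

  double ll = -std::numeric_limits<double>::infinity();
  double ll_old = ll;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    for (int j = 0; j < k; ++j) {
      coef[j] = w[j] / (sg[j] * SQRT2PI);
      inv2s2[j] = 0.5 / (sg[j] * sg[j]);
    }
    // E step
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      double *r = &resp[static_cast<size_t>(i) * k];
      for (int j = 0; j < k; ++j) {
        double d = x[i] - mu[j];
        double dens = coef[j] * std::exp(-d * d * inv2s2[j]);
        r[j] = dens;
        tot += dens;
      }
      if (tot < DENS_FLOOR) tot = DENS_FLOOR;
      ll += std::log(tot);
      double inv = 1.0 / tot;
      for (int j = 0; j < k; ++j) r[j] *= inv;
    }
    if (iter > 0 && std::fabs(ll - ll_old) / n < tol) {
      converged = true;
      break;
    }
    ll_old = ll;
    // M step
    std::fill(nk.begin(), nk.end(), 0.0);
    std::fill(sx.begin(), sx.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double *r = &resp[static_cast<size_t>(i) * k];
      for (int j = 0; j < k; ++j) {
        nk[j] += r[j];
        sx[j] += r[j] * x[i];
      }
    }
    for (int j = 0; j < k; ++j) {
      if (nk[j] <= 0) nk[j] = DENS_FLOOR;
      mu[j] = sx[j] / nk[j];
    }
    std::fill(sv.begin(), sv.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double *r = &resp[static_cast<size_t>(i) * k];
      for (int j = 0; j < k; ++j) {
        double d = x[i] - mu[j];
        sv[j] += r[j] * d * d;
      }
    }
    for (int j = 0; j < k; ++j) {
      sg[j] = std::max(std::sqrt(sv[j] / nk[j]), sigma_floor);
      w[j] = nk[j] / n;
    }
  }

  return List::create(_["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["sigma"] = NumericVector(sg.begin(), sg.end()),
                      _["w"] = NumericVector(w.begin(), w.end()),
                      _["loglik"] = ll, _["iterations"] = iter,
                      _["converged"] = converged);
}

// Log-likelihood of data under fixed mixture parameters.
// [[Rcpp::export]]
double gmm_loglik_cpp(NumericVector x, NumericVector mu, NumericVector sigma,
                      NumericVector w) {
  const int n = x.size(), k = mu.size();
  std::vector<double> coef(k), inv2s2(k);
  for (int j = 0; j < k; ++j) {
    coef[j] = w[j] / (sigma[j] * SQRT2PI);
    inv2s2[j] = 0.5 / (sigma[j] * sigma[j]);
  }
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < k; ++j) {
      double d = x[i] - mu[j];
      tot += coef[j] * std::exp(-d * d * inv2s2[j]);
    }
    ll += std::log(std::max(tot, DENS_FLOOR));
  }
  return ll;
}
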
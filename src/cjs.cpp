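#include <Rcpp.h>
using namespace Rcpp;

// Exact CJS log-likelihood, conditioning on first capture, latent alive/dead
// states summed out by the forward recursion.
//
// det  : n x T detection matrix (0/1)
// first: 0-based occasion of first capture/release per individual
// phi  : n x (T-1) per-individual, per-interval survival probabilities
// p    : length-T resighting probability per occasion (shared across birds)
//
// An individual first caught at the final occasion contributes 0 (likelihood
// 1): the CJS model conditions on first capture.
// [[Rcpp::export]]
double cjs_loglik_cpp(const IntegerMatrix& det, const IntegerVector& first,
                      const NumericMatrix& phi, const NumericVector& p) {
  const int n = det.nrow(), T = det.ncol();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    int f = first[i];
    double wa = 1.0, wd = 0.0;  // P(data so far, alive) / (..., dead)
    for (int t = f; t < T - 1; ++t) {
      const int y = det(i, t + 1);
      const double ph = phi(i, t);
      const double nwa = wa * ph * (y ? p[t + 1] : 1.0 - p[t + 1]);
      const double nwd = y ? 0.0 : wa * (1.0 - ph) + wd;
      wa = nwa;
      wd = nwd;
    }
    const double tot = wa + wd;
    if (tot <= 0.0) return R_NegInf;
    ll += std::log(tot);
  }
  return ll;
}

// Posterior P(alive at occasion t | detection history, parameters) for each
// individual, by the forward-backward algorithm.  Occasions before first
// capture get 0 (the bird is not yet part of the marked population).
// [[Rcpp::export]]
NumericMatrix cjs_alive_marginals_cpp(const IntegerMatrix& det,
                                      const IntegerVector& first,
                                      const NumericMatrix& phi,
                                      const NumericVector& p) {
  const int n = det.nrow(), T = det.ncol();
  NumericMatrix out(n, T);
  std::vector<double> fa(T), fd(T), ba(T), bd(T);
  for (int i = 0; i < n; ++i) {
    const int f = first[i];
    for (int t = 0; t < T; ++t) {
      fa[t] = fd[t] = 0.0;
      ba[t] = bd[t] = 1.0;
    }
    fa[f] = 1.0;
    for (int t = f; t < T - 1; ++t) {
      const int y = det(i, t + 1);
      const double obs_a = y ? p[t + 1] : 1.0 - p[t + 1];
      const double obs_d = y ? 0.0 : 1.0;
      fa[t + 1] = fa[t] * phi(i, t) * obs_a;
      fd[t + 1] = (fa[t] * (1.0 - phi(i, t)) + fd[t]) * obs_d;
    }
    for (int t = T - 2; t >= f; --t) {
      const int y = det(i, t + 1);
      const double obs_a = y ? p[t + 1] : 1.0 - p[t + 1];
      const double obs_d = y ? 0.0 : 1.0;
      ba[t] = phi(i, t) * obs_a * ba[t + 1] +
              (1.0 - phi(i, t)) * obs_d * bd[t + 1];
      bd[t] = obs_d * bd[t + 1];
    }
    for (int t = f; t < T; ++t) {
      const double num = fa[t] * ba[t];
      const double den = num + fd[t] * bd[t];
      out(i, t) = den > 0.0 ? num / den : 0.0;
    }
  }
  return out;
}
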
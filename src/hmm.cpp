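#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward EM for a Gaussian-emission HMM on one trace.
// Emission sd is floored so that noiseless traces stay numerically sane.

static inline double dnorm_one(double y, double mu, double sd) {
  double z = (y - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// [[Rcpp::export]]
List baum_welch_cpp(NumericVector y, NumericVector mu0, NumericVector sigma0,
                    NumericMatrix trans0, NumericVector pi0,
                    int max_iter, double tol, double sigma_floor) {
  const int T = y.size();
  const int K = mu0.size();

  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sigma(sigma0.begin(), sigma0.end());
  std::vector<double> A(K * K);
  std::vector<double> pi(pi0.begin(), pi0.end());
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A[i * K + j] = trans0(i, j);
  for (int k = 0; k < K; ++k)
    if (sigma[k] < sigma_floor) sigma[k] = sigma_floor;

  std::vector<double> alpha(T * K), beta(T * K), gamma(T * K), b(T * K);
  std::vector<double> scale(T);
  std::vector<double> loglik_trace;
  double loglik = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // emission densities
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k) b[t * K + k] = dnorm_one(y[t], mu[k], sigma[k]);

    // forward (scaled)
    double ll = 0.0;
    for (int k = 0; k < K; ++k) alpha[k] = pi[k] * b[k];
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += alpha[k];
    if (s <= 0) s = 1e-300;
    scale[0] = s;
    for (int k = 0; k < K; ++k) alpha[k] /= s;
    ll += std::log(s);
    for (int t = 1; t < T; ++t) {
      s = 0.0;
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        for (int i = 0; i < K; ++i) acc += alpha[(t - 1) * K + i] * A[i * K + j];
        double v = acc * b[t * K + j];
        alpha[t * K + j] = v;
        s += v;
      }
      if (s <= 0) s = 1e-300;
      scale[t] = s;
      for (int j = 0; j < K; ++j) alpha[t * K + j] /= s;
      ll += std::log(s);
    }

    // backward (scaled)
    for (int k = 0; k < K; ++k) beta[(T - 1) * K + k] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int i = 0; i < K; ++i) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j)
          acc += A[i * K + j] * b[(t + 1) * K + j] * beta[(t + 1) * K + j];
        beta[t * K + i] = acc / scale[t + 1];
      }
    }

    // gamma
    for (int t = 0; t < T; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) {
        gamma[t * K + k] = alpha[t * K + k] * beta[t * K + k];
        g += gamma[t * K + k];
      }
      if (g <= 0) g = 1e-300;
      for (int k = 0; k < K; ++k) gamma[t * K + k] /= g;
    }

    loglik_trace.push_back(ll);
    if (iter > 0 && std::fabs(ll - loglik) < tol * (std::fabs(loglik) + 1.0)) {
      loglik = ll;
      converged = true;
      break;
    }
    loglik = ll;

    // M-step: transitions via xi sums
    if (K > 1) {
      std::vector<double> num(K * K, 0.0);
      for (int t = 0; t < T - 1; ++t) {
        for (int i = 0; i < K; ++i) {
          double ai = alpha[t * K + i];
          if (ai == 0) continue;
          for (int j = 0; j < K; ++j) {
            num[i * K + j] += ai * A[i * K + j] * b[(t + 1) * K + j] *
                              beta[(t + 1) * K + j] / scale[t + 1];
          }
        }
      }
      for (int i = 0; i < K; ++i) {
        double rs = 0.0;
        for (int j = 0; j < K; ++j) rs += num[i * K + j];
        if (rs > 0)
          for (int j = 0; j < K; ++j) A[i * K + j] = num[i * K + j] / rs;
      }
    }

    // initial distribution
    for (int k = 0; k < K; ++k) pi[k] = gamma[k];

    // emissions
    for (int k = 0; k < K; ++k) {
      double w = 0.0, wy = 0.0;
      for (int t = 0; t < T; ++t) {
        w += gamma[t * K + k];
        wy += gamma[t * K + k] * y[t];
      }
      if (w > 0) {
        double m = wy / w, wss = 0.0;
        for (int t = 0; t < T; ++t) {
          double d = y[t] - m;
          wss += gamma[t * K + k] * d * d;
        }
        mu[k] = m;
        sigma[k] = std::sqrt(wss / w);
        if (sigma[k] < sigma_floor) sigma[k] = sigma_floor;
      }
    }
  }

  NumericVector occ(K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) occ[k] += gamma[t * K + k] / T;

  NumericMatrix Aout(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) Aout(i, j) = A[i * K + j];

  return List::create(
      _["mu"] = NumericVector(mu.begin(), mu.end()),
      _["sigma"] = NumericVector(sigma.begin(), sigma.end()),
      _["trans"] = Aout, _["init"] = NumericVector(pi.begin(), pi.end()),
      _["loglik"] = loglik, _["loglik_trace"] = NumericVector(loglik_trace.begin(), loglik_trace.end()),
      _["occupancy"] = occ, _["converged"] = converged, _["iterations"] = iter + 1);
}

// [[Rcpp::export]]
List viterbi_cpp(NumericVector y, NumericVector mu, NumericVector sigma,
                 NumericMatrix trans, NumericVector pi) {
  const int T = y.size();
  const int K = mu.size();
  std::vector<double> delta(T * K);
  std::vector<int> psi(T * K);
  const double NEG = -1e300;

  for (int k = 0; k < K; ++k) {
    double lp = pi[k] > 0 ? std::log(pi[k]) : NEG;
    double d = dnorm_one(y[0], mu[k], sigma[k]);
    delta[k] = lp + (d > 0 ? std::log(d) : NEG);
  }
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = NEG;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double la = trans(i, j) > 0 ? std::log(trans(i, j)) : NEG;
        double v = delta[(t - 1) * K + i] + la;
        if (v > best) { best = v; arg = i; }
      }
      double d = dnorm_one(y[t], mu[j], sigma[j]);
      delta[t * K + j] = best + (d > 0 ? std::log(d) : NEG);
      psi[t * K + j] = arg;
    }
  }
  IntegerVector path(T);
  double best = NEG;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta[(T - 1) * K + k] > best) { best = delta[(T - 1) * K + k]; arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi[(t + 1) * K + arg];
    path[t] = arg + 1;
  }
  return List::create(_["path"] = path, _["logprob"] = best);
}
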
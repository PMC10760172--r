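#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// L1-penalized maximum-entropy fit by cyclic coordinate ascent.
//
// Objective (penalized training gain, relative to the uniform background
// distribution):
//   G(lambda) = mean_presence(eta) - log(mean_background(exp(eta)))
//               - sum_j beta_j * |lambda_j|
// Each coordinate takes a Newton step on the smooth part, soft-thresholded
// for the L1 penalty, with step halving so the penalized gain never
// decreases.  The trace records, per accepted update, the feature index and
// the gain increment; percent-contribution accounting consumes it.

// [[Rcpp::export]]
List cpp_maxent_fit(NumericMatrix X, IntegerVector presence_rows,
                    IntegerVector background_rows, NumericVector beta_j,
                    int max_iter, double tolerance) {
  const int J = X.ncol();
  const int np = presence_rows.size();
  const int nb = background_rows.size();

  // presence feature means
  std::vector<double> fbar(J, 0.0);
  for (int j = 0; j < J; ++j) {
    double s = 0.0;
    for (int k = 0; k < np; ++k) s += X(presence_rows[k] - 1, j);
    fbar[j] = s / (double)np;
  }

  std::vector<double> lambda(J, 0.0);
  std::vector<double> eta_b(nb, 0.0);

  double etap_bar = 0.0;       // mean presence linear predictor
  double pen = 0.0;            // L1 penalty
  double gain = 0.0;           // current penalized gain

  std::vector<int> trace_feature;
  std::vector<double> trace_gain, trace_delta;
  std::vector<double> w(nb);

  bool converged = false;
  int cycles = 0;
  for (int it = 0; it < max_iter; ++it) {
    double gain_start = gain;
    for (int j = 0; j < J; ++j) {
      // background weights q (unnormalized, max-shifted)
      double m = eta_b[0];
      for (int i = 1; i < nb; ++i) if (eta_b[i] > m) m = eta_b[i];
      double S = 0.0;
      for (int i = 0; i < nb; ++i) { w[i] = std::exp(eta_b[i] - m); S += w[i]; }
      double Ef = 0.0, Ef2 = 0.0;
      for (int i = 0; i < nb; ++i) {
        double f = X(background_rows[i] - 1, j);
        Ef += w[i] * f;
        Ef2 += w[i] * f * f;
      }
      Ef /= S; Ef2 /= S;
      double grad = fbar[j] - Ef;
      double curv = Ef2 - Ef * Ef;
      if (curv < 1e-12) {
        // (near-)constant feature under q: only the penalty can move it
        if (beta_j[j] == 0.0 || std::fabs(grad) <= beta_j[j]) continue;
        curv = 1e-12;
      }
      double u = lambda[j] + grad / curv;
      double lam_new = 0.0;
      double t = beta_j[j] / curv;
      if (u > t) lam_new = u - t;
      else if (u < -t) lam_new = u + t;
      double delta = lam_new - lambda[j];
      if (std::fabs(delta) < 1e-14) continue;
      // step halving on the true penalized gain
      bool accepted = false;
      for (int h = 0; h < 30; ++h) {
        double lam_try = lambda[j] + delta;
        double pen_try = pen - beta_j[j] * std::fabs(lambda[j])
                             + beta_j[j] * std::fabs(lam_try);
        double mtry = eta_b[0] + delta * X(background_rows[0] - 1, j);
        std::vector<double> tmp(nb);
        for (int i = 0; i < nb; ++i) {
          tmp[i] = eta_b[i] + delta * X(background_rows[i] - 1, j);
          if (tmp[i] > mtry) mtry = tmp[i];
        }
        double s2 = 0.0;
        for (int i = 0; i < nb; ++i) s2 += std::exp(tmp[i] - mtry);
        double lme_try = mtry + std::log(s2 / (double)nb);
        double etap_try = etap_bar + delta * fbar[j];
        double gain_try = etap_try - lme_try - pen_try;
        if (gain_try >= gain - 1e-12) {
          lambda[j] = lam_try;
          eta_b.swap(tmp);
          etap_bar = etap_try;
          pen = pen_try;
          if (gain_try > gain) {
            trace_feature.push_back(j + 1);
            trace_gain.push_back(gain_try);
            trace_delta.push_back(gain_try - gain);
          }
          gain = gain_try;
          accepted = true;
          break;
        }
        delta *= 0.5;
      }
      (void)accepted;
    }
    cycles = it + 1;
    if (gain - gain_start < tolerance) { converged = true; break; }
  }

  // final background distribution: entropy and absolute log Z
  double m = eta_b[0];
  for (int i = 1; i < nb; ++i) if (eta_b[i] > m) m = eta_b[i];
  double S = 0.0;
  for (int i = 0; i < nb; ++i) { w[i] = std::exp(eta_b[i] - m); S += w[i]; }
  double entropy = 0.0;
  for (int i = 0; i < nb; ++i) {
    double q = w[i] / S;
    if (q > 0) entropy -= q * std::log(q);
  }
  double logZ = m + std::log(S);  // log sum_background exp(eta)

  return List::create(
    _["lambda"] = NumericVector(lambda.begin(), lambda.end()),
    _["gain"] = gain,
    _["logZ"] = logZ,
    _["entropy"] = entropy,
    _["converged"] = converged,
    _["n_cycles"] = cycles,
    _["trace_feature"] = IntegerVector(trace_feature.begin(), trace_feature.end()),
    _["trace_gain"] = NumericVector(trace_gain.begin(), trace_gain.end()),
    _["trace_delta"] = NumericVector(trace_delta.begin(), trace_delta.end()));
}
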
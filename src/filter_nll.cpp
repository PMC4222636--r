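#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Negative log-likelihood of one block of prediction-trial responses under
// the DP-KF with the local (hard MAP assignment) approximation. Mirrors the
// R implementation in R/filter.R step for step; agreement is enforced by a
// unit test. pred_rule: 0 = prev (filtered state estimate of the previously
// active mode), 1 = CRP-prior mixture mean, 2 = MAP-prior mode.
// [[Rcpp::export]]
double cpp_block_nll(NumericMatrix obs, NumericMatrix resp,
                     double alpha, double beta,
                     NumericVector q, NumericVector r, NumericVector v,
                     double lambda, NumericVector m0, NumericVector c,
                     int pred_rule, bool include_t1) {
  const int T = obs.nrow(), D = obs.ncol();
  const double LOG2PI = std::log(2.0 * M_PI);

  std::vector<double> mean, var;     // K x D, row-major
  std::vector<double> count;
  std::vector<int> last;
  int zprev = -1;
  double nll = 0.0;

  std::vector<double> pred(D), predm, predv, logpost;

  for (int t = 0; t < T; ++t) {
    const int K = (int)count.size();

    // ---- behavioural prediction of y_t ----
    if (K == 0) {
      for (int d = 0; d < D; ++d) pred[d] = m0[d];
    } else if (pred_rule == 0) {
      double lam = std::pow(lambda, (t + 1) - last[zprev]);
      for (int d = 0; d < D; ++d) pred[d] = lam * mean[zprev * D + d];
    } else {
      // CRP prior weights
      double wsum = alpha;
      std::vector<double> w(K + 1);
      for (int k = 0; k < K; ++k) {
        w[k] = count[k] + (k == zprev ? beta : 0.0);
        wsum += w[k];
      }
      w[K] = alpha;
      if (pred_rule == 1) {
        for (int d = 0; d < D; ++d) pred[d] = w[K] / wsum * m0[d];
        for (int k = 0; k < K; ++k) {
          double lam = std::pow(lambda, (t + 1) - last[k]);
          for (int d = 0; d < D; ++d)
            pred[d] += w[k] / wsum * lam * mean[k * D + d];
        }
      } else {
        int best = 0;
        for (int k = 1; k < K; ++k) if (w[k] > w[best]) best = k;
        if (w[K] > w[best] + 1e-15 * wsum) {
          for (int d = 0; d < D; ++d) pred[d] = m0[d];
        } else {
          double lam = std::pow(lambda, (t + 1) - last[best]);
          for (int d = 0; d < D; ++d) pred[d] = lam * mean[best * D + d];
        }
      }
    }

    if (include_t1 || t > 0) {
      for (int d = 0; d < D; ++d) {
        double e = resp(t, d) - pred[d];
        nll += 0.5 * (LOG2PI + std::log(v[d])) + 0.5 * e * e / v[d];
      }
    }

    // ---- mode posterior (log space) and MAP assignment ----
    predm.assign((K + 1) * D, 0.0);
    predv.assign((K + 1) * D, 0.0);
    logpost.assign(K + 1, 0.0);
    double wsum = alpha;
    for (int k = 0; k < K; ++k)
      wsum += count[k] + (k == zprev ? beta : 0.0);
    for (int k = 0; k <= K; ++k) {
      double prior;
      if (K == 0) {
        prior = 1.0;  // first draw: new mode certain
      } else {
        double w = (k < K) ? count[k] + (k == zprev ? beta : 0.0) : alpha;
        prior = w / wsum;
      }
      double ll = 0.0;
      for (int d = 0; d < D; ++d) {
        double pm, pv;
        if (k < K) {
          int delta = (t + 1) - last[k];
          double lam = std::pow(lambda, delta);
          pm = lam * mean[k * D + d];
          pv = lam * lam * var[k * D + d] + delta * q[d];
        } else {
          pm = m0[d];
          pv = c[d];
        }
        predm[k * D + d] = pm;
        predv[k * D + d] = pv;
        double s = pv + r[d];
        double e = obs(t, d) - pm;
        ll += -0.5 * (LOG2PI + std::log(s)) - 0.5 * e * e / s;
      }
      logpost[k] = (prior > 0.0 ? std::log(prior) : R_NegInf) + ll;
    }
    int zt = 0;
    for (int k = 1; k < K; ++k) if (logpost[k] > logpost[zt]) zt = k;
    if (K > 0 && logpost[K] > logpost[zt]) zt = K;  // strict: existing wins ties

    // ---- update the assigned mode only ----
    if (zt == K) {
      mean.resize((K + 1) * D);
      var.resize((K + 1) * D);
      count.push_back(0.0);
      last.push_back(0);
    }
    for (int d = 0; d < D; ++d) {
      double pm = predm[zt * D + d], pv = predv[zt * D + d];
      double eta = pv / (pv + r[d]);
      mean[zt * D + d] = pm + eta * (obs(t, d) - pm);
      var[zt * D + d] = (1.0 - eta) * pv;
    }
    count[zt] += 1.0;
    last[zt] = t + 1;
    zprev = zt;
  }
  return nll;
}
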
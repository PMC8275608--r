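#include <Rcpp.h>
using namespace Rcpp;

// Sequential recursions for the two-state HMM. Inputs are prepared in R:
// per-observation log emission densities (0 for missing steps, i.e. unit
// emission), per-observation off-diagonal transition probabilities, and an
// integer burst key; a new burst starts wherever the key changes. The first
// observation of each burst is weighted by the stationary distribution of
// the transition matrix evaluated at its own covariates.

// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix logdens, NumericVector g12,
                       NumericVector g21, IntegerVector burst) {
  int n = logdens.nrow();
  double ll = 0.0, w1 = 0.0, w2 = 0.0;
  for (int t = 0; t < n; ++t) {
    double p1, p2;
    if (t == 0 || burst[t] != burst[t - 1]) {
      double s = g12[t] + g21[t];
      if (s <= 0.0) return R_NegInf;
      p1 = g21[t] / s;
      p2 = g12[t] / s;
    } else {
      p1 = w1 * (1.0 - g12[t]) + w2 * g21[t];
      p2 = w1 * g12[t] + w2 * (1.0 - g21[t]);
    }
    double l1 = logdens(t, 0), l2 = logdens(t, 1);
    double m = (l1 > l2) ? l1 : l2;
    if (!R_finite(m)) return R_NegInf;
    double a1 = p1 * std::exp(l1 - m);
    double a2 = p2 * std::exp(l2 - m);
    double c = a1 + a2;
    if (!(c > 0.0) || !R_finite(c)) return R_NegInf;
    ll += std::log(c) + m;
    w1 = a1 / c;
    w2 = a2 / c;
  }
  return ll;
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logdens, NumericVector g12,
                              NumericVector g21, IntegerVector burst) {
  int n = logdens.nrow();
  IntegerVector path(n);
  std::vector<double> d1(n), d2(n);
  std::vector<int> b1(n), b2(n);
  for (int t = 0; t < n; ++t) {
    if (t == 0 || burst[t] != burst[t - 1]) {
      double s = g12[t] + g21[t];
      d1[t] = std::log(g21[t] / s) + logdens(t, 0);
      d2[t] = std::log(g12[t] / s) + logdens(t, 1);
      b1[t] = 0; b2[t] = 0;
    } else {
      // candidate scores into state 1 and 2; ties keep the lower index
      double v11 = d1[t - 1] + std::log(1.0 - g12[t]);
      double v21 = d2[t - 1] + std::log(g21[t]);
      if (v21 > v11) { d1[t] = v21; b1[t] = 2; } else { d1[t] = v11; b1[t] = 1; }
      double v12 = d1[t - 1] + std::log(g12[t]);
      double v22 = d2[t - 1] + std::log(1.0 - g21[t]);
      if (v22 > v12) { d2[t] = v22; b2[t] = 2; } else { d2[t] = v12; b2[t] = 1; }
      d1[t] += logdens(t, 0);
      d2[t] += logdens(t, 1);
    }
    bool last = (t == n - 1) || (burst[t + 1] != burst[t]);
    if (last) {
      // backtrack this burst
      int s = (d2[t] > d1[t]) ? 2 : 1;
      path[t] = s;
      for (int u = t; u > 0 && burst[u] == burst[u - 1]; --u) {
        s = (s == 1) ? b1[u] : b2[u];
        path[u - 1] = s;
      }
    }
  }
  return path;
}

// One-step-ahead (forecast) predictive state probabilities, used for
// pseudo-residuals: returns an n x 2 matrix of P(S_t = j | x_1..t-1).
// Missing observations leave the filter at its predictive value.

// [[Rcpp::export]]
NumericMatrix hmm_predictive_cpp(NumericMatrix logdens, LogicalVector observed,
                                 NumericVector g12, NumericVector g21,
                                 IntegerVector burst) {
  int n = logdens.nrow();
  NumericMatrix pred(n, 2);
  double w1 = 0.0, w2 = 0.0;
  for (int t = 0; t < n; ++t) {
    double p1, p2;
    if (t == 0 || burst[t] != burst[t - 1]) {
      double s = g12[t] + g21[t];
      p1 = g21[t] / s;
      p2 = g12[t] / s;
    } else {
      p1 = w1 * (1.0 - g12[t]) + w2 * g21[t];
      p2 = w1 * g12[t] + w2 * (1.0 - g21[t]);
    }
    pred(t, 0) = p1;
    pred(t, 1) = p2;
    if (observed[t]) {
      double l1 = logdens(t, 0), l2 = logdens(t, 1);
      double m = (l1 > l2) ? l1 : l2;
      double a1 = p1 * std::exp(l1 - m);
      double a2 = p2 * std::exp(l2 - m);
      double c = a1 + a2;
      w1 = a1 / c;
      w2 = a2 / c;
    } else {
      w1 = p1;
      w2 = p2;
    }
  }
  return pred;
}
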
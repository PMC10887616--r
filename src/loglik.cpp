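#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// log pmf of BPoi in the independent-component parameterization,
// accumulated in log space with a running maximum so that counts up to
// ~1e3 do not overflow the finite convolution series.
static double bpoi_logpmf1(int a, int b, double t1, double t2, double t12) {
  const double lt1 = std::log(t1), lt2 = std::log(t2);
  const double lt12 = (t12 > 0.0) ? std::log(t12) : R_NegInf;
  const int mi = std::min(a, b);
  std::vector<double> terms;
  terms.reserve(mi + 1);
  double mx = R_NegInf;
  for (int i = 0; i <= mi; ++i) {
    if (i > 0 && t12 <= 0.0) break;
    double li = (a - i) * lt1 + (b - i) * lt2 - lgamma(a - i + 1.0)
              - lgamma(b - i + 1.0) - lgamma(i + 1.0);
    if (i > 0) li += i * lt12;
    terms.push_back(li);
    if (li > mx) mx = li;
  }
  double s = 0.0;
  for (double li : terms) s += std::exp(li - mx);
  return -(t1 + t2 + t12) + mx + std::log(s);
}

// [[Rcpp::export]]
NumericVector bpoi_logpmf_cpp(IntegerVector x1, IntegerVector x2,
                              double t1, double t2, double t12) {
  int n = x1.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = bpoi_logpmf1(x1[k], x2[k], t1, t2, t12);
  return out;
}

// w[j] = t^j / j!  (Poisson weights up to the normalizing e^{-t})
static std::vector<double> powfac(double t, int m) {
  std::vector<double> w(m + 1);
  w[0] = 1.0;
  for (int j = 1; j <= m; ++j) w[j] = w[j - 1] * t / j;
  return w;
}

// Dense table f[a, b] of the innovation BPoi pmf for a <= m1, b <= m2.
// Linear-space accumulation is safe here: with feasible innovation rates
// the weights t^j/j! stay far below double overflow for the low counts
// this model targets, and the table is what makes the likelihood cheap.
static std::vector<double> bpoi_table(int m1, int m2,
                                      double t1, double t2, double t12) {
  std::vector<double> f((m1 + 1) * (m2 + 1));
  std::vector<double> p1 = powfac(t1, m1), p2 = powfac(t2, m2);
  std::vector<double> p12 = powfac(t12, std::min(m1, m2));
  const double e = std::exp(-(t1 + t2 + t12));
  for (int a = 0; a <= m1; ++a) {
    for (int b = 0; b <= m2; ++b) {
      const int mi = std::min(a, b);
      double s = 0.0;
      for (int i = 0; i <= mi; ++i) {
        if (i > 0 && t12 <= 0.0) break;
        s += p1[a - i] * p2[b - i] * p12[i];
      }
      f[a * (m2 + 1) + b] = e * s;
    }
  }
  return f;
}

// Rows of binomial pmfs: B[np, k] = C(np, k) a^k (1-a)^(np-k), np, k <= m,
// built by the Pascal-style recursion (numerically exact for a in [0,1)).
static std::vector<double> binom_table(int m, double a) {
  std::vector<double> B((m + 1) * (m + 1), 0.0);
  B[0] = 1.0;
  for (int np = 1; np <= m; ++np) {
    double *cur = &B[np * (m + 1)];
    const double *prev = &B[(np - 1) * (m + 1)];
    cur[0] = prev[0] * (1.0 - a);
    for (int k = 1; k <= np; ++k)
      cur[k] = (1.0 - a) * prev[k] + a * prev[k - 1];
  }
  return B;
}

// Conditional log-likelihood of the Poi-CuBINAR(1) model: the sum over
// t = 2..n of the log transition probability, each transition a double
// binomial convolution of the thinning survivors against the innovation
// BPoi pmf of the realized regime transition. Innovation pmf tables are
// built lazily per (r, s) pair and the binomial tables once, so a full
// evaluation is O(n * E[x1] * E[x2]) plus small table costs.
// Returns -Inf for infeasible parameters or numerically vanished terms.
// [[Rcpp::export]]
double cubinar_loglik_cpp(IntegerVector x1, IntegerVector x2,
                          IntegerVector states,
                          double alpha1, double alpha2,
                          NumericVector lambda1, NumericVector lambda2,
                          double phi) {
  const int n = x1.size();
  const int S = lambda1.size();
  if (n < 2) return 0.0;
  int m1 = 0, m2 = 0;
  for (int t = 0; t < n; ++t) {
    if (x1[t] > m1) m1 = x1[t];
    if (x2[t] > m2) m2 = x2[t];
  }
  const double phi_star = phi * (1.0 - alpha1 * alpha2);
  if (phi_star < 0.0 || alpha1 < 0.0 || alpha1 >= 1.0 ||
      alpha2 < 0.0 || alpha2 >= 1.0)
    return R_NegInf;

  std::vector<std::vector<double> > f(S * S);
  const std::vector<double> B1 = binom_table(m1, alpha1);
  const std::vector<double> B2 = binom_table(m2, alpha2);

  double L = 0.0;
  for (int t = 1; t < n; ++t) {
    const int r = states[t - 1] - 1, s = states[t] - 1;
    if (r < 0 || r >= S || s < 0 || s >= S) return R_NegInf;
    std::vector<double> &frs = f[r * S + s];
    if (frs.empty()) {
      const double l1s = lambda1[s] - alpha1 * lambda1[r] - phi_star;
      const double l2s = lambda2[s] - alpha2 * lambda2[r] - phi_star;
      if (l1s <= 0.0 || l2s <= 0.0) return R_NegInf;
      frs = bpoi_table(m1, m2, l1s, l2s, phi_star);
    }
    const int x1t = x1[t], x2t = x2[t], x1p = x1[t - 1], x2p = x2[t - 1];
    const int K = std::min(x1t, x1p), Lm = std::min(x2t, x2p);
    const double *b1 = &B1[x1p * (m1 + 1)];
    const double *b2 = &B2[x2p * (m2 + 1)];
    double p = 0.0;
    for (int k = 0; k <= K; ++k) {
      const double *frow = &frs[(x1t - k) * (m2 + 1)];
      double inner = 0.0;
      for (int l = 0; l <= Lm; ++l) inner += b2[l] * frow[x2t - l];
      p += b1[k] * inner;
    }
    if (!(p > 0.0)) return R_NegInf;
    L += std::log(p);
  }
  return L;
}
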
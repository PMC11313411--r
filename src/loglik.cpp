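#include <Rcpp.h>
using namespace Rcpp;

// State coding (P pools): 1..P = alive/operable in pool, P+1 = dead/operable,
// P+2 = alive/expired, P+3 = dead/expired.
// Observation coding: 1..P = detected in pool, P+1 = not detected,
// P+2 = battery expired, 0 = outside the fish's history.

static inline double logistic(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// [[Rcpp::export]]
NumericMatrix cpp_build_transition(double phi, double delta, NumericMatrix psi) {
  int P = psi.nrow();
  int K = P + 3;
  NumericMatrix T(K, K);
  for (int j = 0; j < P; ++j) {
    for (int i = 0; i < P; ++i) T(i, j) = phi * delta * psi(i, j);
    T(P, j)     = (1.0 - phi) * delta;
    T(P + 1, j) = phi * (1.0 - delta);
    T(P + 2, j) = (1.0 - phi) * (1.0 - delta);
  }
  T(P, P) = delta;            // D/O stays D/O while battery lasts
  T(P + 2, P) = 1.0 - delta;  // D/O -> D/E
  T(P + 1, P + 1) = phi;      // A/E survives
  T(P + 2, P + 1) = 1.0 - phi;
  T(P + 2, P + 2) = 1.0;      // D/E absorbing
  return T;
}

// Forward-algorithm log marginal likelihood for one fish, summing over the
// latent chain. obs points at the coded observations for months
// first_month..(first_month + n_obs - 1); obs[0] is the asserted release
// pool and contributes probability one. Tm is the K x K transition matrix
// (column-major), rho the P x n_months detection-probability table.
static double forward_one(const int *obs, int n_obs, int rel_pool,
                          int first_month, const double *Tm, int K, int P,
                          const double *rho) {
  std::vector<double> a(K, 0.0), b(K, 0.0);
  a[rel_pool - 1] = 1.0;
  double ll = 0.0;
  for (int s = 1; s < n_obs; ++s) {
    int t = first_month + s - 1;  // 0-based month index
    int y = obs[s];
    double scale = 0.0;
    if (y >= 1 && y <= P) {
      int i = y - 1;
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += Tm[i + j * K] * a[j];
      double v = acc * rho[i + t * P];
      std::fill(a.begin(), a.end(), 0.0);
      a[i] = v;
      scale = v;
    } else {
      for (int i = 0; i < K; ++i) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j) acc += Tm[i + j * K] * a[j];
        b[i] = acc;
      }
      if (y == P + 1) {  // not detected: undetected A/O, or D/O
        for (int j = 0; j < P; ++j) {
          a[j] = b[j] * (1.0 - rho[j + t * P]);
          scale += a[j];
        }
        a[P] = b[P];
        scale += a[P];
        a[P + 1] = a[P + 2] = 0.0;
      } else if (y == P + 2) {  // battery expired asserted
        std::fill(a.begin(), a.end(), 0.0);
        a[P + 1] = b[P + 1];
        a[P + 2] = b[P + 2];
        scale = a[P + 1] + a[P + 2];
      } else {
        return NA_REAL;  // malformed coding
      }
    }
    if (scale <= 0.0) return R_NegInf;
    double inv = 1.0 / scale;
    for (int i = 0; i < K; ++i) a[i] *= inv;
    ll += std::log(scale);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_total_loglik(IntegerMatrix obs, IntegerVector rel_month,
                        IntegerVector rel_pool, IntegerVector last_month,
                        double phi, double delta, NumericMatrix psi,
                        NumericVector beta, NumericMatrix effort,
                        double intercept) {
  int n = obs.nrow();
  int P = psi.nrow();
  int K = P + 3;
  int TT = effort.ncol();
  NumericMatrix T = cpp_build_transition(phi, delta, psi);
  std::vector<double> Tm(T.begin(), T.end());
  std::vector<double> rho(P * TT);
  for (int t = 0; t < TT; ++t)
    for (int j = 0; j < P; ++j)
      rho[j + t * P] = logistic(intercept + beta[j] * effort(j, t));
  double total = 0.0;
  std::vector<int> buf;
  for (int f = 0; f < n; ++f) {
    int m0 = rel_month[f], m1 = last_month[f];
    int len = m1 - m0 + 1;
    if (len <= 1) continue;  // release-only history: likelihood one
    buf.resize(len);
    for (int s = 0; s < len; ++s) buf[s] = obs(f, m0 - 1 + s);
    double ll = forward_one(buf.data(), len, rel_pool[f], m0, Tm.data(), K, P,
                            rho.data());
    if (ISNA(ll)) stop("malformed observation code in history %d", f + 1);
    if (ll == R_NegInf) return R_NegInf;
    total += ll;
  }
  return total;
}
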
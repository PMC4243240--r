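#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-sample t-like statistic for the circular arc (i, j] (0-based cumsum
// indices): compares the mean of elements i+1..j against the mean of the
// complement. mse is the pooled within-group variance; a (near-)zero mse with
// a non-zero mean difference is treated as an infinite statistic (noiseless
// step), zero difference as 0.
static inline double arc_stat(const double *S, const double *Q,
                              int i, int j, int n, double scale) {
  const int k = j - i;
  const int m = n - k;
  const double sum_in = S[j] - S[i];
  const double sum_out = S[n] - sum_in;
  const double mean_in = sum_in / k;
  const double mean_out = sum_out / m;
  const double ss_in = (Q[j] - Q[i]) - sum_in * sum_in / k;
  const double ss_out = (Q[n] - (Q[j] - Q[i])) - sum_out * sum_out / m;
  const double diff = mean_in - mean_out;
  const double mse = (n > 2) ? (ss_in + ss_out) / (n - 2) : 0.0;
  if (mse <= 1e-14 * scale) {
    if (std::fabs(diff) <= 1e-12) return 0.0;
    return R_PosInf;
  }
  return std::fabs(diff) / std::sqrt(mse * (1.0 / k + 1.0 / m));
}

static void cumsums(const double *x, int n, std::vector<double> &S,
                    std::vector<double> &Q) {
  S[0] = 0.0;
  Q[0] = 0.0;
  for (int t = 0; t < n; ++t) {
    S[t + 1] = S[t] + x[t];
    Q[t + 1] = Q[t] + x[t] * x[t];
  }
}

// Exhaustive scan over all circular arcs (i, j], min_width <= j - i and
// n - (j - i) >= min_width. Returns c(stat, i, j); the first maximum in
// (i, j) iteration order wins, which keeps the scan deterministic.
// [[Rcpp::export]]
NumericVector cpp_max_arc(NumericVector x, int min_width) {
  const int n = x.size();
  std::vector<double> S(n + 1), Q(n + 1);
  cumsums(REAL(x), n, S, Q);
  const double scale = std::max(1.0, Q[n] / n);
  double best = -1.0;
  int bi = 0, bj = 0;
  for (int i = 0; i <= n - min_width; ++i) {
    const int jmax = std::min(n, i + n - min_width);
    for (int j = i + min_width; j <= jmax; ++j) {
      const double s = arc_stat(S.data(), Q.data(), i, j, n, scale);
      if (s > best) {
        best = s;
        bi = i;
        bj = j;
      }
    }
  }
  return NumericVector::create(best, (double)bi, (double)bj);
}

// Max arc statistic for each column of a matrix of permuted profiles.
// [[Rcpp::export]]
NumericVector cpp_perm_max(NumericMatrix xp, int min_width) {
  const int n = xp.nrow();
  const int B = xp.ncol();
  NumericVector out(B);
  std::vector<double> S(n + 1), Q(n + 1);
  for (int b = 0; b < B; ++b) {
    cumsums(&xp(0, b), n, S, Q);
    const double scale = std::max(1.0, Q[n] / n);
    double best = -1.0;
    for (int i = 0; i <= n - min_width; ++i) {
      const int jmax = std::min(n, i + n - min_width);
      for (int j = i + min_width; j <= jmax; ++j) {
        const double s = arc_stat(S.data(), Q.data(), i, j, n, scale);
        if (s > best) best = s;
      }
    }
    out[b] = best;
  }
  return out;
}
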
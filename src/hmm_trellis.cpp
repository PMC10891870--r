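#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline double logsumexp_row(const std::vector<double>& v) {
  double m = -DBL_MAX;
  for (double x : v) if (x > m) m = x;
  if (m == -DBL_MAX) return -DBL_MAX;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// Log-domain forward recursion.
// logpi: N, logA: N x N (row i -> col j), logB: T x N frame log-densities.
// [[Rcpp::export]]
List hmm_forward(NumericVector logpi, NumericMatrix logA, NumericMatrix logB) {
  const int T = logB.nrow(), N = logB.ncol();
  NumericMatrix la(T, N);
  std::vector<double> acc(N);
  for (int j = 0; j < N; ++j) la(0, j) = logpi[j] + logB(0, j);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < N; ++i) acc[i] = la(t - 1, i) + logA(i, j);
      la(t, j) = logsumexp_row(acc) + logB(t, j);
    }
  std::vector<double> last(N);
  for (int j = 0; j < N; ++j) last[j] = la(T - 1, j);
  return List::create(_["log_alpha"] = la,
                      _["log_likelihood"] = logsumexp_row(last));
}

// Log-domain backward recursion; beta_T = 0.
// [[Rcpp::export]]
NumericMatrix hmm_backward(NumericMatrix logA, NumericMatrix logB) {
  const int T = logB.nrow(), N = logB.ncol();
  NumericMatrix lb(T, N);
  std::vector<double> acc(N);
  for (int j = 0; j < N; ++j) lb(T - 1, j) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j)
        acc[j] = logA(i, j) + logB(t + 1, j) + lb(t + 1, j);
      lb(t, i) = logsumexp_row(acc);
    }
  return lb;
}

// Max-product Viterbi with backtracking; ties resolved to the lower state
// index.  Returns a 1-based path.
// [[Rcpp::export]]
List hmm_viterbi(NumericVector logpi, NumericMatrix logA, NumericMatrix logB) {
  const int T = logB.nrow(), N = logB.ncol();
  NumericMatrix delta(T, N);
  IntegerMatrix psi(T, N);
  for (int j = 0; j < N; ++j) delta(0, j) = logpi[j] + logB(0, j);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < N; ++j) {
      double best = -DBL_MAX;
      int arg = 0;
      for (int i = 0; i < N; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  double best = -DBL_MAX;
  int arg = 0;
  for (int j = 0; j < N; ++j)
    if (delta(T - 1, j) > best) { best = delta(T - 1, j); arg = j; }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return List::create(_["path"] = path, _["log_score"] = best);
}
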
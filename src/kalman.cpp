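#include <Rcpp.h>
using namespace Rcpp;

// AR(p) state-space Kalman filter over one block of observations.
//
// State x_k stacks the last p clean samples; A is the AR companion matrix
// (first row = AR coefficients, identity on the subdiagonal), H = e1',
// Q = diag(sigma2, 0, ..., 0).  The loop carries x and P across calls so a
// signal can be filtered frame-by-frame with per-frame AR refits.
//
// [[Rcpp::export]]
List kalman_filter_block(NumericVector ar, double sigma2, double R,
                         NumericVector z, NumericVector x0,
                         NumericMatrix P0) {
  const int p = ar.size();
  const int n = z.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> P(p * p), Pp(p * p), xp(p), g(p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) P[i * p + j] = P0(i, j);

  NumericVector out(n);

  // A * v for companion A
  auto Amul = [&](const std::vector<double>& v, std::vector<double>& res) {
    double top = 0.0;
    for (int j = 0; j < p; ++j) top += ar[j] * v[j];
    res[0] = top;
    for (int i = 1; i < p; ++i) res[i] = v[i - 1];
  };

  std::vector<double> AP(p * p);
  for (int k = 0; k < n; ++k) {
    // predict: xp = A x
    Amul(x, xp);
    // AP = A * P (row 0 = ar' P, row i = row i-1 of P)
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < p; ++i) s += ar[i] * P[i * p + j];
      AP[j] = s;
    }
    for (int i = 1; i < p; ++i)
      for (int j = 0; j < p; ++j) AP[i * p + j] = P[(i - 1) * p + j];
    // Pp = AP * A' + Q
    for (int i = 0; i < p; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += AP[i * p + j] * ar[j];
      Pp[i * p + 0] = s;
      for (int j = 1; j < p; ++j) Pp[i * p + j] = AP[i * p + (j - 1)];
    }
    Pp[0] += sigma2;

    // gain along H = e1'
    double denom = Pp[0] + R;
    if (denom <= 0.0) denom = 1e-300;
    for (int i = 0; i < p; ++i) g[i] = Pp[i * p + 0] / denom;

    double innov = z[k] - xp[0];
    if (!std::isfinite(innov)) innov = 0.0;  // reset to prediction
    for (int i = 0; i < p; ++i) x[i] = xp[i] + g[i] * innov;

    // P = (I - g H) Pp, then symmetrize
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        P[i * p + j] = Pp[i * p + j] - g[i] * Pp[0 * p + j];
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j) {
        double m = 0.5 * (P[i * p + j] + P[j * p + i]);
        P[i * p + j] = m;
        P[j * p + i] = m;
      }
    out[k] = x[0];
  }

  NumericMatrix Pout(p, p);
  NumericVector xout(p);
  for (int i = 0; i < p; ++i) {
    xout[i] = x[i];
    for (int j = 0; j < p; ++j) Pout(i, j) = P[i * p + j];
  }
  return List::create(_["filtered"] = out, _["x"] = xout, _["P"] = Pout,
                      _["gain"] = NumericVector(g.begin(), g.end()));
}
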
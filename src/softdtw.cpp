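#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// pointwise cost between column i of x and column j of y (p-dimensional)
static inline double point_cost(const NumericMatrix &x, const NumericMatrix &y,
                                int i, int j, bool squared) {
  double s = 0.0;
  const int p = x.nrow();
  for (int d = 0; d < p; ++d) {
    const double diff = x(d, i) - y(d, j);
    s += diff * diff;
  }
  return squared ? s : std::sqrt(s);
}

// soft minimum of three values in stabilised log-space; gamma == 0 -> hard min
static inline double softmin3(double a, double b, double c, double gamma) {
  const double m = std::min(a, std::min(b, c));
  if (gamma == 0.0 || m == INF) return m;
  const double s = std::exp(-(a - m) / gamma) + std::exp(-(b - m) / gamma) +
                   std::exp(-(c - m) / gamma);
  return m - gamma * std::log(s);
}

// [[Rcpp::export(name = ".costMatrixC")]]
NumericMatrix costMatrixC(NumericMatrix x, NumericMatrix y, bool squared) {
  const int n = x.ncol(), m = y.ncol();
  NumericMatrix delta(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      delta(i, j) = point_cost(x, y, i, j, squared);
  return delta;
}

// classic DTW value from a precomputed cost matrix
// [[Rcpp::export(name = ".dtwFromCostC")]]
double dtwFromCostC(NumericMatrix delta) {
  const int n = delta.nrow(), m = delta.ncol();
  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = INF;
    for (int j = 1; j <= m; ++j) {
      const double best =
          std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = delta(i - 1, j - 1) + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// DTW with backtracked optimal alignment path (ties: diagonal > up > left)
// [[Rcpp::export(name = ".dtwPathC")]]
List dtwPathC(NumericMatrix delta) {
  const int n = delta.nrow(), m = delta.ncol();
  NumericMatrix r(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) r(i, j) = INF;
  r(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      r(i, j) = delta(i - 1, j - 1) +
                std::min(r(i - 1, j - 1), std::min(r(i - 1, j), r(i, j - 1)));
  // backtrack
  std::vector<int> pi, pj;
  int i = n, j = m;
  while (i >= 1 && j >= 1) {
    pi.push_back(i);
    pj.push_back(j);
    if (i == 1 && j == 1) break;
    const double d = (i > 1 && j > 1) ? r(i - 1, j - 1) : INF;
    const double u = (i > 1) ? r(i - 1, j) : INF;
    const double l = (j > 1) ? r(i, j - 1) : INF;
    if (d <= u && d <= l) { --i; --j; }
    else if (u <= l) { --i; }
    else { --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["value"] = r(n, m), _["i"] = wrap(pi),
                      _["j"] = wrap(pj));
}

// Soft-DTW forward pass: returns value and the padded (n+1)x(m+1)
// cost-sum table r (row/col 0 are the boundary).
// [[Rcpp::export(name = ".softdtwForwardC")]]
List softdtwForwardC(NumericMatrix delta, double gamma) {
  const int n = delta.nrow(), m = delta.ncol();
  NumericMatrix r(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) r(i, j) = INF;
  r(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      r(i, j) = delta(i - 1, j - 1) +
                softmin3(r(i - 1, j - 1), r(i - 1, j), r(i, j - 1), gamma);
  return List::create(_["value"] = r(n, m), _["r"] = r);
}

// Backward pass: E matrix of partial derivatives e_{i,j} = d r_{n,m} / d r_{i,j},
// computed right-to-left / bottom-to-top with virtual border cells.
// [[Rcpp::export(name = ".softdtwEMatrixC")]]
NumericMatrix softdtwEMatrixC(NumericMatrix delta, NumericMatrix r,
                              double gamma) {
  const int n = delta.nrow(), m = delta.ncol();
  // padded copies with a virtual terminal cell (n+1, m+1)
  NumericMatrix D(n + 2, m + 2), R(n + 2, m + 2), E(n + 2, m + 2);
  for (int i = 0; i <= n + 1; ++i)
    for (int j = 0; j <= m + 1; ++j) { D(i, j) = 0.0; R(i, j) = -INF; E(i, j) = 0.0; }
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) { D(i, j) = delta(i - 1, j - 1); R(i, j) = r(i, j); }
  R(n + 1, m + 1) = r(n, m);
  E(n + 1, m + 1) = 1.0;
  for (int j = m; j >= 1; --j) {
    for (int i = n; i >= 1; --i) {
      // exponents are <= 0 up to soft-min slack; cap against overflow
      double ea = (R(i + 1, j) - R(i, j) - D(i + 1, j)) / gamma;
      double eb = (R(i, j + 1) - R(i, j) - D(i, j + 1)) / gamma;
      double ec = (R(i + 1, j + 1) - R(i, j) - D(i + 1, j + 1)) / gamma;
      const double cap = 0.0;
      const double a = (R(i + 1, j) == -INF) ? 0.0 : std::exp(std::min(ea, cap));
      const double b = (R(i, j + 1) == -INF) ? 0.0 : std::exp(std::min(eb, cap));
      const double c = (R(i + 1, j + 1) == -INF) ? 0.0 : std::exp(std::min(ec, cap));
      E(i, j) = E(i + 1, j) * a + E(i, j + 1) * b + E(i + 1, j + 1) * c;
    }
  }
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) out(i, j) = E(i + 1, j + 1);
  return out;
}

// value + gradient w.r.t. x in one call (squared Euclidean cost only):
// grad_x[, i] = sum_j E(i, j) * 2 * (x[, i] - y[, j])
// [[Rcpp::export(name = ".softdtwValueGradC")]]
List softdtwValueGradC(NumericMatrix x, NumericMatrix y, double gamma) {
  const int p = x.nrow(), n = x.ncol(), m = y.ncol();
  NumericMatrix delta = costMatrixC(x, y, true);
  List fw = softdtwForwardC(delta, gamma);
  NumericMatrix r = fw["r"];
  NumericMatrix E = softdtwEMatrixC(delta, r, gamma);
  NumericMatrix g(p, n);
  for (int i = 0; i < n; ++i) {
    double esum = 0.0;
    for (int j = 0; j < m; ++j) esum += E(i, j);
    for (int d = 0; d < p; ++d) {
      double acc = x(d, i) * esum;
      for (int j = 0; j < m; ++j) acc -= E(i, j) * y(d, j);
      g(d, i) = 2.0 * acc;
    }
  }
  return List::create(_["value"] = as<double>(fw["value"]), _["grad"] = g,
                      _["e"] = E);
}

// univariate DTW between two columns, O(min) memory
static double dtw1d(const NumericMatrix &a, const NumericMatrix &b, int col,
                    bool squared) {
  const int n = a.nrow(), m = b.nrow();
  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = INF;
    const double ai = a(i - 1, col);
    for (int j = 1; j <= m; ++j) {
      const double diff = ai - b(j - 1, col);
      const double d = squared ? diff * diff : std::fabs(diff);
      cur[j] = d + std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// per-channel-summed DTW distance between two epochs (time x channel)
// [[Rcpp::export(name = ".epochDistanceC")]]
double epochDistanceC(NumericMatrix a, NumericMatrix b, bool squared) {
  const int k = a.ncol();
  double s = 0.0;
  for (int c = 0; c < k; ++c) s += dtw1d(a, b, c, squared);
  return s;
}

// weighted Soft-DTW barycenter objective and gradient over a list of series
// [[Rcpp::export(name = ".barycenterObjGradC")]]
List barycenterObjGradC(NumericMatrix x, List ys, NumericVector weights,
                        double gamma) {
  const int p = x.nrow(), n = x.ncol(), N = ys.size();
  NumericMatrix grad(p, n);
  double obj = 0.0;
  for (int s = 0; s < N; ++s) {
    NumericMatrix y = ys[s];
    const double w = weights[s] / (double)y.ncol();
    List vg = softdtwValueGradC(x, y, gamma);
    obj += w * as<double>(vg["value"]);
    NumericMatrix g = vg["grad"];
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < p; ++d) grad(d, i) += w * g(d, i);
  }
  return List::create(_["objective"] = obj, _["grad"] = grad);
}
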
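#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Unimodality deviation statistic for a sorted sample.
//
// The empirical CDF is treated as a band: at the i-th distinct value the CDF
// lies between l_i (value just before the jump) and u_i (just after). A
// unimodal CDF is convex left of its mode and concave right of it; an atom is
// permitted at the mode itself. For a candidate mode at distinct value j the
// best achievable sup-distance is half of
//   max( A(j), B(j) ),
// where A(j) is how far the upper corners u_i poke above the greatest convex
// minorant of the lower corners l_i over i <= j (the mode point itself only
// needs to be reached from below), and B(j) is the mirror-image quantity for
// the least concave majorant over i >= j. The statistic is
//   dip = 0.5 * min_j max(A(j), B(j)).
//
// Computed with an incremental lower-hull stack; points spanned by a new hull
// segment are rescanned, which is worst-case quadratic but near-linear for
// the empirical CDFs met in practice.

static std::vector<double> prefix_dev(const std::vector<double>& x,
                                      const std::vector<double>& l,
                                      const std::vector<double>& u) {
  const int n = (int) x.size();
  std::vector<double> A(n, 0.0);
  std::vector<int> v;      // hull vertex indices
  std::vector<double> pd;  // running max deviation over points up to vertex
  v.reserve(n); pd.reserve(n);
  v.push_back(0);
  pd.push_back(u[0] - l[0]);
  A[0] = 0.0;  // a lone mode point can be matched exactly (atom at the mode)
  for (int m = 1; m < n; ++m) {
    while (v.size() >= 2) {
      int b = v[v.size() - 1], a = v[v.size() - 2];
      double cross = (x[b] - x[a]) * (l[m] - l[a]) - (l[b] - l[a]) * (x[m] - x[a]);
      if (cross <= 0.0) { v.pop_back(); pd.pop_back(); } else break;
    }
    int t = v.back();
    double slope = (l[m] - l[t]) / (x[m] - x[t]);
    double mx_all = 0.0, mx_excl = 0.0;
    for (int i = t + 1; i <= m; ++i) {
      double h = l[t] + slope * (x[i] - x[t]);
      double d = u[i] - h;
      if (d > mx_all) mx_all = d;
      if (i < m && d > mx_excl) mx_excl = d;
    }
    double prev = pd.back();
    A[m] = std::max(prev, mx_excl);
    v.push_back(m);
    pd.push_back(std::max(prev, mx_all));
  }
  return A;
}

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector values) {
  std::vector<double> xs(values.begin(), values.end());
  std::sort(xs.begin(), xs.end());
  const int n = (int) xs.size();
  if (n == 0) return NA_REAL;
  // collapse ties: distinct x with lower/upper ECDF corners
  std::vector<double> x, l, u;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && xs[j + 1] == xs[i]) ++j;
    x.push_back(xs[i]);
    l.push_back((double) i / n);
    u.push_back((double) (j + 1) / n);
    i = j + 1;
  }
  const int k = (int) x.size();
  if (k == 1) return 0.0;
  std::vector<double> A = prefix_dev(x, l, u);
  // reflect for the concave (right) side: x -> -x reversed, band flipped
  std::vector<double> xr(k), lr(k), ur(k);
  for (int j = 0; j < k; ++j) {
    xr[j] = -x[k - 1 - j];
    lr[j] = 1.0 - u[k - 1 - j];
    ur[j] = 1.0 - l[k - 1 - j];
  }
  std::vector<double> Ar = prefix_dev(xr, lr, ur);
  double best = R_PosInf;
  for (int j = 0; j < k; ++j) {
    double m = std::max(A[j], Ar[k - 1 - j]);
    if (m < best) best = m;
  }
  return 0.5 * best;
}
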
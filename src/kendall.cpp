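#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Inversion counting by merge sort: number of strictly decreasing pairs in y.
// Ties are kept stable and never counted, which is what tau-b needs (tied
// pairs are neither concordant nor discordant).
static long long merge_count(std::vector<double>& y, std::vector<double>& buf,
                             int lo, int hi) {
  if (hi - lo < 2) return 0;
  int mid = (lo + hi) / 2;
  long long cnt = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  int i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) { cnt += mid - i; buf[k++] = y[j++]; }
    else             { buf[k++] = y[i++]; }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi)  buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return cnt;
}

static long long tie_pairs(const std::vector<double>& v) {
  // v must be sorted; sum over runs of t*(t-1)/2
  long long s = 0, run = 1;
  for (size_t i = 1; i < v.size(); ++i) {
    if (v[i] == v[i - 1]) ++run;
    else { s += run * (run - 1) / 2; run = 1; }
  }
  s += run * (run - 1) / 2;
  return s;
}

// Knight's O(n log n) tau-b. Returns NA_REAL when either margin is constant
// (denominator zero): the correlation is undefined, never silently 0.
static double tau_b_core(const std::vector<double>& x,
                         const std::vector<double>& y) {
  const int n = (int)x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  const long long n0 = (long long)n * (n - 1) / 2;

  // ties in x, and joint (x, y) ties, from the (x, y)-sorted order
  long long n1 = 0, n3 = 0, runx = 1, runxy = 1;
  std::vector<double> ysort(n);
  for (int i = 0; i < n; ++i) ysort[i] = y[ord[i]];
  for (int i = 1; i < n; ++i) {
    bool samex = x[ord[i]] == x[ord[i - 1]];
    bool samey = ysort[i] == ysort[i - 1];
    if (samex) ++runx; else { n1 += runx * (runx - 1) / 2; runx = 1; }
    if (samex && samey) ++runxy; else { n3 += runxy * (runxy - 1) / 2; runxy = 1; }
  }
  n1 += runx * (runx - 1) / 2;
  n3 += runxy * (runxy - 1) / 2;

  std::vector<double> buf(n), ywork(ysort);
  long long D = merge_count(ywork, buf, 0, n);  // discordant pairs

  std::sort(ysort.begin(), ysort.end());
  long long n2 = tie_pairs(ysort);

  double den = std::sqrt((double)(n0 - n1) * (double)(n0 - n2));
  if (den == 0.0) return NA_REAL;
  // C - D = n0 - n1 - n2 + n3 - 2D
  double S = (double)(n0 - n1 - n2 + n3) - 2.0 * (double)D;
  return S / den;
}

// [[Rcpp::export(name = ".tau_b_cpp")]]
double tau_b_cpp(NumericVector x, NumericVector y) {
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  return tau_b_core(xs, ys);
}

// All pairwise tau-b among the rows of X (genes x samples).
// [[Rcpp::export(name = ".tau_matrix_cpp")]]
NumericMatrix tau_matrix_cpp(NumericMatrix X) {
  const int g = X.nrow(), n = X.ncol();
  NumericMatrix out(g, g);
  std::vector<std::vector<double> > rows(g, std::vector<double>(n));
  for (int i = 0; i < g; ++i)
    for (int j = 0; j < n; ++j) rows[i][j] = X(i, j);
  for (int i = 0; i < g; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < g; ++j) {
      double t = tau_b_core(rows[i], rows[j]);
      out(i, j) = t;
      out(j, i) = t;
    }
  }
  return out;
}

// tau-b of each row of X against a single vector z.
// [[Rcpp::export(name = ".tau_vs_vector_cpp")]]
NumericVector tau_vs_vector_cpp(NumericMatrix X, NumericVector z) {
  const int g = X.nrow(), n = X.ncol();
  std::vector<double> zs(z.begin(), z.end());
  NumericVector out(g);
  std::vector<double> row(n);
  for (int i = 0; i < g; ++i) {
    for (int j = 0; j < n; ++j) row[j] = X(i, j);
    out[i] = tau_b_core(row, zs);
  }
  return out;
}
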
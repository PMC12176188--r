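#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Inversion = pair i < j with v[i] > v[j]; ties never count. Swap counts can
// reach n(n-1)/2 ~ 5e9 at n = 1e5, so counters are doubles (exact to 2^53).

static double insertion_sort_imp(double* v, R_xlen_t n) {
  double swaps = 0.0;
  for (R_xlen_t i = 1; i < n; ++i) {
    double key = v[i];
    R_xlen_t j = i - 1;
    while (j >= 0 && v[j] > key) {
      v[j + 1] = v[j];
      --j;
      swaps += 1.0;
    }
    v[j + 1] = key;
  }
  return swaps;
}

static double merge_imp(double* from, double* to, R_xlen_t middle,
                        R_xlen_t len) {
  double swaps = 0.0;
  R_xlen_t pos = 0, left = 0, right = middle;
  while (left < middle && right < len) {
    if (from[right] < from[left]) {
      // every element still waiting on the left is inverted with from[right]
      swaps += static_cast<double>(middle - left);
      to[pos++] = from[right++];
    } else {
      to[pos++] = from[left++];
    }
  }
  while (left < middle) to[pos++] = from[left++];
  while (right < len) to[pos++] = from[right++];
  return swaps;
}

static double merge_sort_imp(double* v, double* buf, R_xlen_t len,
                             int threshold) {
  if (len < threshold) return insertion_sort_imp(v, len);
  R_xlen_t half = len / 2;
  double swaps = merge_sort_imp(v, buf, half, threshold);
  swaps += merge_sort_imp(v + half, buf + half, len - half, threshold);
  swaps += merge_imp(v, buf, half, len);
  std::copy(buf, buf + len, v);
  return swaps;
}

// sum over runs of equal values of L(L-1)/2; input must be nondecreasing
static double tie_pairs_imp(const double* v, R_xlen_t n) {
  double pairs = 0.0;
  R_xlen_t run = 1;
  for (R_xlen_t i = 1; i <= n; ++i) {
    if (i < n && v[i] == v[i - 1]) {
      ++run;
    } else {
      pairs += 0.5 * static_cast<double>(run) * static_cast<double>(run - 1);
      run = 1;
    }
  }
  return pairs;
}

// [[Rcpp::export]]
List insertion_sort_count_cpp(NumericVector values) {
  NumericVector out = clone(values);
  double swaps = insertion_sort_imp(out.begin(), out.size());
  return List::create(_["sorted"] = out, _["swaps"] = swaps);
}

// [[Rcpp::export]]
List merge_sort_count_cpp(NumericVector values, int threshold = 10) {
  NumericVector out = clone(values);
  std::vector<double> buf(out.size());
  double swaps = merge_sort_imp(out.begin(), buf.data(), out.size(), threshold);
  return List::create(_["sorted"] = out, _["swaps"] = swaps);
}

// [[Rcpp::export]]
double count_tie_pairs_cpp(NumericVector sorted_values) {
  return tie_pairs_imp(sorted_values.begin(), sorted_values.size());
}

// Knight's algorithm: sort by (x, then y) so x-tied pairs can never register
// as y-inversions, count tie pairs in x, in y and jointly, then count the
// y-inversions by merge sort.  S = m - tx - ty + txy - 2*swaps equals c - d;
// tau-b = S / sqrt((m - tx)(m - ty)).
// [[Rcpp::export]]
List knight_tau_cpp(NumericVector x, NumericVector y, int threshold = 10) {
  R_xlen_t n = x.size();
  std::vector<R_xlen_t> ord(n);
  std::iota(ord.begin(), ord.end(), static_cast<R_xlen_t>(0));
  std::sort(ord.begin(), ord.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  std::vector<double> xs(n), ys(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    xs[i] = x[ord[i]];
    ys[i] = y[ord[i]];
  }

  double m = 0.5 * static_cast<double>(n) * static_cast<double>(n - 1);
  double tie_x = tie_pairs_imp(xs.data(), n);

  // joint ties: runs of identical (x, y) in the (x, y)-sorted sequence
  double tie_xy = 0.0;
  R_xlen_t run = 1;
  for (R_xlen_t i = 1; i <= n; ++i) {
    if (i < n && xs[i] == xs[i - 1] && ys[i] == ys[i - 1]) {
      ++run;
    } else {
      tie_xy += 0.5 * static_cast<double>(run) * static_cast<double>(run - 1);
      run = 1;
    }
  }

  std::vector<double> buf(n);
  double swaps = merge_sort_imp(ys.data(), buf.data(), n, threshold);
  double tie_y = tie_pairs_imp(ys.data(), n);  // ys now sorted

  double S = m - tie_x - tie_y + tie_xy - 2.0 * swaps;
  double denom = std::sqrt(m - tie_x) * std::sqrt(m - tie_y);
  double tau = (denom > 0.0) ? S / denom : NA_REAL;

  return List::create(
      _["tau"] = tau, _["S"] = S, _["m"] = m, _["tie_x"] = tie_x,
      _["tie_y"] = tie_y, _["tie_xy"] = tie_xy, _["swaps"] = swaps,
      _["n"] = static_cast<double>(n));
}

// Exact null distribution of the concordant-pair statistic: w(n, k) counts
// permutations of n items with inversion statistic k, via the recursion
// w(n, k) = sum_{i=0}^{n-1} w(n-1, k-i), w(1, 0) = 1, memoized with -1 as the
// "not yet computed" sentinel.  Counts are doubles; exactness holds while
// n! < 2^53 (n <= 18) and magnitudes stay representable far beyond the n < 50
// exact-test range.
static double ckendall_rec(int k, int n, std::vector<std::vector<double> >& w) {
  int u = n * (n - 1) / 2;
  if (k < 0 || k > u) return 0.0;
  if (w[n][k] < 0.0) {
    if (n == 1) {
      w[n][k] = (k == 0) ? 1.0 : 0.0;
    } else {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += ckendall_rec(k - i, n - 1, w);
      w[n][k] = s;
    }
  }
  return w[n][k];
}

// [[Rcpp::export]]
NumericVector ckendall_cpp(IntegerVector k, int n) {
  int u = n * (n - 1) / 2;
  std::vector<std::vector<double> > w(
      n + 1, std::vector<double>(u + 1, -1.0));
  NumericVector out(k.size());
  for (R_xlen_t i = 0; i < k.size(); ++i) {
    out[i] = (k[i] == NA_INTEGER) ? NA_REAL : ckendall_rec(k[i], n, w);
  }
  return out;
}

// P(T <= floor(q)) under the exact null, normalized by Gamma(n + 1) = n!
// [[Rcpp::export]]
NumericVector pkendall_cpp(NumericVector q, int n) {
  int u = n * (n - 1) / 2;
  std::vector<std::vector<double> > w(
      n + 1, std::vector<double>(u + 1, -1.0));
  double nfact = ::Rf_gammafn(static_cast<double>(n) + 1.0);
  NumericVector out(q.size());
  for (R_xlen_t i = 0; i < q.size(); ++i) {
    if (NumericVector::is_na(q[i])) {
      out[i] = NA_REAL;
      continue;
    }
    double qi = std::floor(q[i] + 1e-7);
    if (qi < 0.0) {
      out[i] = 0.0;
    } else if (qi >= static_cast<double>(u)) {
      out[i] = 1.0;
    } else {
      double acc = 0.0;
      int qk = static_cast<int>(qi);
      for (int j = 0; j <= qk; ++j) acc += ckendall_rec(j, n, w);
      out[i] = acc / nfact;
    }
  }
  return out;
}
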
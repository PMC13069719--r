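#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Hartigan & Hartigan's dip statistic: the minimal sup-norm distance between
// the empirical CDF of a sample and the class of unimodal CDFs.
//
// Geometry, in "count" units (heights are 0..n): probe i (1-based, sorted)
// contributes an upper ECDF corner at height i and a lower corner at height
// i - 1.  A unimodal CDF is convex left of its single mode and concave right
// of it (a jump is allowed only at the mode).  For a candidate modal
// interval, the best convex fit on the left deviates from the ECDF by half
// the largest vertical excess of upper corners above the greatest convex
// minorant (GCM) of the lower corners; symmetrically on the right with the
// least concave majorant (LCM) of the upper corners.  The algorithm narrows
// the modal interval from [1, n] until the GCM/LCM gap inside it no longer
// exceeds the deviations accumulated outside, following the iterative scheme
// of the published dip algorithm.  Final dip = (count units) / (2n).
//
// Hulls are recomputed on the restricted interval at each iteration; the
// interval shrinks strictly, so the loop terminates.

namespace {

// Lower convex hull (GCM) vertex indices of points (x[i], i), i in [lo, hi],
// 1-based indices, ascending.  Cross-multiplied slope comparisons so tied x
// values (vertical runs) are handled without division.
static void lower_hull(const std::vector<double>& x, int lo, int hi,
                       std::vector<int>& out) {
  out.clear();
  for (int i = lo; i <= hi; ++i) {
    while (out.size() >= 2) {
      int b = out[out.size() - 1], a = out[out.size() - 2];
      // keep b iff slope(a->b) < slope(b->i): (b-a)*(x_i-x_b) < (i-b)*(x_b-x_a)
      double lhs = (double)(b - a) * (x[i - 1] - x[b - 1]);
      double rhs = (double)(i - b) * (x[b - 1] - x[a - 1]);
      if (lhs < rhs) break;
      out.pop_back();
    }
    out.push_back(i);
  }
}

// Upper concave hull (LCM) vertex indices of points (x[i], i).
static void upper_hull(const std::vector<double>& x, int lo, int hi,
                       std::vector<int>& out) {
  out.clear();
  for (int i = lo; i <= hi; ++i) {
    while (out.size() >= 2) {
      int b = out[out.size() - 1], a = out[out.size() - 2];
      // keep b iff slope(a->b) > slope(b->i)
      double lhs = (double)(b - a) * (x[i - 1] - x[b - 1]);
      double rhs = (double)(i - b) * (x[b - 1] - x[a - 1]);
      if (lhs > rhs) break;
      out.pop_back();
    }
    out.push_back(i);
  }
}

// Piecewise-linear hull value (in index units) at the x-position of data
// index j, where the bracketing hull segment is chosen by data index.
static double hull_value_at(const std::vector<double>& x,
                            const std::vector<int>& hull, int j,
                            int* left_vertex, int* right_vertex) {
  // hull is ascending; find segment [hull[s], hull[s+1]] with
  // hull[s] <= j <= hull[s+1]
  size_t s = 0;
  while (s + 1 < hull.size() && hull[s + 1] < j) ++s;
  int a = hull[s];
  int b = (s + 1 < hull.size()) ? hull[s + 1] : hull[s];
  if (left_vertex) *left_vertex = a;
  if (right_vertex) *right_vertex = b;
  if (a == j || b == a) return (double)(a == j ? a : b);
  double dx = x[b - 1] - x[a - 1];
  if (dx <= 0.0) {
    // vertical run: hull passes through both; value at x_j equals height of
    // the vertex with matching index side
    return (double)(j <= a ? a : b);
  }
  return a + (x[j - 1] - x[a - 1]) * (double)(b - a) / dx;
}

// Max excess of upper ECDF corners above GCM chords over data range
// [lo, hi]; "count" units, minimum 1 (the degenerate single-point term).
static double convex_side_dip(const std::vector<double>& x,
                              const std::vector<int>& hull, int lo, int hi) {
  double dmax = 1.0;
  for (size_t s = 0; s + 1 < hull.size(); ++s) {
    int a = hull[s], b = hull[s + 1];
    if (a < lo || b > hi) continue;
    if (b - a <= 1) continue;
    double dx = x[b - 1] - x[a - 1];
    if (dx <= 0.0) continue;
    double slope = (double)(b - a) / dx;
    for (int j = a + 1; j < b; ++j) {
      double chord = a + (x[j - 1] - x[a - 1]) * slope;
      double t = (double)j - chord + 1.0;  // upper corner j vs lower chord
      if (t > dmax) dmax = t;
    }
  }
  return dmax;
}

static double concave_side_dip(const std::vector<double>& x,
                               const std::vector<int>& hull, int lo, int hi) {
  double dmax = 1.0;
  for (size_t s = 0; s + 1 < hull.size(); ++s) {
    int a = hull[s], b = hull[s + 1];
    if (a < lo || b > hi) continue;
    if (b - a <= 1) continue;
    double dx = x[b - 1] - x[a - 1];
    if (dx <= 0.0) continue;
    double slope = (double)(b - a) / dx;
    for (int j = a + 1; j < b; ++j) {
      double chord = a + (x[j - 1] - x[a - 1]) * slope;
      double t = chord - (double)j + 1.0;  // upper chord vs lower corner j
      if (t > dmax) dmax = t;
    }
  }
  return dmax;
}

// Core: x must be sorted ascending, finite, n >= 2.  Returns dip.
static double dip_sorted_core(const std::vector<double>& x) {
  const int n = (int)x.size();
  if (n < 2) return 0.0;
  if (x.front() == x.back()) return 0.5 / n;  // degenerate: all values tied

  int lo = 1, hi = n;
  double dip = 1.0;  // count units; true minimum is 1 => 1/(2n) at the end

  std::vector<int> gcm, lcm;
  for (int iter = 0; iter < 2 * n + 10; ++iter) {
    lower_hull(x, lo, hi, gcm);
    upper_hull(x, lo, hi, lcm);

    // largest gap between the LCM curve (upper corners) and the GCM curve
    // (lower corners) inside [lo, hi]
    double d = 0.0;
    int new_lo = lo, new_hi = hi;
    for (size_t s = 0; s < lcm.size(); ++s) {
      int v = lcm[s];
      int gl, gr;
      double gv = hull_value_at(x, gcm, v, &gl, &gr);
      double gap = (double)v - gv + 1.0;
      if (gap > d) { d = gap; new_lo = gl; new_hi = v; }
    }
    for (size_t s = 0; s < gcm.size(); ++s) {
      int w = gcm[s];
      int ll, lr;
      double lv = hull_value_at(x, lcm, w, &ll, &lr);
      double gap = lv - (double)w + 1.0;
      if (gap > d) { d = gap; new_lo = w; new_hi = lr; }
    }

    if (d <= dip) break;

    // deviations outside the candidate modal interval
    double dip_l = convex_side_dip(x, gcm, lo, new_lo);
    double dip_u = concave_side_dip(x, lcm, new_hi, hi);
    double dip_new = std::max(dip_l, dip_u);
    if (dip_new > dip) dip = dip_new;

    if (new_lo == lo && new_hi == hi) break;  // no shrink: settled
    lo = new_lo;
    hi = new_hi;
  }
  return dip / (2.0 * n);
}

}  // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector values, bool sorted = false) {
  std::vector<double> x(values.begin(), values.end());
  for (double v : x)
    if (!std::isfinite(v)) stop("dip statistic requires finite values");
  if (!sorted) std::sort(x.begin(), x.end());
  return dip_sorted_core(x);
}

// Monte-Carlo null dips: B samples of size n from the standard uniform,
// generated pre-sorted via the exponential-spacings construction so no sort
// is needed.  Uses R's RNG stream (respects set.seed()).
// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int B) {
  if (n < 2) stop("n must be >= 2");
  if (B < 1) stop("B must be >= 1");
  NumericVector out(B);
  std::vector<double> x(n);
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      acc += exp_rand();
      x[i] = acc;
    }
    double total = acc + exp_rand();
    for (int i = 0; i < n; ++i) x[i] /= total;
    out[b] = dip_sorted_core(x);
  }
  return out;
}
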
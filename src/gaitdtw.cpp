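#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double local_cost(double x, double y, int cost_type) {
  double d = x - y;
  return cost_type == 2 ? d * d : std::fabs(d);
}

// Accumulated-cost matrix for the symmetric step pattern {(1,0),(0,1),(1,1)}.
// band < 0 disables the Sakoe-Chiba constraint; otherwise cells with
// |i - j| > band are unreachable (Inf).
// [[Rcpp::export]]
NumericMatrix dtw_cost_matrix_cpp(NumericVector a, NumericVector b,
                                  int cost_type, int band) {
  int n = a.size(), m = b.size();
  NumericMatrix D(n, m);
  std::fill(D.begin(), D.end(), R_PosInf);
  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (band >= 0) {
      jlo = std::max(0, i - band);
      jhi = std::min(m - 1, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = R_PosInf;
        if (i > 0) best = std::min(best, D(i - 1, j));
        if (j > 0) best = std::min(best, D(i, j - 1));
        if (i > 0 && j > 0) best = std::min(best, D(i - 1, j - 1));
      }
      D(i, j) = local_cost(a[i], b[j], cost_type) + best;
    }
  }
  return D;
}

// Distance only, O(m) memory; used for medoid search and cohort scoring.
// [[Rcpp::export]]
double dtw_distance_cpp(NumericVector a, NumericVector b, int cost_type,
                        int band) {
  int n = a.size(), m = b.size();
  std::vector<double> prev(m, R_PosInf), cur(m, R_PosInf);
  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (band >= 0) {
      jlo = std::max(0, i - band);
      jhi = std::min(m - 1, i + band);
    }
    std::fill(cur.begin(), cur.end(), R_PosInf);
    for (int j = jlo; j <= jhi; ++j) {
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = R_PosInf;
        if (i > 0) best = std::min(best, prev[j]);
        if (j > 0) best = std::min(best, cur[j - 1]);
        if (i > 0 && j > 0) best = std::min(best, prev[j - 1]);
      }
      cur[j] = local_cost(a[i], b[j], cost_type) + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// DTW distance of one reference against each series in a list.
// [[Rcpp::export]]
NumericVector dtw_distance_many_cpp(NumericVector ref, List series,
                                    int cost_type) {
  int k = series.size();
  NumericVector out(k);
  for (int s = 0; s < k; ++s)
    out[s] = dtw_distance_cpp(ref, series[s], cost_type, -1);
  return out;
}

// Full pairwise DTW distance matrix (symmetric, zero diagonal).
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(List series, int cost_type) {
  int k = series.size();
  NumericMatrix D(k, k);
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j) {
      double d = dtw_distance_cpp(series[i], series[j], cost_type, -1);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}

// Local maxima with topographic prominence and minimum separation.
// A sample is a candidate peak if strictly greater than both neighbours
// (left edge of a plateau wins). Prominence: drop to the highest valley
// separating the peak from any higher terrain on either side. Peaks below
// min_prom are discarded; remaining peaks are greedily kept from highest
// to lowest, suppressing any peak within min_dist samples of a kept one.
// Returns 1-based indices in ascending order.
// [[Rcpp::export]]
IntegerVector find_peaks_cpp(NumericVector x, int min_dist, double min_prom) {
  int n = x.size();
  std::vector<int> cand;
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1]) {
      int j = i;
      while (j < n - 1 && x[j + 1] == x[j]) ++j;
      if (j < n - 1 && x[j + 1] < x[i]) cand.push_back(i);
      i = j;
    }
  }
  std::vector<int> keep;
  for (size_t c = 0; c < cand.size(); ++c) {
    int p = cand[c];
    double h = x[p];
    double pass_at = h - min_prom;
    // side minimum runs until strictly higher terrain; once it drops to
    // pass_at the side cannot fail (extending a scan only lowers the min)
    double lmin = h, rmin = h;
    for (int i = p - 1; i >= 0; --i) {
      if (x[i] > h) break;
      if (x[i] < lmin) lmin = x[i];
      if (lmin <= pass_at) break;
    }
    for (int i = p + 1; i < n; ++i) {
      if (x[i] > h) break;
      if (x[i] < rmin) rmin = x[i];
      if (rmin <= pass_at) break;
    }
    if (h - std::max(lmin, rmin) >= min_prom) keep.push_back(p);
  }
  // order by height, then greedy non-maximum suppression at min_dist;
  // keep[] is sorted by position, so conflicts are a contiguous window
  std::vector<size_t> ord(keep.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t i, size_t j) {
    if (x[keep[i]] != x[keep[j]]) return x[keep[i]] > x[keep[j]];
    return keep[i] < keep[j];
  });
  std::vector<bool> taken(keep.size(), false), dead(keep.size(), false);
  for (size_t oi = 0; oi < ord.size(); ++oi) {
    size_t i = ord[oi];
    if (dead[i]) continue;
    taken[i] = true;
    for (size_t j = i; j-- > 0 && keep[i] - keep[j] < min_dist;)
      if (!taken[j]) dead[j] = true;
    for (size_t j = i + 1; j < keep.size() && keep[j] - keep[i] < min_dist; ++j)
      if (!taken[j]) dead[j] = true;
  }
  std::vector<int> out;
  for (size_t i = 0; i < keep.size(); ++i)
    if (taken[i]) out.push_back(keep[i] + 1);
  std::sort(out.begin(), out.end());
  return wrap(out);
}
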
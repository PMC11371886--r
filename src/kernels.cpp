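#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sequential artifact filter: a beat is kept when inside [lo, hi], labelled
// normal, and within rel * (running median of the last `window` accepted
// intervals). The very first accepted beat is judged on bounds/label only.
// [[Rcpp::export]]
LogicalVector cpp_median_filter(NumericVector x, LogicalVector non_normal,
                                double lo, double hi, double rel, int window) {
  int n = x.size();
  LogicalVector keep(n);
  std::vector<double> acc;
  std::vector<double> buf;
  acc.reserve(n);
  for (int i = 0; i < n; ++i) {
    bool ok = x[i] >= lo && x[i] <= hi && !non_normal[i];
    if (ok && !acc.empty()) {
      int w = std::min<int>(window, acc.size());
      buf.assign(acc.end() - w, acc.end());
      std::nth_element(buf.begin(), buf.begin() + w / 2, buf.end());
      double med = buf[w / 2];
      if (w % 2 == 0) {
        double lowmax = *std::max_element(buf.begin(), buf.begin() + w / 2);
        med = (med + lowmax) / 2.0;
      }
      if (std::fabs(x[i] - med) > rel * med) ok = false;
    }
    keep[i] = ok;
    if (ok) acc.push_back(x[i]);
  }
  return keep;
}

// Sample entropy template counts: B = ordered pairs (i != j) of m-templates
// within Chebyshev distance r, A = same for (m+1)-templates, both over the
// first N - m template start points (Richman & Moorman convention).
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // number of templates of length m and m+1 considered
  double A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0;
      bool okm = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { okm = false; break; }
      }
      if (!okm) continue;
      B += 1;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1;
    }
  }
  return NumericVector::create(2 * A, 2 * B);  // ordered-pair counts
}

// Correlation sums C(r) for sorted radii, Chebyshev metric on a delay
// embedding (dimension m, delay lag), excluding pairs with |i - j| <= theiler.
// [[Rcpp::export]]
NumericVector cpp_corr_sums(NumericVector x, int m, int lag,
                            NumericVector radii, int theiler) {
  int n = x.size();
  int np = n - (m - 1) * lag;  // number of embedded points
  int nr = radii.size();
  std::vector<double> counts(nr, 0.0);
  double npairs = 0;
  for (int i = 0; i < np - 1; ++i) {
    for (int j = i + 1; j < np; ++j) {
      if (j - i <= theiler) continue;
      npairs += 1;
      double d = 0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k * lag] - x[j + k * lag]);
        if (dd > d) d = dd;
      }
      // first radius >= d
      int pos = std::lower_bound(radii.begin(), radii.end(), d) -
                radii.begin();
      if (pos < nr) counts[pos] += 1;
    }
  }
  NumericVector C(nr);
  double cum = 0;
  for (int k = 0; k < nr; ++k) {
    cum += counts[k];
    C[k] = npairs > 0 ? cum / npairs : NA_REAL;
  }
  return C;
}

// Cao's E(d): mean over reference points of the ratio of the (d+1)- to
// d-dimensional Chebyshev distance to the d-dimensional nearest neighbour.
// Reference points are an evenly spaced subset of size <= n_ref.
// [[Rcpp::export]]
double cpp_cao_E(NumericVector x, int lag, int d, int n_ref) {
  int n = x.size();
  int np = n - d * lag;  // points embeddable in both d and d+1 dims
  if (np < 3) return NA_REAL;
  int nref = std::min(n_ref, np);
  double stride = (double)np / nref;
  double sum = 0;
  int used = 0;
  for (int ri = 0; ri < nref; ++ri) {
    int i = (int)(ri * stride);
    double best = R_PosInf;
    int bestj = -1;
    for (int j = 0; j < np; ++j) {
      if (j == i) continue;
      double dist = 0;
      for (int k = 0; k < d; ++k) {
        double dd = std::fabs(x[i + k * lag] - x[j + k * lag]);
        if (dd > dist) dist = dd;
        if (dist >= best) break;
      }
      if (dist > 0 && dist < best) { best = dist; bestj = j; }
    }
    if (bestj < 0 || !R_finite(best)) continue;
    double dist1 = 0;
    for (int k = 0; k <= d; ++k) {
      double dd = std::fabs(x[i + k * lag] - x[bestj + k * lag]);
      if (dd > dist1) dist1 = dd;
    }
    sum += dist1 / best;
    used += 1;
  }
  return used > 0 ? sum / used : NA_REAL;
}

// Rosenstein mean log divergence: for each embedded point, the nearest
// neighbour (Euclidean) outside the Theiler window and within `radius`;
// returns mean log divergence at iterations 0..kmax and the fraction of
// points without an admissible neighbour.
// [[Rcpp::export]]
List cpp_rosenstein(NumericVector x, int m, int lag, double radius,
                    int theiler, int kmax) {
  int n = x.size();
  int np = n - (m - 1) * lag;
  std::vector<double> logsum(kmax + 1, 0.0);
  std::vector<int> logcnt(kmax + 1, 0);
  int no_nb = 0, total = 0;
  double r2 = radius * radius;
  for (int i = 0; i < np; ++i) {
    total += 1;
    double best = R_PosInf;
    int bestj = -1;
    for (int j = 0; j < np; ++j) {
      if (std::abs(j - i) <= theiler) continue;
      double dist = 0;
      for (int k = 0; k < m; ++k) {
        double dd = x[i + k * lag] - x[j + k * lag];
        dist += dd * dd;
        if (dist >= best) break;
      }
      if (dist > 0 && dist < best && dist <= r2) { best = dist; bestj = j; }
    }
    if (bestj < 0) { no_nb += 1; continue; }
    for (int k = 0; k <= kmax; ++k) {
      if (i + k >= np || bestj + k >= np) break;
      double dist = 0;
      for (int c = 0; c < m; ++c) {
        double dd = x[i + k + c * lag] - x[bestj + k + c * lag];
        dist += dd * dd;
      }
      if (dist > 0) {
        logsum[k] += 0.5 * std::log(dist);
        logcnt[k] += 1;
      }
    }
  }
  NumericVector mld(kmax + 1);
  for (int k = 0; k <= kmax; ++k)
    mld[k] = logcnt[k] > 0 ? logsum[k] / logcnt[k] : NA_REAL;
  return List::create(_["mean_log_div"] = mld,
                      _["frac_no_neighbor"] =
                          total > 0 ? (double)no_nb / total : 1.0);
}

// Two-sample log-rank statistics for candidate splits x <= cut vs x > cut.
// time/event/x must be sorted by ascending time. Returns the signed
// standardized statistic (O - E)/sqrt(V) for the left (x <= cut) group.
// [[Rcpp::export]]
NumericVector cpp_logrank_stats(NumericVector time, IntegerVector event,
                                NumericVector x, NumericVector cuts) {
  int n = time.size();
  int nc = cuts.size();
  NumericVector out(nc);
  std::vector<int> suffix(n + 1);
  for (int c = 0; c < nc; ++c) {
    double cut = cuts[c];
    suffix[n] = 0;
    for (int i = n - 1; i >= 0; --i)
      suffix[i] = suffix[i + 1] + (x[i] <= cut ? 1 : 0);
    double OmE = 0, V = 0;
    int i = 0;
    while (i < n) {
      int j = i;
      int d = 0, d1 = 0;
      while (j < n && time[j] == time[i]) {
        if (event[j]) { d += 1; if (x[j] <= cut) d1 += 1; }
        ++j;
      }
      if (d > 0) {
        double nt = n - i;
        double n1 = suffix[i];
        OmE += d1 - d * n1 / nt;
        if (nt > 1)
          V += d * (n1 / nt) * (1 - n1 / nt) * (nt - d) / (nt - 1);
      }
      i = j;
    }
    out[c] = V > 0 ? OmE / std::sqrt(V) : 0.0;
  }
  return out;
}
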
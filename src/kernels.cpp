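#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Spike times are trial-relative milliseconds; sample i (0-based) covers
// [i/fs, (i+1)/fs) seconds, so a spike at t ms maps to floor(t * fs / 1000).

// [[Rcpp::export]]
NumericVector cpp_sta(NumericVector spike_ms, NumericVector z, double fs,
                      int half) {
  int n = z.size(), m = spike_ms.size(), w = 2 * half + 1;
  NumericVector out(w);
  for (int s = 0; s < m; ++s) {
    int i0 = (int)std::floor(spike_ms[s] * fs / 1000.0);
    int lo = std::max(0, i0 - half), hi = std::min(n - 1, i0 + half);
    for (int idx = lo; idx <= hi; ++idx) out[idx - i0 + half] += z[idx];
  }
  if (m > 0)
    for (int k = 0; k < w; ++k) out[k] /= (double)m;
  return out;
}

// Reconstruction: place one filter row at every spike and sum.
// `row` holds a 1-based bank-row index per spike (length 1 = shared row).
// [[Rcpp::export]]
NumericVector cpp_recon(NumericVector spike_ms, NumericMatrix coefs,
                        IntegerVector row, double fs, int n) {
  int m = spike_ms.size(), w = coefs.ncol(), half = (w - 1) / 2;
  NumericVector out(n);
  for (int s = 0; s < m; ++s) {
    int r = (row.size() == 1 ? row[0] : row[s]) - 1;
    int i0 = (int)std::floor(spike_ms[s] * fs / 1000.0);
    int lo = std::max(0, i0 - half), hi = std::min(n - 1, i0 + half);
    for (int idx = lo; idx <= hi; ++idx) out[idx] += coefs(r, idx - i0 + half);
  }
  return out;
}

static void rank_avg(const double* x, int n, double* r) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [x](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    i = j + 1;
  }
}

// Average ranks (ties share the mean rank), as rank(x, ties.method = "average").
// [[Rcpp::export]]
NumericVector cpp_rank(NumericVector x) {
  int n = x.size();
  NumericVector r(n);
  rank_avg(REAL(x), n, REAL(r));
  return r;
}

static double spearman_vs_rank(const double* xr, const double* y, int n,
                               std::vector<double>& scratch) {
  scratch.resize(n);
  rank_avg(y, n, scratch.data());
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += xr[i]; my += scratch[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    double dx = xr[i] - mx, dy = scratch[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// Spearman cc of y against precomputed ranks xr; NA if either side constant.
// [[Rcpp::export]]
double cpp_spearman(NumericVector xr, NumericVector y) {
  std::vector<double> scratch;
  return spearman_vs_rank(REAL(xr), REAL(y), xr.size(), scratch);
}

// Batched decode: for each spike-time vector, place its filter row(s) and
// correlate the reconstruction with the gauge ranks. `rows` parallels
// `trains` (each element length 1 or the train length, 1-based).
// [[Rcpp::export]]
NumericVector cpp_decode_many(List trains, List rows, NumericMatrix coefs,
                              double fs, int n, NumericVector zg_rank) {
  int m = trains.size();
  NumericVector out(m);
  std::vector<double> recon(n), scratch;
  int w = coefs.ncol(), half = (w - 1) / 2;
  for (int k = 0; k < m; ++k) {
    NumericVector t = trains[k];
    if (t.size() == 0) { out[k] = NA_REAL; continue; }
    IntegerVector rk = rows[k];
    std::fill(recon.begin(), recon.end(), 0.0);
    const double* cp = REAL(coefs);
    int nr = coefs.nrow();
    for (int s = 0; s < t.size(); ++s) {
      int r = (rk.size() == 1 ? rk[0] : rk[s]) - 1;
      int i0 = (int)std::floor(t[s] * fs / 1000.0);
      int lo = std::max(0, i0 - half), hi = std::min(n - 1, i0 + half);
      for (int idx = lo; idx <= hi; ++idx)
        recon[idx] += cp[r + (std::size_t)(idx - i0 + half) * nr];
    }
    out[k] = spearman_vs_rank(REAL(zg_rank), recon.data(), n, scratch);
  }
  return out;
}

// Sum of unit-mass Gaussians (density per ms) on the analysis grid,
// truncated at 10 SD (relative error < 1e-22).
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector spike_ms, int n, double fs,
                               double sigma_ms) {
  NumericVector out(n);
  double dt = 1000.0 / fs;  // ms per sample
  double norm = 1.0 / (sigma_ms * std::sqrt(2.0 * M_PI));
  double inv2s2 = 1.0 / (2.0 * sigma_ms * sigma_ms);
  int halfw = (int)std::ceil(10.0 * sigma_ms / dt);
  for (int s = 0; s < spike_ms.size(); ++s) {
    double t = spike_ms[s];
    int ic = (int)std::floor(t / dt);
    int lo = std::max(0, ic - halfw), hi = std::min(n - 1, ic + halfw);
    for (int idx = lo; idx <= hi; ++idx) {
      double d = idx * dt - t;
      out[idx] += norm * std::exp(-d * d * inv2s2);
    }
  }
  return out;
}

// Count cross-correlogram with bins centered on multiples of bin_ms,
// half-open [c - bin/2, c + bin/2). Inputs must be sorted ascending.
// Self-pairs (identical index when pre and post are the same vector) ARE
// counted; callers computing an ACH for display should zero the centre bin.
// [[Rcpp::export]]
IntegerVector cpp_cch(NumericVector pre, NumericVector post, double bin_ms,
                      double half_range_ms) {
  int nb = (int)std::lround(half_range_ms / bin_ms);
  IntegerVector counts(2 * nb + 1);
  double lo = -(nb + 0.5) * bin_ms, hi = (nb + 0.5) * bin_ms;
  int np = post.size(), j0 = 0;
  for (int i = 0; i < pre.size(); ++i) {
    while (j0 < np && post[j0] - pre[i] < lo) ++j0;
    for (int j = j0; j < np; ++j) {
      double d = post[j] - pre[i];
      if (d >= hi) break;
      int k = (int)std::floor(d / bin_ms + 0.5);
      if (k >= -nb && k <= nb) ++counts[k + nb];
    }
  }
  return counts;
}
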
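#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Nonlinear time-series features. These are the per-epoch, per-channel
// workhorses of the pipeline; they run ~10^5 times per cohort, hence C++.
// All distance conventions follow the Richman-Moorman (SampEn, Chebyshev,
// strict d < r) and Chen (FuzzyEn, mean-centred templates, exponential
// similarity) definitions.
// ---------------------------------------------------------------------------

static double vec_median(std::vector<double> v) {
  const size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.end());
  return 0.5 * (hi + v[n / 2 - 1]);
}

// Kaspar-Schuster scan counting new subsequences in a symbol string; the
// trailing incomplete word counts as one.
// [[Rcpp::export]]
int cpp_lzc_count(IntegerVector bits) {
  const int n = bits.size();
  std::vector<char> s(n);
  for (int i = 0; i < n; ++i) s[i] = (char)bits[i];
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  bool stop = false;
  while (!stop) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; stop = true; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) { stop = true; }
        else { i = 0; k = 1; kmax = 1; }
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Lempel-Ziv complexity of the median-binarized series, normalized by
// N / log2(N).
// [[Rcpp::export]]
double cpp_lzc(NumericVector x) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  const double med = vec_median(v);
  IntegerVector bits(n);
  for (int i = 0; i < n; ++i) bits[i] = (x[i] >= med) ? 1 : 0;
  return (double)cpp_lzc_count(bits) / ((double)n / std::log2((double)n));
}

// Fraction of first-difference scatter points within radius rho.
// [[Rcpp::export]]
double cpp_ctm(NumericVector x, double rho) {
  const int n = x.size();
  long cnt = 0;
  for (int i = 0; i + 2 < n; ++i) {
    const double d1 = x[i + 1] - x[i];
    const double d2 = x[i + 2] - x[i + 1];
    if (std::sqrt(d1 * d1 + d2 * d2) < rho) ++cnt;
  }
  return (double)cnt / (double)(n - 2);
}

// Sample entropy, template pairs over i<j in 1..N-m, Chebyshev distance,
// strict d < r. Pairs are enumerated through a sort on the first template
// element (only pairs with |x_i - x_j| < r can match), which prunes the
// O(N^2) scan to the matching neighbourhoods; the counts are exact
// integers, so the result is identical to the naive double loop.
// Returns NA when no matches exist at either length.
// [[Rcpp::export]]
double cpp_sampen(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nm = n - m;
  std::vector<int> ord(nm);
  for (int i = 0; i < nm; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  long A = 0, B = 0;
  int lo = 0;
  for (int b = 1; b < nm; ++b) {
    const int j = ord[b];
    while (x[j] - x[ord[lo]] >= r) ++lo;
    for (int a = lo; a < b; ++a) {
      const int i = ord[a];
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) >= r) { match = false; break; }
      }
      if (match) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) < r) ++A;
      }
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

// Fuzzy entropy (Chen et al. convention): N-m mean-centred templates at both
// lengths m and m+1, similarity exp(-d^n / r), FuzzyEn = ln phi_m - ln phi_m1.
// Shared pair normalization cancels, so pair sums suffice.
static inline double int_pow(double d, double nexp) {
  if (nexp == 1.0) return d;
  if (nexp == 2.0) return d * d;
  if (nexp == 3.0) return d * d * d;
  return std::pow(d, nexp);
}

// exp(-z) underflows to exactly 0 for z > ~745.2; skipping the call there
// is bit-identical and avoids most exp() work for distant template pairs.
static inline double exp_sim(double d, double nexp, double inv_r) {
  const double z = int_pow(d, nexp) * inv_r;
  return (z > 746.0) ? 0.0 : std::exp(-z);
}

// [[Rcpp::export]]
double cpp_fuzzyen(NumericVector x, int m, double r, double nexp) {
  const int n = x.size();
  const int nm = n - m;
  const double inv_r = 1.0 / r;
  // centred templates: tm = length-m rows, tm1 = length-(m+1) rows
  std::vector<double> tm((size_t)nm * m), tm1((size_t)nm * (m + 1));
  for (int i = 0; i < nm; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    const double mu_m = s / m, mu_m1 = (s + x[i + m]) / (m + 1);
    for (int k = 0; k < m; ++k) tm[(size_t)i * m + k] = x[i + k] - mu_m;
    for (int k = 0; k <= m; ++k) tm1[(size_t)i * (m + 1) + k] = x[i + k] - mu_m1;
  }
  double sum_m = 0.0, sum_m1 = 0.0;
  for (int i = 0; i < nm - 1; ++i) {
    const double* ti = &tm[(size_t)i * m];
    const double* ti1 = &tm1[(size_t)i * (m + 1)];
    for (int j = i + 1; j < nm; ++j) {
      const double* tj = &tm[(size_t)j * m];
      const double* tj1 = &tm1[(size_t)j * (m + 1)];
      if (m == 1) {
        sum_m += 1.0;  // single-point centred templates are all zero
      } else {
        double dm = 0.0;
        for (int k = 0; k < m; ++k) {
          const double d = std::fabs(ti[k] - tj[k]);
          if (d > dm) dm = d;
        }
        sum_m += exp_sim(dm, nexp, inv_r);
      }
      double dm1 = 0.0;
      for (int k = 0; k <= m; ++k) {
        const double d = std::fabs(ti1[k] - tj1[k]);
        if (d > dm1) dm1 = d;
      }
      sum_m1 += exp_sim(dm1, nexp, inv_r);
    }
  }
  return std::log(sum_m) - std::log(sum_m1);
}

// Auto-mutual information profile over lags 0..max_lag via an equal-width
// 2-D histogram (bins per axis, edges from the full series range). Base-2
// logs; marginals taken from each lag's own pair set.
// [[Rcpp::export]]
NumericVector cpp_ami_profile(NumericVector x, int max_lag, int bins) {
  const int n = x.size();
  double mn = x[0], mx = x[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < mn) mn = x[i];
    if (x[i] > mx) mx = x[i];
  }
  NumericVector out(max_lag + 1);
  if (mx <= mn) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  const double width = (mx - mn) / bins;
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) {
    int bi = (int)((x[i] - mn) / width);
    if (bi >= bins) bi = bins - 1;
    b[i] = bi;
  }
  std::vector<double> joint(bins * bins), pi(bins), pj(bins);
  for (int k = 0; k <= max_lag; ++k) {
    std::fill(joint.begin(), joint.end(), 0.0);
    std::fill(pi.begin(), pi.end(), 0.0);
    std::fill(pj.begin(), pj.end(), 0.0);
    const int np = n - k;
    for (int t = 0; t < np; ++t) joint[b[t] * bins + b[t + k]] += 1.0;
    for (int u = 0; u < bins; ++u)
      for (int v = 0; v < bins; ++v) {
        pi[u] += joint[u * bins + v];
        pj[v] += joint[u * bins + v];
      }
    double mi = 0.0;
    for (int u = 0; u < bins; ++u) {
      if (pi[u] == 0) continue;
      for (int v = 0; v < bins; ++v) {
        const double c = joint[u * bins + v];
        if (c == 0 || pj[v] == 0) continue;
        mi += (c / np) * std::log2(c * np / (pi[u] * pj[v]));
      }
    }
    out[k] = mi;
  }
  return out;
}

// All five nonlinear features for one epoch, one column per channel.
// data is samples x channels. SampEn/FuzzyEn tolerances scale with the
// channel SD; CTM optionally runs on the z-scored channel. ami_summary:
// 0 = mean of the normalized profile over lags >= 1, 1 = least-squares
// slope of the normalized profile vs lag (in s^-1, lag_dt = 1/fs).
// [[Rcpp::export]]
NumericMatrix cpp_nonlinear_channels(NumericMatrix data, double ctm_rho,
                                     bool ctm_norm, int se_m, double se_r,
                                     int fe_m, double fe_r, double fe_n,
                                     int ami_max_lag, int ami_bins,
                                     int ami_summary, double lag_dt) {
  const int n = data.nrow(), nch = data.ncol();
  NumericMatrix out(5, nch);
  rownames(out) = CharacterVector::create("LZC", "CTM", "SampEn", "FuzzyEn", "AMI");
  for (int ch = 0; ch < nch; ++ch) {
    NumericVector x = data(_, ch);
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += x[i];
    mean /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += (x[i] - mean) * (x[i] - mean);
    const double sd = std::sqrt(ss / (n - 1));
    if (sd == 0.0) {
      out(0, ch) = NA_REAL; out(1, ch) = 1.0; out(2, ch) = 0.0;
      out(3, ch) = 0.0; out(4, ch) = NA_REAL;
      continue;
    }
    out(0, ch) = cpp_lzc(x);
    if (ctm_norm) {
      NumericVector z(n);
      for (int i = 0; i < n; ++i) z[i] = (x[i] - mean) / sd;
      out(1, ch) = cpp_ctm(z, ctm_rho);
    } else {
      out(1, ch) = cpp_ctm(x, ctm_rho);
    }
    out(2, ch) = cpp_sampen(x, se_m, se_r * sd);
    out(3, ch) = cpp_fuzzyen(x, fe_m, fe_r * sd, fe_n);
    NumericVector prof = cpp_ami_profile(x, ami_max_lag, ami_bins);
    if (NumericVector::is_na(prof[0]) || prof[0] <= 0.0) {
      out(4, ch) = NA_REAL;
    } else {
      const int K = ami_max_lag;
      if (ami_summary == 0) {
        double s = 0.0;
        for (int k = 1; k <= K; ++k) s += prof[k] / prof[0];
        out(4, ch) = s / K;
      } else {
        // slope of normalized profile vs lag in seconds, lags 0..K
        double sx = 0.0, sy = 0.0, sxx = 0.0, sxy = 0.0;
        const int np = K + 1;
        for (int k = 0; k <= K; ++k) {
          const double t = k * lag_dt, y = prof[k] / prof[0];
          sx += t; sy += y; sxx += t * t; sxy += t * y;
        }
        out(4, ch) = (np * sxy - sx * sy) / (np * sxx - sx * sx);
      }
    }
  }
  return out;
}
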
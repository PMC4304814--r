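#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double median_inplace(double* v, int n) {
  if (n == 0) return 0.0;
  const int mid = n / 2;
  std::nth_element(v, v + mid, v + n);
  double hi = v[mid];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v, v + mid);
  return 0.5 * (lo + hi);
}

// Pointwise median across latency-aligned residual trials.
//
// x: trial x channel x time array (dim attribute set).
// others: list of channel x time cluster waveforms to subtract.
// other_shifts: trial x K integer matrix of per-trial sample shifts for the
//   subtracted clusters (waveform k in trial i sits at +other_shifts(i,k)).
// target_shifts: per-trial sample shifts of the cluster being estimated;
//   trial i is read at time t + target_shifts[i] so the result lives in the
//   cluster's aligned (template) frame.
// Samples falling outside the epoch are dropped from the median. `taper`
// (length ns) is the cluster's window weight: zero-weight samples are
// skipped and the median is scaled by the weight.
// [[Rcpp::export]]
NumericMatrix cpp_cluster_median(NumericVector x, List others,
                                 IntegerMatrix other_shifts,
                                 IntegerVector target_shifts,
                                 NumericVector taper) {
  IntegerVector d = x.attr("dim");
  const int nt = d[0], nc = d[1], ns = d[2];
  const int K = others.size();
  std::vector<NumericMatrix> w(K);
  for (int k = 0; k < K; ++k) w[k] = as<NumericMatrix>(others[k]);
  NumericMatrix out(nc, ns);
  std::vector<double> buf(nt);
  const double* xp = REAL(x);
  for (int c = 0; c < nc; ++c) {
    for (int t = 0; t < ns; ++t) {
      if (taper[t] == 0.0) { out(c, t) = 0.0; continue; }
      int n = 0;
      for (int i = 0; i < nt; ++i) {
        const int tau = t + target_shifts[i];        // source sample in epoch
        if (tau < 0 || tau >= ns) continue;
        double v = xp[(R_xlen_t)i +
                      (R_xlen_t)nt * ((R_xlen_t)c + (R_xlen_t)nc * tau)];
        for (int k = 0; k < K; ++k) {
          const int tk = tau - other_shifts(i, k);
          if (tk >= 0 && tk < ns) v -= w[k](c, tk);
        }
        buf[n++] = v;
      }
      out(c, t) = taper[t] * median_inplace(buf.data(), n);
    }
  }
  return out;
}

// Trial-average of the summed clusters, each shifted to its per-trial
// latency: the model's prediction of the conventional average.
// waves: list of channel x time matrices; shifts: trial x K sample shifts.
// [[Rcpp::export]]
NumericMatrix cpp_model_average(List waves, IntegerMatrix shifts,
                                int nc, int ns) {
  const int K = waves.size();
  const int nt = shifts.nrow();
  std::vector<NumericMatrix> w(K);
  for (int k = 0; k < K; ++k) w[k] = as<NumericMatrix>(waves[k]);
  NumericMatrix out(nc, ns);
  for (int i = 0; i < nt; ++i) {
    for (int k = 0; k < K; ++k) {
      const int s = shifts(i, k);
      for (int t = 0; t < ns; ++t) {
        const int src = t - s;
        if (src >= 0 && src < ns) {
          for (int c = 0; c < nc; ++c) out(c, t) += w[k](c, src);
        }
      }
    }
  }
  const double inv = 1.0 / nt;
  for (int c = 0; c < nc; ++c)
    for (int t = 0; t < ns; ++t) out(c, t) *= inv;
  return out;
}

// Per-trial residuals x_i - sum_k shift(w_k, s_ik); returns an array shaped
// like x.
// [[Rcpp::export]]
NumericVector cpp_residuals(NumericVector x, List waves,
                            IntegerMatrix shifts) {
  IntegerVector d = x.attr("dim");
  const int nt = d[0], nc = d[1], ns = d[2];
  const int K = waves.size();
  std::vector<NumericMatrix> w(K);
  for (int k = 0; k < K; ++k) w[k] = as<NumericMatrix>(waves[k]);
  NumericVector out = clone(x);
  for (int i = 0; i < nt; ++i) {
    for (int k = 0; k < K; ++k) {
      const int s = shifts(i, k);
      for (int t = std::max(0, s); t < std::min(ns, ns + s); ++t) {
        const int src = t - s;
        for (int c = 0; c < nc; ++c)
          out[(R_xlen_t)i + (R_xlen_t)nt * ((R_xlen_t)c + (R_xlen_t)nc * t)] -=
            w[k](c, src);
      }
    }
  }
  out.attr("dim") = d;
  return out;
}
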
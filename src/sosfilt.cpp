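#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed biquad cascade. sos is n_sections x 6
// (b0 b1 b2 a0 a1 a2) with a0 == 1. State zi (2 per section) starts at zero.
static void run_sos(const NumericMatrix& sos, double* x, R_xlen_t n) {
  const int ns = sos.nrow();
  std::vector<double> b0(ns), b1(ns), b2(ns), a1(ns), a2(ns);
  for (int s = 0; s < ns; ++s) {
    b0[s] = sos(s, 0); b1[s] = sos(s, 1); b2[s] = sos(s, 2);
    a1[s] = sos(s, 4); a2[s] = sos(s, 5);
  }
  std::vector<double> z1(ns, 0.0), z2(ns, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    for (int s = 0; s < ns; ++s) {
      const double y = b0[s] * v + z1[s];
      z1[s] = b1[s] * v - a1[s] * y + z2[s];
      z2[s] = b2[s] * v - a2[s] * y;
      v = y;
    }
    x[i] = v;
  }
}

// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  NumericVector y = clone(x);
  run_sos(sos, y.begin(), y.size());
  return y;
}

// Zero-phase forward-backward SOS filter with odd (antisymmetric) edge
// extension of `padlen` samples at each end, as in the classic filtfilt
// edge treatment. Returns a vector the same length as x.
// [[Rcpp::export(name = ".sosfiltfilt_cpp")]]
NumericVector sosfiltfilt_cpp(NumericMatrix sos, NumericVector x, int padlen) {
  const R_xlen_t n = x.size();
  if (padlen < 0) stop("padlen must be >= 0");
  if (padlen > n - 1) padlen = (int)(n - 1);
  const R_xlen_t m = n + 2 * (R_xlen_t)padlen;
  std::vector<double> buf(m);
  // odd extension: 2*x[0] - x[padlen..1], x, 2*x[n-1] - x[n-2..n-1-padlen]
  for (R_xlen_t i = 0; i < padlen; ++i)
    buf[i] = 2.0 * x[0] - x[padlen - i];
  for (R_xlen_t i = 0; i < n; ++i) buf[padlen + i] = x[i];
  for (R_xlen_t i = 0; i < padlen; ++i)
    buf[padlen + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  run_sos(sos, buf.data(), m);
  std::reverse(buf.begin(), buf.end());
  run_sos(sos, buf.data(), m);
  std::reverse(buf.begin(), buf.end());
  NumericVector y(n);
  for (R_xlen_t i = 0; i < n; ++i) y[i] = buf[padlen + i];
  return y;
}

// Accumulate per-(window, phase-bin) amplitude sums and counts in one pass.
// ph, am: decimated phase/amplitude series; win: 1-based window id per
// sample (0 = outside any scored window). Bins tile (-pi, pi] uniformly.
// [[Rcpp::export(name = ".pa_accumulate_cpp")]]
List pa_accumulate_cpp(NumericVector ph, NumericVector am, IntegerVector win,
                       int n_bins, int n_win) {
  const R_xlen_t n = ph.size();
  IntegerVector counts(n_bins * n_win);
  NumericVector sums(n_bins * n_win);
  const double scale = n_bins / (2.0 * M_PI);
  for (R_xlen_t i = 0; i < n; ++i) {
    const int w = win[i];
    if (w < 1 || w > n_win) continue;
    const double p = ph[i];
    if (!R_finite(p) || !R_finite(am[i])) continue;
    int b = (int)std::floor((p + M_PI) * scale);
    if (b < 0) b = 0;
    if (b >= n_bins) b = n_bins - 1;
    const R_xlen_t k = (R_xlen_t)(w - 1) * n_bins + b;
    counts[k] += 1;
    sums[k] += am[i];
  }
  return List::create(_["counts"] = counts, _["sums"] = sums);
}

// Compose one synthetic channel in a single pass and write it into row
// `ch` (1-based) of the channels-x-samples signal matrix:
//   sig[ch, i] = base[i] + fast_amp * carrier[i] * carrier_scale * env[i]
//                + N(0, noise_sd)
// with env = max(0, 1 + depth * cos(phase_slow - phi)), where phi is the
// interictal coupling phase except inside the (sorted, disjoint) preictal
// sample ranges [pre_start, pre_end] (1-based, inclusive), which use the
// preictal phase. cos/sin of the slow phase are passed precomputed. The
// white measurement noise is drawn inline from R's RNG (one draw per
// sample, in sample order, exactly as rnorm(n) would).
// [[Rcpp::export(name = ".compose_channel_cpp")]]
void compose_channel_cpp(NumericMatrix sig, int ch, NumericVector base,
                         NumericVector cos_ph, NumericVector sin_ph,
                         NumericVector carrier, double carrier_scale,
                         double noise_sd, double depth, double fast_amp,
                         double cphi0, double sphi0,
                         IntegerVector pre_start, IntegerVector pre_end,
                         double cphi1, double sphi1) {
  const R_xlen_t n = base.size();
  const int nch = sig.nrow();
  double* out = &sig(ch - 1, 0);
  const int nseg = pre_start.size();
  const double amp = fast_amp * carrier_scale;
  int seg = 0;
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    while (seg < nseg && (R_xlen_t)pre_end[seg] < i + 1) ++seg;
    const bool pre = seg < nseg && (R_xlen_t)pre_start[seg] <= i + 1;
    const double c = pre ? cphi1 : cphi0;
    const double s = pre ? sphi1 : sphi0;
    double env = 1.0 + depth * (cos_ph[i] * c + sin_ph[i] * s);
    if (env < 0) env = 0;
    out[(R_xlen_t)i * nch] = base[i] + amp * carrier[i] * env +
      noise_sd * norm_rand();
  }
  PutRNGstate();
}
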
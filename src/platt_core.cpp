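#include <Rcpp.h>
#include <complex>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cascade of four identical first-order complex IIR stages per channel,
// y_c = b_c * (1 / (1 - p_c z^-1))^4 applied to a real input signal.
// Returns the complex band matrix (channels x samples). Samples are the
// outer loop so writes into the column-major result are contiguous.
// [[Rcpp::export]]
ComplexMatrix gt_cascade_cpp(NumericVector x, ComplexVector pole,
                             ComplexVector fir) {
  const int n = x.size();
  const int nch = pole.size();
  ComplexMatrix out(nch, n);
  Rcomplex *o = COMPLEX(out);
  const double *xp = REAL(x);
  // explicit real/imag arithmetic with per-channel register state
  // (std::complex multiplication lowers to a libgcc call with inf/nan
  // handling, an order of magnitude slower)
  for (int c = 0; c < nch; ++c) {
    const double ar = pole[c].r, ai = pole[c].i;
    const double br = fir[c].r, bi = fir[c].i;
    double s1r = 0, s1i = 0, s2r = 0, s2i = 0, s3r = 0, s3i = 0,
           s4r = 0, s4i = 0, tr, ti;
    Rcomplex *oc = o + c;
    for (int i = 0; i < n; ++i) {
      tr = xp[i] + ar * s1r - ai * s1i;
      ti = ar * s1i + ai * s1r;
      s1r = tr; s1i = ti;
      tr = s1r + ar * s2r - ai * s2i;
      ti = s1i + ar * s2i + ai * s2r;
      s2r = tr; s2i = ti;
      tr = s2r + ar * s3r - ai * s3i;
      ti = s2i + ar * s3i + ai * s3r;
      s3r = tr; s3i = ti;
      tr = s3r + ar * s4r - ai * s4i;
      ti = s3i + ar * s4i + ai * s4r;
      s4r = tr; s4i = ti;
      oc[(std::size_t)i * nch].r = br * s4r - bi * s4i;
      oc[(std::size_t)i * nch].i = br * s4i + bi * s4r;
    }
  }
  return out;
}

// Hold/decay envelope tracker: each new local maximum of the instantaneous
// amplitude is held for hold_ms, then decays at decay_db_per_ms until
// overtaken by the current amplitude. Onsets are taken instantaneously.
// [[Rcpp::export]]
NumericMatrix track_envelope_cpp(NumericMatrix amp, double fs,
                                 double hold_ms, double decay_db_per_ms) {
  const int nch = amp.nrow();
  const int n = amp.ncol();
  NumericMatrix out(nch, n);
  const double *a = REAL(amp);
  double *o = REAL(out);
  const int hold_samples = (int)std::lround(hold_ms * fs / 1000.0);
  const double decay_factor =
      std::pow(10.0, -decay_db_per_ms / (20.0 * fs / 1000.0));
  for (int c = 0; c < nch; ++c) {
    double held = 0.0;
    int timer = 0;
    const double *ac = a + c;
    double *oc = o + c;
    for (int i = 0; i < n; ++i) {
      const double cur = ac[(std::size_t)i * nch];
      if (cur >= held) {
        held = cur;
        timer = hold_samples;
      } else if (timer > 0) {
        --timer;
      } else {
        held *= decay_factor;
        if (cur >= held) {
          held = cur;
          timer = hold_samples;
        }
      }
      oc[(std::size_t)i * nch] = held;
    }
  }
  return out;
}

// Per-sample applied gain in dB: zero-order hold of the frame-rate gain
// trajectory, slew-limited to max_db_per_period * fc / fs dB per sample.
// [[Rcpp::export]]
NumericMatrix applied_gain_cpp(NumericMatrix gains_db, int n_samples,
                               double fs, double frame_rate,
                               NumericVector fc, double max_db_per_period) {
  const int nch = gains_db.nrow();
  const int nf = gains_db.ncol();
  NumericMatrix out(nch, n_samples);
  double *o = REAL(out);
  const double *gm = REAL(gains_db);
  std::vector<double> step(nch), g(nch);
  for (int c = 0; c < nch; ++c) {
    step[c] = max_db_per_period * fc[c] / fs;
    g[c] = gm[c];
  }
  for (int i = 0; i < n_samples; ++i) {
    int fi = (int)(i * frame_rate / fs);
    if (fi >= nf) fi = nf - 1;
    const double *gf = gm + (std::size_t)fi * nch;
    double *oc = o + (std::size_t)i * nch;
    for (int c = 0; c < nch; ++c) {
      double d = gf[c] - g[c];
      if (d > step[c]) d = step[c];
      if (d < -step[c]) d = -step[c];
      g[c] += d;
      oc[c] = g[c];
    }
  }
  return out;
}

// Resynthesis: sum of real parts of all channels, each scaled by the
// slew-limited linear gain; norm is the constant passband normalization
// of the joint filterbank response. The linear gain per channel is
// recomputed only when its dB value moves, so static gains cost no exp.
// [[Rcpp::export]]
NumericVector resynthesize_cpp(ComplexMatrix bands, NumericMatrix gains_db,
                               double fs, double frame_rate, NumericVector fc,
                               double max_db_per_period, double norm) {
  const int nch = bands.nrow();
  const int n = bands.ncol();
  NumericVector out(n);
  const Rcomplex *bm = COMPLEX(bands);
  const double *gm = REAL(gains_db);
  const int nf = gains_db.ncol();
  const double ln10_20 = std::log(10.0) / 20.0;
  std::vector<double> step(nch), g(nch), lin(nch);
  for (int c = 0; c < nch; ++c) {
    step[c] = max_db_per_period * fc[c] / fs;
    g[c] = gm[c];
    lin[c] = std::exp(g[c] * ln10_20);
  }
  for (int i = 0; i < n; ++i) {
    int fi = (int)(i * frame_rate / fs);
    if (fi >= nf) fi = nf - 1;
    const double *gf = gm + (std::size_t)fi * nch;
    const Rcomplex *bc = bm + (std::size_t)i * nch;
    double acc = 0.0;
    for (int c = 0; c < nch; ++c) {
      double d = gf[c] - g[c];
      if (d != 0.0) {
        if (d > step[c]) d = step[c];
        if (d < -step[c]) d = -step[c];
        g[c] += d;
        lin[c] = std::exp(g[c] * ln10_20);
      }
      acc += bc[c].r * lin[c];
    }
    out[i] = acc * norm;
  }
  return out;
}

// Instantaneous amplitude (magnitude) of a complex band matrix.
// [[Rcpp::export]]
NumericMatrix band_magnitude_cpp(ComplexMatrix bands) {
  const int nch = bands.nrow();
  const int n = bands.ncol();
  NumericMatrix out(nch, n);
  const Rcomplex *bm = COMPLEX(bands);
  double *o = REAL(out);
  const std::size_t total = (std::size_t)nch * n;
  for (std::size_t i = 0; i < total; ++i) {
    o[i] = std::sqrt(bm[i].r * bm[i].r + bm[i].i * bm[i].i);
  }
  return out;
}
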
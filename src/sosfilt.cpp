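#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Cascaded-biquad (second-order-section) zero-phase filtering.
//
// Each row of `sos` is one section: b0 b1 b2 a0 a1 a2 with a0 == 1.
// Filtering runs the cascade forward then backward over an odd-reflection
// extension of the signal, with per-section steady-state initial conditions
// (the state a constant input equal to the first processed sample would
// leave behind). The exported routine averages the forward-backward and
// backward-forward results, which makes the operator exactly symmetric
// under time reversal.
//
// Columns are processed in blocks with the column loop innermost so the
// recurrence, which is serial in time, still vectorizes across traces.

namespace {

constexpr int kBlock = 16;

struct Biquad {
  double b0, b1, b2, a1, a2;
  double zi1, zi2;  // steady-state state per unit constant input
  double gdc;       // DC gain
};

static std::vector<Biquad> make_sections(const NumericMatrix &sos) {
  std::vector<Biquad> s(sos.nrow());
  for (int i = 0; i < sos.nrow(); ++i) {
    Biquad q;
    q.b0 = sos(i, 0); q.b1 = sos(i, 1); q.b2 = sos(i, 2);
    q.a1 = sos(i, 4); q.a2 = sos(i, 5);
    double den = 1.0 + q.a1 + q.a2;
    q.gdc = (std::abs(den) > 1e-12) ? (q.b0 + q.b1 + q.b2) / den : 0.0;
    // Direct-form II transposed steady state for constant unit input.
    q.zi2 = q.b2 - q.a2 * q.gdc;
    q.zi1 = q.b1 - q.a1 * q.gdc + q.zi2;
    s[i] = q;
  }
  return s;
}

// Value of the odd (point-symmetric) extension of x at integer position p,
// folding repeatedly about both endpoints so the pad may exceed the signal
// length. Each reflection maps v(p) -> 2 * v(edge) - v(mirror(p)).
static double odd_sample(const double *x, int n, long p) {
  double scale = 1.0, shift = 0.0;
  while (p < 0 || p >= n) {
    if (p < 0) {
      shift += 2.0 * x[0] * scale;
      scale = -scale;
      p = -p;
    } else {
      shift += 2.0 * x[n - 1] * scale;
      scale = -scale;
      p = 2L * (n - 1) - p;
    }
  }
  return scale * x[p] + shift;
}

// One directional pass (dir = +1 forward, -1 backward) of the full cascade
// over a row-major block buf[len][bs], in place.
static void cascade_pass(const std::vector<Biquad> &sec,
                         std::vector<double> &buf, int len, int bs,
                         int dir) {
  const int start = dir > 0 ? 0 : len - 1;
  double level[kBlock], z1[kBlock], z2[kBlock];
  for (int j = 0; j < bs; ++j) level[j] = buf[(size_t) start * kBlock + j];
  for (const Biquad &q : sec) {
    for (int j = 0; j < bs; ++j) {
      z1[j] = q.zi1 * level[j];
      z2[j] = q.zi2 * level[j];
    }
    for (int t = 0; t < len; ++t) {
      double *row = &buf[(size_t) (dir > 0 ? t : len - 1 - t) * kBlock];
      for (int j = 0; j < bs; ++j) {
        double x = row[j];
        double out = q.b0 * x + z1[j];
        z1[j] = q.b1 * x - q.a1 * out + z2[j];
        z2[j] = q.b2 * x - q.a2 * out;
        row[j] = out;
      }
    }
    for (int j = 0; j < bs; ++j) level[j] *= q.gdc;
  }
}

}  // namespace

// [[Rcpp::export(name = ".sos_filtfilt_mat")]]
NumericMatrix sos_filtfilt_mat(NumericMatrix sos, NumericMatrix x, int pad) {
  const int n = x.nrow(), m = x.ncol();
  if (n < 2) stop("need at least 2 samples");
  if (pad < 0) stop("pad must be nonnegative");
  std::vector<Biquad> sec = make_sections(sos);
  const int len = n + 2 * pad;
  NumericMatrix out(n, m);
  std::vector<double> fb((size_t) len * kBlock), bf((size_t) len * kBlock);
  for (int j0 = 0; j0 < m; j0 += kBlock) {
    const int bs = std::min(kBlock, m - j0);
    for (int j = 0; j < bs; ++j) {
      const double *col = &x(0, j0 + j);
      for (int t = 0; t < len; ++t) {
        double v = odd_sample(col, n, (long) t - pad);
        fb[(size_t) t * kBlock + j] = v;
        bf[(size_t) t * kBlock + j] = v;
      }
    }
    cascade_pass(sec, fb, len, bs, +1);
    cascade_pass(sec, fb, len, bs, -1);
    cascade_pass(sec, bf, len, bs, -1);
    cascade_pass(sec, bf, len, bs, +1);
    for (int j = 0; j < bs; ++j) {
      for (int t = 0; t < n; ++t) {
        const size_t r = (size_t) (pad + t) * kBlock + j;
        out(t, j0 + j) = 0.5 * (fb[r] + bf[r]);
      }
    }
  }
  return out;
}

// Normalize each column of noise, tone and background to unit RMS and mix:
// out[, j] = w[j] * noise[, j] + (1 - w[j]) * tone[, j] + bg_rms * bg[, j].
// Fused here because the mixing touches several large matrices that would
// otherwise each allocate full-size temporaries.
// [[Rcpp::export(name = ".synth_mix")]]
NumericMatrix synth_mix(NumericMatrix noise, NumericMatrix tone,
                        NumericMatrix bg, NumericVector w, double bg_rms) {
  const int n = noise.nrow(), m = noise.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double *pn = &noise(0, j), *pt = &tone(0, j), *pb = &bg(0, j);
    double sn = 0, st = 0, sb = 0;
    for (int t = 0; t < n; ++t) {
      sn += pn[t] * pn[t]; st += pt[t] * pt[t]; sb += pb[t] * pb[t];
    }
    const double cn = sn > 0 ? w[j] / std::sqrt(sn / n) : 0.0;
    const double ct = st > 0 ? (1.0 - w[j]) / std::sqrt(st / n) : 0.0;
    const double cb = sb > 0 ? bg_rms / std::sqrt(sb / n) : 0.0;
    double *po = &out(0, j);
    for (int t = 0; t < n; ++t) {
      po[t] = cn * pn[t] + ct * pt[t] + cb * pb[t];
    }
  }
  return out;
}
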
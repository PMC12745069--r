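#include <Rcpp.h>
using namespace Rcpp;

// Per-sample kernels for gaze synthesis and event detection. These are the
// only hot loops at 2000 Hz; the event logic stays in R.

// Assemble the binocular sample stream from the piecewise-linear event
// plan: position(t) = a[e] + b[e] * (t - t0[e]) for event e, each eye
// offset by half the vergence in x, plus i.i.d. Gaussian jitter per sample
// and axis (R's RNG).
// [[Rcpp::export]]
List cpp_assemble_gaze(IntegerVector ev_len, NumericVector ev_ax,
                       NumericVector ev_bx, NumericVector ev_ay,
                       NumericVector ev_by, IntegerVector ev_drop,
                       double dt, double half_v, double jit) {
  int n_ev = ev_len.size();
  int n = 0;
  for (int e = 0; e < n_ev; ++e) n += ev_len[e];
  NumericVector t(n), lx(n), ly(n), rx(n), ry(n);
  LogicalVector vl(n), vr(n);
  int i = 0;
  for (int e = 0; e < n_ev; ++e) {
    int m = ev_len[e];
    bool dl = ev_drop[e] == 1, dr = ev_drop[e] == 2;
    for (int k = 0; k < m; ++k, ++i) {
      double tau = k * dt;
      double px = ev_ax[e] + ev_bx[e] * tau;
      double py = ev_ay[e] + ev_by[e] * tau;
      t[i] = i * dt;
      if (jit > 0) {
        lx[i] = px - half_v + jit * norm_rand();
        ly[i] = py + jit * norm_rand();
        rx[i] = px + half_v + jit * norm_rand();
        ry[i] = py + jit * norm_rand();
      } else {
        lx[i] = px - half_v; ly[i] = py;
        rx[i] = px + half_v; ry[i] = py;
      }
      vl[i] = !dl; vr[i] = !dr;
    }
  }
  return List::create(_["t"] = t, _["lx"] = lx, _["ly"] = ly, _["rx"] = rx,
                      _["ry"] = ry, _["vl"] = vl, _["vr"] = vr);
}

// Per-gap stability flags: for each consecutive sample pair, TRUE when
// every eye valid at both endpoints moved no more than thr px (single-eye
// stretches use that eye alone; pairs with no eye valid at both endpoints
// are unstable).
// [[Rcpp::export]]
LogicalVector cpp_gap_stability(NumericVector lx, NumericVector ly,
                                NumericVector rx, NumericVector ry,
                                LogicalVector vl, LogicalVector vr,
                                double thr) {
  int n = lx.size();
  if (n < 2) return LogicalVector(0);
  LogicalVector out(n - 1);
  double thr2 = thr * thr;
  for (int i = 1; i < n; ++i) {
    bool lv = vl[i - 1] && vl[i];
    bool rv = vr[i - 1] && vr[i];
    bool ok = lv || rv;
    if (ok && lv) {
      double dx = lx[i] - lx[i - 1], dy = ly[i] - ly[i - 1];
      if (dx * dx + dy * dy > thr2) ok = false;
    }
    if (ok && rv) {
      double dx = rx[i] - rx[i - 1], dy = ry[i] - ry[i - 1];
      if (dx * dx + dy * dy > thr2) ok = false;
    }
    out[i - 1] = ok;
  }
  return out;
}
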
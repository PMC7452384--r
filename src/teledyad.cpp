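// Hot numerical kernels: swimmer integration, plug-in transfer-entropy
// counting, and the lag-scan of the normalized cross-correlation. Each has
// an independent R/brute-force oracle in the test suite.
#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap_pi(double a) {
  return std::atan2(std::sin(a), std::cos(a));
}

// Integrate one swimmer's heading/position given its precomputed speed
// series. guide_heading (length n, may be empty) is blended in with weight
// c at a lag of lag_f frames; (target_x, target_y) is the attraction target.
// [[Rcpp::export(name = ".integrate_swimmer_cpp")]]
List integrate_swimmer_cpp(NumericVector speed, NumericVector hnoise,
                           double dt, NumericVector arena, double gain_wall,
                           double margin, double h0, NumericVector p0,
                           double c, int lag_f, NumericVector guide_heading,
                           double gain_att, NumericVector target_x,
                           NumericVector target_y) {
  const int n = speed.size();
  NumericVector h(n), x(n), y(n);
  h[0] = h0; x[0] = p0[0]; y[0] = p0[1];
  const double ax = arena[0], ay = arena[1];
  const bool has_guide = guide_heading.size() == n && c > 0;
  const bool has_att = gain_att > 0 && target_x.size() == n;
  for (int t = 0; t < n - 1; ++t) {
    double torque = 0.0;
    double d = std::min(std::min(x[t], ax - x[t]), std::min(y[t], ay - y[t]));
    if (d < margin) {
      double to_center = std::atan2(ay / 2.0 - y[t], ax / 2.0 - x[t]);
      torque += gain_wall * (1.0 - d / margin) * wrap_pi(to_center - h[t]);
    }
    if (has_att) {
      double dx = target_x[t] - x[t], dy = target_y[t] - y[t];
      double dist = std::sqrt(dx * dx + dy * dy);
      if (dist > 1e-9) {
        double w = dist / 10.0; if (w > 1.0) w = 1.0;
        torque += gain_att * w * wrap_pi(std::atan2(dy, dx) - h[t]);
      }
    }
    double u = h[t] + torque * dt + hnoise[t];
    if (has_guide && t + 1 >= lag_f)
      u = u + c * wrap_pi(guide_heading[t + 1 - lag_f] - u);
    h[t + 1] = wrap_pi(u);
    double nx = x[t] + speed[t + 1] * dt * std::cos(h[t + 1]);
    double ny = y[t] + speed[t + 1] * dt * std::sin(h[t + 1]);
    x[t + 1] = std::min(std::max(nx, 0.0), ax);
    y[t + 1] = std::min(std::max(ny, 0.0), ay);
  }
  return List::create(_["h"] = h, _["x"] = x, _["y"] = y);
}

// Plug-in transfer entropy x -> y over the 4-symbol alphabet with history
// length k; transitions whose frames straddle a segment boundary are
// dropped (counts pooled across segments, gaps never bridged). Empty-cell
// convention 0 log 0 = 0. Returns TE (>= 0, units of log `base`) and the
// number of joint samples used.
// [[Rcpp::export(name = ".te_core_cpp")]]
List te_core_cpp(IntegerVector x, IntegerVector y, int k, double base,
                 IntegerVector seg) {
  const int n = y.size(), A = 4;
  if (x.size() != n) stop("alignment error");
  if (n < k + 1) stop("insufficient overlap");
  int K = 1; for (int j = 0; j < k; ++j) K *= A;
  const int ncell = A * K * K;
  std::vector<int> cnt(ncell, 0);
  const bool has_seg = seg.size() == n;
  const int *py = INTEGER(y), *px = INTEGER(x);
  const int *ps = has_seg ? INTEGER(seg) : nullptr;
  long m = 0;
  if (k == 1 && !has_seg) {                  // hot path
    for (int t = 0; t < n - 1; ++t)
      ++cnt[(py[t + 1] - 1) + A * (py[t] - 1) + A * A * (px[t] - 1)];
    m = n - 1;
  } else {
    // history ending at t (0-based t = k-1 .. n-2) predicts y[t+1]
    for (int t = k - 1; t < n - 1; ++t) {
      if (has_seg && ps[t + 1] != ps[t - k + 1]) continue;
      int yk = 0, xk = 0, pw = 1;
      for (int j = 0; j < k; ++j) {          // most recent symbol = lowest digit
        yk += (py[t - j] - 1) * pw;
        xk += (px[t - j] - 1) * pw;
        pw *= A;
      }
      ++cnt[(py[t + 1] - 1) + A * yk + A * K * xk];
      ++m;
    }
  }
  if (m < 1) stop("insufficient overlap");
  // marginals
  std::vector<double> m_yz(A * K, 0.0), m_zx(K * K, 0.0), m_z(K, 0.0);
  for (int lx = 0; lx < K; ++lx)
    for (int jz = 0; jz < K; ++jz)
      for (int iy = 0; iy < A; ++iy) {
        int cc = cnt[iy + A * jz + A * K * lx];
        if (!cc) continue;
        m_yz[iy + A * jz] += cc;
        m_zx[jz + K * lx] += cc;
        m_z[jz] += cc;
      }
  double te = 0.0;
  for (int lx = 0; lx < K; ++lx)
    for (int jz = 0; jz < K; ++jz)
      for (int iy = 0; iy < A; ++iy) {
        int cc = cnt[iy + A * jz + A * K * lx];
        if (!cc) continue;
        te += cc * std::log(cc * m_z[jz] /
                            (m_yz[iy + A * jz] * m_zx[jz + K * lx]));
      }
  te /= m * std::log(base);
  if (te < 0) te = 0;                        // guard against rounding
  return List::create(_["te"] = te, _["n"] = (double)m);
}

// Pearson correlation of a vs b at every integer lag in [-Lmax, Lmax],
// normalization recomputed on the overlapping support at each lag; frames
// where either value is NA are dropped pairwise. Lags with fewer than
// min_overlap complete pairs, or zero variance, yield NA.
// [[Rcpp::export(name = ".xcorr_profile_cpp")]]
NumericVector xcorr_profile_cpp(NumericVector a, NumericVector b, int Lmax,
                                int min_overlap) {
  const int n = a.size();
  const double *pa = REAL(a), *pb = REAL(b);
  NumericVector out(2 * Lmax + 1, NA_REAL);
  bool has_na = false;
  for (int i = 0; i < n && !has_na; ++i)
    has_na = ISNAN(pa[i]) || ISNAN(pb[i]);
  if (!has_na) {
    // prefix sums give the per-lag overlap moments in O(1); only the cross
    // term needs a pass per lag
    std::vector<double> ca(n + 1, 0), caa(n + 1, 0), cb(n + 1, 0), cbb(n + 1, 0);
    for (int i = 0; i < n; ++i) {
      ca[i + 1] = ca[i] + pa[i];   caa[i + 1] = caa[i] + pa[i] * pa[i];
      cb[i + 1] = cb[i] + pb[i];   cbb[i + 1] = cbb[i] + pb[i] * pb[i];
    }
    for (int L = -Lmax; L <= Lmax; ++L) {
      int lo = std::max(0, -L), hi = std::min(n, n - L);   // a[i] with b[i+L]
      long cnt = hi - lo;
      if (cnt < min_overlap) continue;
      double sab = 0;
      for (int i = lo; i < hi; ++i) sab += pa[i] * pb[i + L];
      double sa = ca[hi] - ca[lo], saa = caa[hi] - caa[lo];
      double sb = cb[hi + L] - cb[lo + L], sbb = cbb[hi + L] - cbb[lo + L];
      double va = saa - sa * sa / cnt, vb = sbb - sb * sb / cnt;
      if (va <= 0 || vb <= 0) continue;
      out[L + Lmax] = (sab - sa * sb / cnt) / std::sqrt(va * vb);
    }
    return out;
  }
  for (int L = -Lmax; L <= Lmax; ++L) {
    int lo = std::max(0, -L), hi = std::min(n, n - L);
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    long cnt = 0;
    for (int i = lo; i < hi; ++i) {
      double av = pa[i], bv = pb[i + L];
      if (ISNAN(av) || ISNAN(bv)) continue;
      sa += av; sb += bv; saa += av * av; sbb += bv * bv; sab += av * bv;
      ++cnt;
    }
    if (cnt < min_overlap) continue;
    double va = saa - sa * sa / cnt, vb = sbb - sb * sb / cnt;
    if (va <= 0 || vb <= 0) continue;
    out[L + Lmax] = (sab - sa * sb / cnt) / std::sqrt(va * vb);
  }
  return out;
}
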
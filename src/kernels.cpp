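// Compiled kernels for the per-frame / per-contour inner loops: the
// functional bank over contour-matrix columns, Viterbi pitch smoothing,
// and pitch-period marker picking.  Semantics mirror the R reference
// implementations in R/functionals.R and R/f0.R exactly; the R versions
// remain the documented definition and the test oracle.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KEPS = 1e-10;

static double quantile7(const std::vector<double>& s, double p) {
  int n = s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  double fr = h - lo;
  if (lo + 1 >= n) return s[n - 1];
  return s[lo] * (1 - fr) + s[lo + 1] * fr;
}

static double pop_sd_vec(const std::vector<double>& v) {
  int n = v.size();
  if (n == 0) return 0.0;
  double m = 0, s = 0;
  for (double x : v) m += x;
  m /= n;
  for (double x : v) s += (x - m) * (x - m);
  return std::sqrt(s / n);
}

// solve a k x k linear system by Gaussian elimination with partial
// pivoting; returns false when (near-)singular
static bool solve_small(std::vector<std::vector<double> > A,
                        std::vector<double> b, std::vector<double>& out) {
  int k = b.size();
  for (int c = 0; c < k; ++c) {
    int piv = c;
    for (int rTmp = c + 1; rTmp < k; ++rTmp)
      if (std::fabs(A[rTmp][c]) > std::fabs(A[piv][c])) piv = rTmp;
    if (std::fabs(A[piv][c]) < 1e-300) return false;
    std::swap(A[c], A[piv]);
    std::swap(b[c], b[piv]);
    for (int rr = c + 1; rr < k; ++rr) {
      double f = A[rr][c] / A[c][c];
      for (int cc = c; cc < k; ++cc) A[rr][cc] -= f * A[c][cc];
      b[rr] -= f * b[c];
    }
  }
  out.assign(k, 0.0);
  for (int rr = k - 1; rr >= 0; --rr) {
    double acc = b[rr];
    for (int cc = rr + 1; cc < k; ++cc) acc -= A[rr][cc] * out[cc];
    out[rr] = acc / A[rr][rr];
  }
  return true;
}

// [[Rcpp::export(name = "cpp_bank")]]
NumericMatrix cpp_bank(NumericMatrix M) {
  const int n = M.nrow(), K = M.ncol();
  const int NF = 54;
  NumericMatrix out(K, NF);
  // canonical column order; must match compute_all_functionals()
  CharacterVector cn = CharacterVector::create(
      "quartile_1", "quartile_2", "quartile_3", "iqr_1_2", "iqr_2_3",
      "iqr_1_3", "percentile_1", "percentile_99", "range_1_99", "pos_min",
      "pos_max", "range", "contour_centroid", "flatness", "up25_duration",
      "up50_duration", "up75_duration", "up90_duration", "rise_duration",
      "curvature_duration", "seglen_mean", "seglen_max", "seglen_min",
      "seglen_sd", "pct_nonzero", "amean", "rqmean", "stddev", "skewness",
      "kurtosis", "lp_gain", "lp_coef_1", "lp_coef_2", "lp_coef_3",
      "lp_coef_4", "lp_coef_5", "peak_mean", "peak_mean_rel",
      "peak_dist_mean", "peak_dist_sd", "peak_amp_mean", "min_amp_mean",
      "peak_amp_range", "rise_slope_mean", "rise_slope_sd",
      "fall_slope_mean", "fall_slope_sd", "linreg_slope", "linreg_offset",
      "linreg_err", "quadreg_a", "quadreg_b", "quadreg_offset",
      "quadreg_err");
  colnames(out) = cn;
  if (!Rf_isNull(colnames(M))) rownames(out) = colnames(M);

  const double den = (n > 1) ? (double)(n - 1) : 1.0;
  std::vector<double> s(n), tt(n);
  for (int i = 0; i < n; ++i) tt[i] = i / den;
  double tmean = 0, vt = 0;
  for (int i = 0; i < n; ++i) tmean += tt[i];
  tmean /= n;
  for (int i = 0; i < n; ++i) vt += (tt[i] - tmean) * (tt[i] - tmean);

  // normal-equation matrix for the quadratic fit (shared across columns)
  std::vector<std::vector<double> > XtX(3, std::vector<double>(3, 0.0));
  if (n >= 3) {
    for (int i = 0; i < n; ++i) {
      double t2 = tt[i] * tt[i];
      XtX[0][0] += t2 * t2;  XtX[0][1] += t2 * tt[i];  XtX[0][2] += t2;
      XtX[1][1] += tt[i] * tt[i];  XtX[1][2] += tt[i];
    }
    XtX[1][0] = XtX[0][1];  XtX[2][0] = XtX[0][2];
    XtX[2][1] = XtX[1][2];  XtX[2][2] = n;
  }

  for (int k = 0; k < K; ++k) {
    const double* x = &M(0, k);
    double* o = &out(k, 0);
    auto set = [&](int col, double v) { out(k, col) = v; };
    (void)o;

    // percentiles
    s.assign(x, x + n);
    std::sort(s.begin(), s.end());
    double q1 = quantile7(s, 0.25), q2 = quantile7(s, 0.50),
           q3 = quantile7(s, 0.75), p1 = quantile7(s, 0.01),
           p99 = quantile7(s, 0.99);
    set(0, q1); set(1, q2); set(2, q3);
    set(3, q2 - q1); set(4, q3 - q2); set(5, q3 - q1);
    set(6, p1); set(7, p99); set(8, p99 - p1);

    // moments
    double mu = 0, sq = 0;
    for (int i = 0; i < n; ++i) { mu += x[i]; sq += x[i] * x[i]; }
    mu /= n; sq /= n;
    double m2 = 0, m3 = 0, m4 = 0;
    for (int i = 0; i < n; ++i) {
      double d = x[i] - mu;
      m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
    }
    m2 /= n; m3 /= n; m4 /= n;
    set(25, mu); set(26, std::sqrt(sq)); set(27, std::sqrt(m2));
    set(28, m2 > KEPS ? m3 / std::pow(m2, 1.5) : 0.0);
    set(29, m2 > KEPS ? m4 / (m2 * m2) - 3.0 : 0.0);

    // temporal
    int imin = 0, imax = 0;
    for (int i = 1; i < n; ++i) {
      if (x[i] < x[imin]) imin = i;
      if (x[i] > x[imax]) imax = i;
    }
    double mn = x[imin], mx = x[imax], rg = mx - mn;
    set(9, imin / den); set(10, imax / den); set(11, rg);
    double sden = 0, snum = 0, aabs = 0, lgs = 0;
    for (int i = 0; i < n; ++i) {
      double sh = x[i] - mn;
      sden += sh; snum += tt[i] * sh;
      double ax = std::fabs(x[i]);
      aabs += ax; lgs += std::log(ax + KEPS);
    }
    set(12, sden > KEPS ? snum / sden : 0.5);
    set(13, std::exp(lgs / n) / (aabs / n + KEPS));
    double thr[4] = {mn + 0.25 * rg, mn + 0.50 * rg, mn + 0.75 * rg,
                     mn + 0.90 * rg};
    int up[4] = {0, 0, 0, 0};
    int nz = 0, nrise = 0, ncurv = 0;
    for (int i = 0; i < n; ++i) {
      for (int q = 0; q < 4; ++q) if (x[i] > thr[q]) ++up[q];
      if (std::fabs(x[i]) > KEPS) ++nz;
      if (i >= 1 && x[i] > x[i - 1]) ++nrise;
      // rounding order matches R's diff(x, differences = 2)
      if (i >= 2 && (x[i] - x[i - 1]) - (x[i - 1] - x[i - 2]) > 0) ++ncurv;
    }
    for (int q = 0; q < 4; ++q) set(14 + q, (double)up[q] / n);
    set(18, n >= 2 ? (double)nrise / (n - 1) : 0.0);
    set(19, n >= 3 ? (double)ncurv / (n - 2) : 0.0);
    set(24, (double)nz / n);

    // segment lengths above min + 0.25 range
    if (rg > KEPS) {
      std::vector<double> lens;
      int run = 0;
      for (int i = 0; i < n; ++i) {
        if (x[i] > thr[0]) {
          ++run;
        } else if (run > 0) {
          lens.push_back(run); run = 0;
        }
      }
      if (run > 0) lens.push_back(run);
      if (!lens.empty()) {
        double lm = 0, lmax = lens[0], lmin = lens[0];
        for (double l : lens) {
          lm += l;
          if (l > lmax) lmax = l;
          if (l < lmin) lmin = l;
        }
        set(20, lm / lens.size()); set(21, lmax); set(22, lmin);
        set(23, pop_sd_vec(lens));
      }
    }

    // linear prediction (order 5, autocorrelation method)
    if (n > 5 && m2 * n > KEPS * n) {
      std::vector<double> r(6, 0.0);
      for (int lag = 0; lag <= 5; ++lag) {
        double acc = 0;
        for (int i = 0; i + lag < n; ++i)
          acc += (x[i] - mu) * (x[i + lag] - mu);
        r[lag] = acc / n;
      }
      if (r[0] >= KEPS) {
        std::vector<std::vector<double> > A(5, std::vector<double>(5));
        for (int i = 0; i < 5; ++i)
          for (int j = 0; j < 5; ++j) A[i][j] = r[std::abs(i - j)];
        std::vector<double> rhs(r.begin() + 1, r.end()), a;
        if (solve_small(A, rhs, a)) {
          double g = r[0];
          for (int i = 0; i < 5; ++i) g -= a[i] * r[i + 1];
          set(30, g > 0 ? g : 0.0);
          for (int i = 0; i < 5; ++i) set(31 + i, a[i]);
        }
      }
    }

    // peaks: strict local maxima above the mean with at least 5% of the
    // contour range of salience over the flanking minima (matches the R
    // reference in peaks_block)
    std::vector<int> cand, mins;
    for (int i = 1; i + 1 < n; ++i) {
      if (x[i] > x[i - 1] && x[i] > x[i + 1] && x[i] > mu)
        cand.push_back(i);
      if (x[i] < x[i - 1] && x[i] < x[i + 1]) mins.push_back(i);
    }
    // anchors: {0, minima, n-1}; candidates and anchors are both sorted,
    // so a single forward sweep finds the flanking anchors
    std::vector<int> anchors;
    anchors.push_back(0);
    for (int mIdx : mins) anchors.push_back(mIdx);
    anchors.push_back(n - 1);
    std::vector<int> pk, pprev, pnxt;
    {
      size_t ap = 0;
      const double sal = 0.05 * rg;
      for (size_t j = 0; j < cand.size(); ++j) {
        int i = cand[j];
        while (ap + 1 < anchors.size() && anchors[ap + 1] < i) ++ap;
        int prev = anchors[ap];
        int nxt = anchors[ap + 1];
        double flank = x[prev] > x[nxt] ? x[prev] : x[nxt];
        if (x[i] - flank >= sal) {
          pk.push_back(i);
          pprev.push_back(prev);
          pnxt.push_back(nxt);
        }
      }
    }
    if (!pk.empty()) {
      std::vector<double> amp(pk.size()), rises(pk.size()),
          falls(pk.size());
      double pm = 0;
      for (size_t j = 0; j < pk.size(); ++j) pm += x[pk[j]];
      pm /= pk.size();
      for (size_t j = 0; j < pk.size(); ++j) {
        int i = pk[j];
        double y1 = x[i - 1], y2 = x[i], y3 = x[i + 1];
        double dd = y1 - 2 * y2 + y3;
        double d = 0;
        if (std::fabs(dd) >= KEPS) {
          d = 0.5 * (y1 - y3) / dd;
          if (d > 1) d = 1;
          if (d < -1) d = -1;
        }
        amp[j] = y2 - 0.25 * (y1 - y3) * d;
        rises[j] = (x[i] - x[pprev[j]]) / (double)(i - pprev[j]);
        falls[j] = (x[i] - x[pnxt[j]]) / (double)(pnxt[j] - i);
      }
      set(36, pm); set(37, pm - mu);
      if (pk.size() >= 2) {
        std::vector<double> dist(pk.size() - 1);
        double dm = 0;
        for (size_t j = 1; j < pk.size(); ++j) {
          dist[j - 1] = pk[j] - pk[j - 1];
          dm += dist[j - 1];
        }
        set(38, dm / dist.size());
        set(39, pop_sd_vec(dist));
      }
      double am = 0, amx = amp[0], amn = amp[0];
      for (double a2 : amp) {
        am += a2;
        if (a2 > amx) amx = a2;
        if (a2 < amn) amn = a2;
      }
      set(40, am / amp.size());
      if (!mins.empty()) {
        double mm = 0;
        for (int mIdx : mins) mm += x[mIdx];
        set(41, mm / mins.size());
      }
      set(42, amx - amn);
      double rm = 0, fm = 0;
      for (size_t j = 0; j < pk.size(); ++j) { rm += rises[j]; fm += falls[j]; }
      set(43, rm / pk.size()); set(44, pop_sd_vec(rises));
      set(45, fm / pk.size()); set(46, pop_sd_vec(falls));
    }

    // regression
    if (n >= 2) {
      double sxy = 0;
      for (int i = 0; i < n; ++i) sxy += (tt[i] - tmean) * (x[i] - mu);
      double slope = sxy / vt;
      double off = mu - slope * tmean;
      double err = 0;
      for (int i = 0; i < n; ++i) {
        double rres = x[i] - off - slope * tt[i];
        err += rres * rres;
      }
      set(47, slope); set(48, off); set(49, err / n);
      if (n >= 3) {
        std::vector<double> Xty(3, 0.0), cf;
        for (int i = 0; i < n; ++i) {
          Xty[0] += tt[i] * tt[i] * x[i];
          Xty[1] += tt[i] * x[i];
          Xty[2] += x[i];
        }
        if (solve_small(XtX, Xty, cf)) {
          double qerr = 0;
          for (int i = 0; i < n; ++i) {
            double fit = cf[0] * tt[i] * tt[i] + cf[1] * tt[i] + cf[2];
            qerr += (x[i] - fit) * (x[i] - fit);
          }
          set(50, cf[0]); set(51, cf[1]); set(52, cf[2]);
          set(53, qerr / n);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = "cpp_viterbi")]]
IntegerVector cpp_viterbi(NumericMatrix em, NumericMatrix trans) {
  const int nc = em.nrow(), nf = em.ncol();
  IntegerVector path(nf);
  std::vector<double> delta(nc), nxt(nc);
  IntegerMatrix psi(nc, nf);
  for (int i = 0; i < nc; ++i) delta[i] = em(i, 0);
  const double* trp = REAL(trans);
  for (int t = 1; t < nf; ++t) {
    for (int j = 0; j < nc; ++j) {
      const double* tc = trp + (size_t)j * nc;
      double best = delta[0] - tc[0];
      int arg = 0;
      for (int i = 1; i < nc; ++i) {
        double v = delta[i] - tc[i];
        if (v > best) { best = v; arg = i; }
      }
      nxt[j] = best + em(j, t);
      psi(j, t) = arg;
    }
    delta = nxt;
  }
  int arg = 0;
  for (int i = 1; i < nc; ++i) if (delta[i] > delta[arg]) arg = i;
  path[nf - 1] = arg + 1;
  for (int t = nf - 1; t >= 1; --t) {
    arg = psi(arg, t);
    path[t - 1] = arg + 1;
  }
  return path;
}

// [[Rcpp::export(name = "cpp_period_markers")]]
List cpp_period_markers(NumericVector seg, double period) {
  const int n = seg.size();
  int first_hi = std::min((double)n, std::max(3.0, std::ceil(1.5 * period)));
  int i = 0;
  for (int j = 1; j < first_hi; ++j) if (seg[j] > seg[i]) i = j;
  std::vector<double> pos, amp;
  while (true) {
    double p = i + 1, a = seg[i];
    if (i > 0 && i + 1 < n) {
      double y1 = seg[i - 1], y2 = seg[i], y3 = seg[i + 1];
      double dd = y1 - 2 * y2 + y3;
      if (std::fabs(dd) >= KEPS) {
        double d = 0.5 * (y1 - y3) / dd;
        if (d > 1) d = 1;
        if (d < -1) d = -1;
        p = i + 1 + d;
        a = y2 - 0.25 * (y1 - y3) * d;
      }
    }
    pos.push_back(p);
    amp.push_back(a);
    int lo1 = (int)std::lround((i + 1) + 0.7 * period);   // 1-based bounds
    int hi1 = (int)std::lround((i + 1) + 1.3 * period);
    if (hi1 > n) break;
    int best = lo1 - 1;
    for (int j = lo1 - 1; j <= hi1 - 1; ++j) if (seg[j] > seg[best]) best = j;
    i = best;
  }
  return List::create(Named("pos") = pos, Named("amp") = amp,
                      Named("n") = (int)pos.size());
}

// Direct autocorrelation voicing: unbiased normalized ACF maximum in a
// +/-15% neighbourhood of the tracked pitch period, computed straight
// from overlapping raw frames of the (decimated) signal.

// [[Rcpp::export(name = "cpp_acf_voicing")]]
NumericVector cpp_acf_voicing(NumericVector x, int wl, int hp, int nf,
                              NumericVector lag0) {
  NumericVector vp(nf);
  for (int t = 0; t < nf; ++t) {
    const double* f = &x[t * hp];
    double r0 = 0;
    for (int i = 0; i < wl; ++i) r0 += f[i] * f[i];
    if (r0 < KEPS) { vp[t] = 0; continue; }
    int lo = (int)std::lround(0.85 * lag0[t]) - 1;
    int hi = (int)std::lround(1.15 * lag0[t]) + 1;
    if (lo < 1) lo = 1;
    if (hi > wl - 1) hi = wl - 1;
    if (hi < lo) { vp[t] = 0; continue; }
    std::vector<double> rv(hi - lo + 1);
    int arg = 0;
    for (int lag = lo; lag <= hi; ++lag) {
      double r = 0;
      for (int i = 0; i + lag < wl; ++i) r += f[i] * f[i + lag];
      rv[lag - lo] = r * (double)wl / (wl - lag);
      if (rv[lag - lo] > rv[arg]) arg = lag - lo;
    }
    double best = rv[arg];
    // the true period generally sits between integer lags: parabolic
    // refinement of the autocorrelation peak
    if (arg > 0 && arg + 1 < (int)rv.size()) {
      double y1 = rv[arg - 1], y2 = rv[arg], y3 = rv[arg + 1];
      double den = y1 - 2 * y2 + y3;
      if (std::fabs(den) >= KEPS) {
        double d = 0.5 * (y1 - y3) / den;
        if (d > 1) d = 1;
        if (d < -1) d = -1;
        best = y2 - 0.25 * (y1 - y3) * d;
      }
    }
    double v = best / r0;
    vp[t] = v < 0 ? 0 : (v > 1 ? 1 : v);
  }
  return vp;
}
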
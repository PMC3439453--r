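#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Circular shift of a histogram by a fractional number of bins (linear
// interpolation). Positive shift moves the peak to later bins.
static std::vector<double> shift_hist(const std::vector<double>& h, double shift) {
  int n = h.size();
  std::vector<double> out(n);
  if (shift == 0.0) { out = h; return out; }
  for (int t = 0; t < n; ++t) {
    double src = t - shift;
    double fl = std::floor(src);
    double fr = src - fl;
    int i0 = ((int)fl % n + n) % n;
    int i1 = (i0 + 1) % n;
    out[t] = (1.0 - fr) * h[i0] + fr * h[i1];
  }
  return out;
}

// IRF (x) exp(-t/tau) by the O(n) recursion s[t] = e*s[t-1] + irf[t].
// wrap = TRUE gives the periodic steady state (pre-excitation tail of
// incomplete decays across the repetition window), in closed form from a
// single zero-initialised pass.
static void conv_irf_exp_into(const std::vector<double>& irf, double tau,
                              double dt, bool wrap, std::vector<double>& s) {
  int n = irf.size();
  double e = std::exp(-dt / tau);
  s.resize(n);
  double acc = 0.0;
  for (int t = 0; t < n; ++t) { acc = e * acc + irf[t]; s[t] = acc; }
  if (wrap) {
    double en = std::pow(e, n);
    double c = s[n - 1] / (1.0 - en); // steady-state carry-in from previous periods
    double f = e;
    for (int t = 0; t < n; ++t) { s[t] += c * f; f *= e; }
  }
}

static std::vector<double> conv_irf_exp(const std::vector<double>& irf,
                                        double tau, double dt, bool wrap) {
  std::vector<double> out;
  conv_irf_exp_into(irf, tau, dt, wrap, out);
  return out;
}

// [[Rcpp::export]]
NumericVector conv_irf_exp_cpp(NumericVector irf, double tau, double dt, bool wrap) {
  std::vector<double> h(irf.begin(), irf.end());
  std::vector<double> out = conv_irf_exp(h, tau, dt, wrap);
  return NumericVector(out.begin(), out.end());
}

// Weighted least squares for y ~ sum_k a_k * B_k with a_k >= 0, by active-set
// enumeration over the (at most 2^k, k<=3) clamp patterns. Returns RSS and
// writes coefficients + fitted values.
static double nnls_small(const std::vector<std::vector<double> >& B,
                         const std::vector<double>& y,
                         const std::vector<double>& w,
                         std::vector<double>& coef,
                         std::vector<double>& fitted) {
  int k = B.size(), n = y.size();
  double best = R_PosInf;
  std::vector<double> bestc(k, 0.0);
  for (int mask = (1 << k) - 1; mask >= 0; --mask) {
    std::vector<int> act;
    for (int j = 0; j < k; ++j) if (mask & (1 << j)) act.push_back(j);
    int m = act.size();
    // normal equations for active set
    double A[9] = {0}, b[3] = {0};
    for (int i = 0; i < n; ++i) {
      for (int p = 0; p < m; ++p) {
        double bp = B[act[p]][i];
        b[p] += w[i] * bp * y[i];
        for (int q = p; q < m; ++q) A[p * 3 + q] += w[i] * bp * B[act[q]][i];
      }
    }
    for (int p = 0; p < m; ++p) for (int q = 0; q < p; ++q) A[p * 3 + q] = A[q * 3 + p];
    // Gaussian elimination with partial pivot
    double M[3][4];
    for (int p = 0; p < m; ++p) { for (int q = 0; q < m; ++q) M[p][q] = A[p * 3 + q]; M[p][m] = b[p]; }
    bool ok = true;
    for (int c = 0; c < m && ok; ++c) {
      int piv = c;
      for (int r = c + 1; r < m; ++r) if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
      if (std::fabs(M[piv][c]) < 1e-300) { ok = false; break; }
      if (piv != c) for (int q = 0; q <= m; ++q) std::swap(M[c][q], M[piv][q]);
      for (int r = 0; r < m; ++r) if (r != c) {
        double f = M[r][c] / M[c][c];
        for (int q = c; q <= m; ++q) M[r][q] -= f * M[c][q];
      }
    }
    if (!ok) continue;
    std::vector<double> cf(k, 0.0);
    bool feas = true;
    for (int p = 0; p < m; ++p) {
      double v = M[p][m] / M[p][p];
      if (v < 0) { feas = false; break; }
      cf[act[p]] = v;
    }
    if (!feas) continue;
    double rss = 0.0;
    for (int i = 0; i < n; ++i) {
      double f = 0.0;
      for (int j = 0; j < k; ++j) f += cf[j] * B[j][i];
      double r = y[i] - f;
      rss += w[i] * r * r;
    }
    if (rss < best) { best = rss; bestc = cf; }
    if (mask == (1 << k) - 1 && best < R_PosInf) {
      // unconstrained solution feasible: optimal, stop enumerating
      bool allpos = true;
      for (int j = 0; j < k; ++j) if (bestc[j] < 0) allpos = false;
      if (allpos) break;
    }
  }
  coef = bestc;
  fitted.assign(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) fitted[i] += bestc[j] * B[j][i];
  return best;
}

struct BiexpObj {
  const std::vector<double>* y;
  const std::vector<double>* irf;
  const std::vector<double>* w;
  double dt; bool wrap; bool fit_shift; double shift_max;
  double tau_lo, tau_hi;
  mutable std::vector<std::vector<double> > B;
  mutable std::vector<double> cf_buf, ft_buf, irfs_buf;
  // params: log(tau1), log(tau2) [, shift]
  double operator()(const std::vector<double>& x,
                    std::vector<double>* coef = 0,
                    std::vector<double>* fitted = 0) const {
    double tau1 = std::exp(x[0]), tau2 = std::exp(x[1]);
    double shift = fit_shift ? x[2] : 0.0;
    double pen = 0.0;
    if (tau1 < tau_lo) { pen += (tau_lo - tau1); tau1 = tau_lo; }
    if (tau2 < tau_lo) { pen += (tau_lo - tau2); tau2 = tau_lo; }
    if (tau1 > tau_hi) { pen += (tau1 - tau_hi); tau1 = tau_hi; }
    if (tau2 > tau_hi) { pen += (tau2 - tau_hi); tau2 = tau_hi; }
    if (fit_shift && std::fabs(shift) > shift_max) {
      pen += (std::fabs(shift) - shift_max) * 10.0;
      shift = shift > 0 ? shift_max : -shift_max;
    }
    int n = y->size();
    if (B.size() != 3) { B.resize(3); B[2].assign(n, 1.0); }
    const std::vector<double>* irfp = irf;
    if (shift != 0.0) { irfs_buf = shift_hist(*irf, shift); irfp = &irfs_buf; }
    conv_irf_exp_into(*irfp, tau1, dt, wrap, B[0]);
    conv_irf_exp_into(*irfp, tau2, dt, wrap, B[1]);
    double rss = nnls_small(B, *y, *w, cf_buf, ft_buf);
    if (coef) *coef = cf_buf;
    if (fitted) *fitted = ft_buf;
    return rss * (1.0 + pen);
  }
};

// Generic Nelder-Mead, dimension d <= 3.
template <class F>
static bool nelder_mead(const F& f, std::vector<double>& x, double& fx,
                        const std::vector<double>& step,
                        int maxit, double tol) {
  int d = x.size();
  std::vector<std::vector<double> > S(d + 1, x);
  std::vector<double> fv(d + 1);
  for (int j = 0; j < d; ++j) S[j + 1][j] += step[j];
  for (int j = 0; j <= d; ++j) fv[j] = f(S[j]);
  int it = 0;
  for (; it < maxit; ++it) {
    // order
    std::vector<int> ord(d + 1);
    for (int j = 0; j <= d; ++j) ord[j] = j;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return fv[a] < fv[b]; });
    int lo = ord[0], hi = ord[d], nh = ord[d - 1];
    double spread = 0.0;
    for (int j = 0; j <= d; ++j)
      for (int q = 0; q < d; ++q)
        spread = std::max(spread, std::fabs(S[j][q] - S[lo][q]));
    if (spread < 2e-4 ||
        std::fabs(fv[hi] - fv[lo]) <= tol * (std::fabs(fv[lo]) + tol)) break;
    std::vector<double> cen(d, 0.0);
    for (int j = 0; j <= d; ++j) if (j != hi)
      for (int q = 0; q < d; ++q) cen[q] += S[j][q] / d;
    auto pt = [&](double a) {
      std::vector<double> p(d);
      for (int q = 0; q < d; ++q) p[q] = cen[q] + a * (S[hi][q] - cen[q]);
      return p;
    };
    std::vector<double> xr = pt(-1.0);
    double fr = f(xr);
    if (fr < fv[lo]) {
      std::vector<double> xe = pt(-2.0);
      double fe = f(xe);
      if (fe < fr) { S[hi] = xe; fv[hi] = fe; } else { S[hi] = xr; fv[hi] = fr; }
    } else if (fr < fv[nh]) {
      S[hi] = xr; fv[hi] = fr;
    } else {
      std::vector<double> xc = pt(fr < fv[hi] ? -0.5 : 0.5);
      double fc = f(xc);
      if (fc < std::min(fr, fv[hi])) { S[hi] = xc; fv[hi] = fc; }
      else { // shrink
        for (int j = 0; j <= d; ++j) if (j != lo) {
          for (int q = 0; q < d; ++q) S[j][q] = S[lo][q] + 0.5 * (S[j][q] - S[lo][q]);
          fv[j] = f(S[j]);
        }
      }
    }
  }
  int lo = 0;
  for (int j = 1; j <= d; ++j) if (fv[j] < fv[lo]) lo = j;
  x = S[lo]; fx = fv[lo];
  return it < maxit;
}

// [[Rcpp::export]]
List fit_biexp_cpp(NumericVector y, NumericVector irf, double dt, bool wrap,
                   NumericVector w, bool fit_shift, double shift_max,
                   double tau_lo, double tau_hi,
                   NumericVector init_tau, double init_shift, int maxit) {
  std::vector<double> yv(y.begin(), y.end()), iv(irf.begin(), irf.end()),
      wv(w.begin(), w.end());
  BiexpObj obj{&yv, &iv, &wv, dt, wrap, fit_shift, shift_max, tau_lo, tau_hi};
  int d = fit_shift ? 3 : 2;
  std::vector<double> x(d, 0.0);
  if (init_tau.size() == 2 && init_tau[0] > 0) {
    x[0] = std::log(init_tau[0]); x[1] = std::log(init_tau[1]);
    if (fit_shift) x[2] = init_shift;
  } else {
    // coarse grid over ordered (tau1, tau2) pairs, shift = 0
    int ng = 7;
    std::vector<double> taus(ng);
    for (int i = 0; i < ng; ++i)
      taus[i] = std::exp(std::log(150.0) + i * (std::log(6000.0) - std::log(150.0)) / (ng - 1));
    double best = R_PosInf;
    for (int i = 0; i < ng; ++i) for (int j = i; j < ng; ++j) {
      std::vector<double> xg(d, 0.0);
      xg[0] = std::log(taus[i]); xg[1] = std::log(taus[j]);
      double fg = obj(xg);
      if (fg < best) { best = fg; x = xg; }
    }
  }
  std::vector<double> step(d, 0.25);
  if (fit_shift) step[2] = 0.5;
  double fx;
  bool conv = nelder_mead(obj, x, fx, step, maxit, 1e-9);
  std::vector<double> coef, fitted;
  double rss = obj(x, &coef, &fitted);
  double tau1 = std::exp(x[0]), tau2 = std::exp(x[1]);
  double a1 = coef[0], a2 = coef[1];
  if (tau1 > tau2) { std::swap(tau1, tau2); std::swap(a1, a2); }
  return List::create(
      _["tau1"] = tau1, _["tau2"] = tau2, _["a1"] = a1, _["a2"] = a2,
      _["background"] = coef[2], _["shift"] = fit_shift ? x[2] : 0.0,
      _["rss"] = rss, _["converged"] = conv,
      _["fitted"] = NumericVector(fitted.begin(), fitted.end()));
}

struct MonoObj {
  const std::vector<double>* y;
  const std::vector<double>* irf;
  const std::vector<double>* w;
  double dt; bool wrap; double tau_lo, tau_hi;
  double operator()(const std::vector<double>& x,
                    std::vector<double>* coef = 0,
                    std::vector<double>* fitted = 0) const {
    double tau = std::exp(x[0]);
    double pen = 0.0;
    if (tau < tau_lo) { pen += tau_lo - tau; tau = tau_lo; }
    if (tau > tau_hi) { pen += tau - tau_hi; tau = tau_hi; }
    int n = y->size();
    std::vector<std::vector<double> > B(2);
    B[0] = conv_irf_exp(*irf, tau, dt, wrap);
    B[1].assign(n, 1.0);
    std::vector<double> cf, ft;
    double rss = nnls_small(B, *y, *w, cf, ft);
    if (coef) *coef = cf;
    if (fitted) *fitted = ft;
    return rss * (1.0 + pen);
  }
};

static List fit_mono_one(const std::vector<double>& yv, const std::vector<double>& iv,
                         double dt, bool wrap, const std::vector<double>& wv,
                         double tau_lo, double tau_hi) {
  MonoObj obj{&yv, &iv, &wv, dt, wrap, tau_lo, tau_hi};
  // golden-section on log tau
  double a = std::log(tau_lo), b = std::log(tau_hi);
  const double g = 0.618033988749895;
  double c = b - g * (b - a), dpt = a + g * (b - a);
  std::vector<double> xc(1, c), xd(1, dpt);
  double fc = obj(xc), fd = obj(xd);
  for (int it = 0; it < 60 && (b - a) > 1e-6; ++it) {
    if (fc < fd) { b = dpt; dpt = c; fd = fc; c = b - g * (b - a); xc[0] = c; fc = obj(xc); }
    else { a = c; c = dpt; fc = fd; dpt = a + g * (b - a); xd[0] = dpt; fd = obj(xd); }
  }
  std::vector<double> x(1, 0.5 * (a + b));
  std::vector<double> coef, fitted;
  double rss = obj(x, &coef, &fitted);
  return List::create(_["tau"] = std::exp(x[0]), _["amplitude"] = coef[0],
                      _["background"] = coef[1], _["rss"] = rss,
                      _["fitted"] = NumericVector(fitted.begin(), fitted.end()));
}

// [[Rcpp::export]]
List fit_monoexp_cpp(NumericVector y, NumericVector irf, double dt, bool wrap,
                     NumericVector w, double tau_lo, double tau_hi) {
  std::vector<double> yv(y.begin(), y.end()), iv(irf.begin(), irf.end()),
      wv(w.begin(), w.end());
  return fit_mono_one(yv, iv, dt, wrap, wv, tau_lo, tau_hi);
}

// Batched pixel-wise mono-exponential fits. counts: npix x nbins matrix.
// Neyman first pass then one Pearson re-weighted pass; returns
// npix x 4 matrix (tau, amplitude, background, chi2_reduced_pearson).
// [[Rcpp::export]]
NumericMatrix fit_monoexp_pixels_cpp(NumericMatrix counts, NumericVector irf,
                                     double dt, bool wrap,
                                     double tau_lo, double tau_hi) {
  int npix = counts.nrow(), n = counts.ncol();
  std::vector<double> iv(irf.begin(), irf.end());
  NumericMatrix out(npix, 4);
  std::vector<double> yv(n), wv(n);
  for (int p = 0; p < npix; ++p) {
    for (int t = 0; t < n; ++t) {
      yv[t] = counts(p, t);
      wv[t] = 1.0 / std::max(yv[t], 1.0);
    }
    List f1 = fit_mono_one(yv, iv, dt, wrap, wv, tau_lo, tau_hi);
    NumericVector ft = f1["fitted"];
    for (int t = 0; t < n; ++t) wv[t] = 1.0 / std::max((double)ft[t], 1e-3);
    List f2 = fit_mono_one(yv, iv, dt, wrap, wv, tau_lo, tau_hi);
    NumericVector ft2 = f2["fitted"];
    double chi2 = 0.0;
    for (int t = 0; t < n; ++t) {
      double m = std::max((double)ft2[t], 1e-3);
      double r = yv[t] - ft2[t];
      chi2 += r * r / m;
    }
    out(p, 0) = f2["tau"];
    out(p, 1) = f2["amplitude"];
    out(p, 2) = f2["background"];
    out(p, 3) = chi2 / std::max(1, n - 3);
  }
  return out;
}

// Rank-order (quantile) filter over a disc or annulus neighbourhood.
// offsets: k x 2 integer matrix (dx, dy). Quantile type 7, pixels outside the
// image are dropped from the neighbourhood.
// [[Rcpp::export]]
NumericMatrix rank_filter_cpp(NumericMatrix img, IntegerMatrix offsets, double prob) {
  int nr = img.nrow(), nc = img.ncol(), k = offsets.nrow();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int o = 0; o < k; ++o) {
        int ii = i + offsets(o, 0), jj = j + offsets(o, 1);
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) buf.push_back(img(ii, jj));
      }
      int m = buf.size();
      std::sort(buf.begin(), buf.end());
      double h = (m - 1) * prob;
      int lo = (int)std::floor(h);
      double fr = h - lo;
      out(i, j) = lo + 1 < m ? buf[lo] + fr * (buf[lo + 1] - buf[lo]) : buf[lo];
    }
  }
  return out;
}

// 8- (or 4-) connected component labeling of a logical mask.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > nb;
  for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) {
    if (dx == 0 && dy == 0) continue;
    if (connectivity == 4 && dx != 0 && dy != 0) continue;
    nb.push_back(std::make_pair(dx, dy));
  }
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!mask(i, j) || lab(i, j) != 0) continue;
    lab(i, j) = ++next;
    q.push(std::make_pair(i, j));
    while (!q.empty()) {
      std::pair<int, int> p = q.front(); q.pop();
      for (size_t o = 0; o < nb.size(); ++o) {
        int ii = p.first + nb[o].first, jj = p.second + nb[o].second;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (mask(ii, jj) && lab(ii, jj) == 0) {
          lab(ii, jj) = next;
          q.push(std::make_pair(ii, jj));
        }
      }
    }
  }
  return lab;
}
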
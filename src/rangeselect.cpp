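#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Accumulate weighted bivariate normal kernels onto a grid of cell centers.
// Covariances are per point (vxx, vyy, vxy recycled); evaluation is truncated
// beyond `cut` marginal SDs, where the density is negligible.
// [[Rcpp::export]]
NumericMatrix cpp_accumulate_gaussian(double x0, double y0, double grain,
                                      int nrows, int ncols,
                                      NumericVector px, NumericVector py,
                                      NumericVector vxx, NumericVector vyy,
                                      NumericVector vxy, NumericVector w,
                                      double cut = 6.0) {
  NumericMatrix out(nrows, ncols);
  int n = px.size();
  for (int i = 0; i < n; ++i) {
    double a = vxx[i % vxx.size()], b = vyy[i % vyy.size()],
           c = vxy[i % vxy.size()];
    double det = a * b - c * c;
    if (det <= 0 || a <= 0 || b <= 0) stop("kernel covariance not SPD");
    double inva = b / det, invb = a / det, invc = -c / det;
    double norm = w[i % w.size()] / (2.0 * M_PI * std::sqrt(det));
    double sdx = std::sqrt(a), sdy = std::sqrt(b);
    int c0 = (int)std::floor((px[i] - cut * sdx - x0) / grain - 0.5);
    int c1 = (int)std::ceil((px[i] + cut * sdx - x0) / grain - 0.5);
    int r0 = (int)std::floor((py[i] - cut * sdy - y0) / grain - 0.5);
    int r1 = (int)std::ceil((py[i] + cut * sdy - y0) / grain - 0.5);
    if (c0 < 0) c0 = 0; if (r0 < 0) r0 = 0;
    if (c1 > ncols - 1) c1 = ncols - 1;
    if (r1 > nrows - 1) r1 = nrows - 1;
    for (int cc = c0; cc <= c1; ++cc) {
      double dx = x0 + (cc + 0.5) * grain - px[i];
      for (int rr = r0; rr <= r1; ++rr) {
        double dy = y0 + (rr + 0.5) * grain - py[i];
        double q = inva * dx * dx + 2.0 * invc * dx * dy + invb * dy * dy;
        if (q < 2.0 * cut * cut + 50.0)
          out(rr, cc) += norm * std::exp(-0.5 * q);
      }
    }
  }
  return out;
}

// k nearest neighbours by brute force (indices 1-based, self excluded).
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (k >= n) stop("k must be < n");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      // tie-break on index for determinism
      d[j] = std::make_pair(dx * dx + dy * dy, j);
    }
    d[i].first = R_PosInf;
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) out(i, j) = d[j].second + 1;
  }
  return out;
}

struct Tri {
  int a, b, c;   // CCW order
};

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// incircle predicate: > 0 when d lies inside the circumcircle of the CCW
// triangle (a, b, c)
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double dx, double dy) {
  double adx = ax - dx, ady = ay - dy;
  double bdx = bx - dx, bdy = by - dy;
  double cdx = cx - dx, cdy = cy - dy;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - cdy * bd) -
         ady * (bdx * cd - cdx * bd) +
         ad * (bdx * cdy - cdx * bdy);
}

// Delaunay triangulation (Bowyer-Watson with determinant predicates).
// Points must be unique; collinear inputs yield zero triangles. Zero-area
// slivers are kept so the triangle union always tiles the convex hull.
// Returns an m x 3 matrix of 1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  // scale to the unit box for numerical stability
  double xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y);
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) return IntegerMatrix(0, 3);
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) {
    px[i] = (x[i] - xmin) / span;
    py[i] = (y[i] - ymin) / span;
  }
  // super-triangle well outside the unit box (CCW)
  px[n] = -30.0; py[n] = -30.0;
  px[n + 1] = 31.0; py[n + 1] = -30.0;
  px[n + 2] = 0.5; py[n + 2] = 45.0;
  std::vector<Tri> tris;
  Tri st; st.a = n; st.b = n + 1; st.c = n + 2;
  tris.push_back(st);
  std::vector<char> bad;
  for (int i = 0; i < n; ++i) {
    bad.assign(tris.size(), 0);
    std::map<std::pair<int, int>, int> edge_count;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (incircle(px[tris[t].a], py[tris[t].a], px[tris[t].b],
                   py[tris[t].b], px[tris[t].c], py[tris[t].c],
                   px[i], py[i]) > 0) {
        bad[t] = 1;
        int v[3] = {tris[t].a, tris[t].b, tris[t].c};
        for (int e = 0; e < 3; ++e) {
          int u = v[e], w = v[(e + 1) % 3];
          std::pair<int, int> key(std::min(u, w), std::max(u, w));
          edge_count[key]++;
        }
      }
    }
    std::vector<Tri> keep;
    keep.reserve(tris.size());
    for (size_t t = 0; t < tris.size(); ++t)
      if (!bad[t]) keep.push_back(tris[t]);
    for (std::map<std::pair<int, int>, int>::iterator it = edge_count.begin();
         it != edge_count.end(); ++it) {
      if (it->second != 1) continue;  // internal edge of the cavity
      Tri nt; nt.a = it->first.first; nt.b = it->first.second; nt.c = i;
      if (orient2d(px[nt.a], py[nt.a], px[nt.b], py[nt.b],
                   px[nt.c], py[nt.c]) < 0)
        std::swap(nt.a, nt.b);        // keep CCW; zero-area slivers retained
      keep.push_back(nt);
    }
    tris.swap(keep);
  }
  std::vector<std::array<int, 3> > out;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (tris[t].a < n && tris[t].b < n && tris[t].c < n) {
      std::array<int, 3> tri = {{tris[t].a, tris[t].b, tris[t].c}};
      out.push_back(tri);
    }
  }
  // Boundary repair: roundoff in conflict decisions near the far
  // super-triangle can notch the hull by a sliver. Chain the directed
  // boundary edges and ear-fill every concave corner so the triangle union
  // tiles the convex hull exactly.
  if (!out.empty()) {
    std::map<std::pair<int, int>, int> undirected;
    for (size_t t = 0; t < out.size(); ++t)
      for (int e = 0; e < 3; ++e) {
        int u = out[t][e], w = out[t][(e + 1) % 3];
        undirected[std::make_pair(std::min(u, w), std::max(u, w))]++;
      }
    std::map<int, int> nxt;   // boundary edges, oriented CCW
    for (size_t t = 0; t < out.size(); ++t)
      for (int e = 0; e < 3; ++e) {
        int u = out[t][e], w = out[t][(e + 1) % 3];
        if (undirected[std::make_pair(std::min(u, w), std::max(u, w))] == 1)
          nxt[u] = w;
      }
    if (!nxt.empty()) {
      std::vector<int> cyc;
      int start = nxt.begin()->first, v = start;
      size_t guard = 0;
      do {
        cyc.push_back(v);
        std::map<int, int>::iterator it = nxt.find(v);
        if (it == nxt.end()) { cyc.clear(); break; }
        v = it->second;
      } while (v != start && ++guard <= nxt.size());
      if (cyc.size() == nxt.size() && cyc.size() >= 3) {
        bool filled = true;
        while (filled && cyc.size() > 3) {
          filled = false;
          for (size_t i = 0; i < cyc.size(); ++i) {
            int a = cyc[i], b = cyc[(i + 1) % cyc.size()],
                c = cyc[(i + 2) % cyc.size()];
            if (orient2d(px[a], py[a], px[b], py[b], px[c], py[c]) < 0) {
              std::array<int, 3> tri = {{a, c, b}};
              out.push_back(tri);
              cyc.erase(cyc.begin() + (i + 1) % cyc.size());
              filled = true;
              break;
            }
          }
        }
      }
    }
  }
  IntegerMatrix res(out.size(), 3);
  for (size_t t = 0; t < out.size(); ++t)
    for (int j = 0; j < 3; ++j) res(t, j) = out[t][j] + 1;
  return res;
}

static inline double hermite(int k, double t) {
  switch (k) {
    case 0: return 1.0;
    case 1: return t;
    case 2: return t * t - 1.0;
    case 3: return t * (t * t - 3.0);
    case 4: return t * t * (t * t - 6.0) + 3.0;
  }
  return 0.0;
}

// Fourth-order integrated density-derivative functionals psi_r, |r| = 4,
// estimated with an isotropic Gaussian pilot of SD g on (pre-sphered) data.
// Returns (psi40, psi31, psi22, psi13, psi04).
// [[Rcpp::export]]
NumericVector cpp_psi4(NumericVector x, NumericVector y, double g) {
  int n = x.size();
  double s[5] = {0, 0, 0, 0, 0};
  double inv_g = 1.0 / g;
  double c0 = 1.0 / (2.0 * M_PI * g * g);  // phi_g(u) * phi_g(v) prefactor
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double u = (x[i] - x[j]) * inv_g, v = (y[i] - y[j]) * inv_g;
      double e = c0 * std::exp(-0.5 * (u * u + v * v));
      double mult = (j == i) ? 1.0 : 2.0;
      for (int r = 0; r <= 4; ++r)
        s[r] += mult * hermite(4 - r, u) * hermite(r, v) * e;
    }
  }
  NumericVector out(5);
  double scale = std::pow(inv_g, 4) / ((double)n * (double)n);
  for (int r = 0; r < 5; ++r) out[r] = s[r] * scale;
  return out;
}

// ---- Brownian bridge likelihood machinery -------------------------------

// Negative log-likelihood of sigma2 for the leave-one-out bridge construction
// on fixes [a, b] (0-based, inclusive): local odd positions are scored
// against the bridge defined by their neighbours. The predictive variance
// carries the bridge term, the (interpolation-weighted) endpoint location
// errors, and the scored fix's own location error.
static double bb_nll(const double *t, const double *x, const double *y,
                     const double *e2, int a, int b, double sig2, int *m) {
  double nll = 0.0;
  int cnt = 0;
  for (int e = a + 1; e + 1 <= b; e += 2) {
    double T = t[e + 1] - t[e - 1];
    if (T <= 0) continue;
    double al = (t[e] - t[e - 1]) / T;
    double mx = x[e - 1] + al * (x[e + 1] - x[e - 1]);
    double my = y[e - 1] + al * (y[e + 1] - y[e - 1]);
    double v = T * al * (1.0 - al) * sig2 + e2[e] +
               (1.0 - al) * (1.0 - al) * e2[e - 1] + al * al * e2[e + 1];
    if (v <= 0) v = 1e-12;
    double d2 = (x[e] - mx) * (x[e] - mx) + (y[e] - my) * (y[e] - my);
    nll += std::log(2.0 * M_PI * v) + d2 / (2.0 * v);
    cnt++;
  }
  if (m) *m = cnt;
  return nll;
}

static double bb_mle(const double *t, const double *x, const double *y,
                     const double *e2, int a, int b, double hi, int *m) {
  // golden-section on [0, hi]
  const double gr = 0.6180339887498949;
  double lo = 0.0, c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
  double fc = bb_nll(t, x, y, e2, a, b, c, m);
  double fd = bb_nll(t, x, y, e2, a, b, d, NULL);
  for (int it = 0; it < 200 && (hi - lo) > 1e-10 * (1.0 + hi); ++it) {
    if (fc < fd) {
      hi = d; d = c; fd = fc;
      c = hi - gr * (hi - lo);
      fc = bb_nll(t, x, y, e2, a, b, c, NULL);
    } else {
      lo = c; c = d; fc = fd;
      d = lo + gr * (hi - lo);
      fd = bb_nll(t, x, y, e2, a, b, d, NULL);
    }
  }
  return 0.5 * (lo + hi);
}

// Windowed dynamic Brownian-bridge motion variances with BIC breakpoint
// selection. Returns per-fix sigma2 (m^2/s).
// [[Rcpp::export]]
NumericVector cpp_dbbmm_variances(NumericVector t, NumericVector x,
                                  NumericVector y, NumericVector err2,
                                  int window, int margin, double sig2_hi) {
  int n = t.size();
  if (window > n) stop("window larger than number of fixes");
  NumericVector sum(n), cnt(n);
  const double *tp = t.begin(), *xp = x.begin(), *yp = y.begin(),
               *ep = err2.begin();
  for (int s = 0; s + window <= n; ++s) {
    int a = s, b = s + window - 1;
    int m1 = 0;
    double sig_single = bb_mle(tp, xp, yp, ep, a, b, sig2_hi, &m1);
    double nll_single = bb_nll(tp, xp, yp, ep, a, b, sig_single, NULL);
    double best_bic = 2.0 * nll_single + 1.0 * std::log((double)std::max(m1, 1));
    int best_b = -1;
    double best_l = sig_single, best_r = sig_single;
    for (int bp = margin; bp <= window - 1 - margin; ++bp) {
      int mid = a + bp;
      int mL = 0, mR = 0;
      double sL = bb_mle(tp, xp, yp, ep, a, mid, sig2_hi, &mL);
      double sR = bb_mle(tp, xp, yp, ep, mid, b, sig2_hi, &mR);
      double nll2 = bb_nll(tp, xp, yp, ep, a, mid, sL, NULL) +
                    bb_nll(tp, xp, yp, ep, mid, b, sR, NULL);
      int m2 = std::max(mL + mR, 1);
      double bic = 2.0 * nll2 + 2.0 * std::log((double)m2);
      if (bic < best_bic - 1e-12) {
        best_bic = bic; best_b = bp; best_l = sL; best_r = sR;
      }
    }
    for (int i = 0; i < window; ++i) {
      double v = (best_b < 0) ? sig_single
                              : (i <= best_b ? best_l : best_r);
      sum[s + i] += v;
      cnt[s + i] += 1.0;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sum[i] / std::max(cnt[i], 1.0);
  // trajectory margins inherit the nearest interior value
  for (int i = 0; i < margin && i < n; ++i) out[i] = out[std::min(margin, n - 1)];
  for (int i = n - margin; i < n; ++i)
    if (i >= 0) out[i] = out[std::max(n - margin - 1, 0)];
  return out;
}

// Single-range Brownian-motion variance MLE (used by the R front end for
// cross-checking and speed on long tracks).
// [[Rcpp::export]]
List cpp_bbmm_mle(NumericVector t, NumericVector x, NumericVector y,
                  NumericVector err2, double sig2_hi) {
  int m = 0;
  double s = bb_mle(t.begin(), x.begin(), y.begin(), err2.begin(),
                    0, t.size() - 1, sig2_hi, &m);
  double nll = bb_nll(t.begin(), x.begin(), y.begin(), err2.begin(),
                      0, t.size() - 1, s, NULL);
  return List::create(_["sigma2"] = s, _["nll"] = nll, _["n_bridges"] = m);
}
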
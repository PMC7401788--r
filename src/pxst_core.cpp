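#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear read of ref at fractional 0-based (ry, rx). Returns false when any
// of the four neighbours is outside the grid or uncovered.
static inline bool bilin_read(const double* ref, const int* cov,
                              int mr, int mc, double ry, double rx,
                              double& out) {
  int i0 = (int)std::floor(ry), j0 = (int)std::floor(rx);
  if (i0 < 0 || j0 < 0 || i0 + 1 >= mr || j0 + 1 >= mc) return false;
  double fy = ry - i0, fx = rx - j0;
  int a = i0 + mr * j0;
  int b = a + 1;          // (i0+1, j0)
  int c = a + mr;         // (i0, j0+1)
  int d = c + 1;          // (i0+1, j0+1)
  if (!cov[a] || !cov[b] || !cov[c] || !cov[d]) return false;
  out = (1 - fy) * (1 - fx) * ref[a] + fy * (1 - fx) * ref[b] +
        (1 - fy) * fx * ref[c] + fy * fx * ref[d];
  return true;
}

// [[Rcpp::export]]
List cpp_splat_reference(NumericVector images, NumericMatrix W,
                         LogicalMatrix mask, NumericVector u,
                         NumericMatrix dx, NumericVector origin,
                         double pitch, IntegerVector ref_shape) {
  IntegerVector dim = images.attr("dim");
  int nr = dim[0], nc = dim[1], N = dim[2];
  int mr = ref_shape[0], mc = ref_shape[1];
  NumericMatrix num(mr, mc), den(mr, mc), cnt(mr, mc);
  const double* im = images.begin();
  const double* uu = u.begin();
  for (int n = 0; n < N; ++n) {
    double dy = dx(n, 0), dxn = dx(n, 1);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!mask(i, j)) continue;
        double w = W(i, j);
        if (!(w > 0)) continue;
        double ry = (uu[i + nr * j] - dy - origin[0]) / pitch;
        double rx = (uu[i + nr * j + nr * nc] - dxn - origin[1]) / pitch;
        int i0 = (int)std::floor(ry), j0 = (int)std::floor(rx);
        if (i0 < 0 || j0 < 0 || i0 + 1 >= mr || j0 + 1 >= mc) continue;
        double fy = ry - i0, fx = rx - j0;
        double val = im[i + nr * j + (size_t)nr * nc * n] / w;
        double wt = w * w;
        double w00 = (1 - fy) * (1 - fx), w10 = fy * (1 - fx);
        double w01 = (1 - fy) * fx,       w11 = fy * fx;
        num(i0, j0)         += w00 * wt * val; den(i0, j0)         += w00 * wt;
        num(i0 + 1, j0)     += w10 * wt * val; den(i0 + 1, j0)     += w10 * wt;
        num(i0, j0 + 1)     += w01 * wt * val; den(i0, j0 + 1)     += w01 * wt;
        num(i0 + 1, j0 + 1) += w11 * wt * val; den(i0 + 1, j0 + 1) += w11 * wt;
        cnt(i0, j0) += w00; cnt(i0 + 1, j0) += w10;
        cnt(i0, j0 + 1) += w01; cnt(i0 + 1, j0 + 1) += w11;
      }
    }
  }
  return List::create(_["num"] = num, _["den"] = den, _["count"] = cnt);
}

// per-axis 3-point parabola vertex on the 3x3 error patch around the integer
// minimum; a true minimum at the centre node confines the vertex to +-1/2
static inline double parabola_vertex(double em, double e0, double ep) {
  double den = em - 2 * e0 + ep;
  if (den <= 0) return 0;
  double o = 0.5 * (em - ep) / den;
  if (o > 0.5) o = 0.5;
  if (o < -0.5) o = -0.5;
  return o;
}

// successive per-axis parabolic refinement with halving step; eval returns
// the (mean) error at a continuous shift or +Inf when not computable
template <typename F>
static inline void refine_subpixel(F eval, double& cy, double& cx,
                                   double e0) {
  for (double h = 0.5; h >= 0.249; h /= 2) {
    double em = eval(cy, cx - h), ep = eval(cy, cx + h);
    if (R_finite(em) && R_finite(ep) && R_finite(e0)) {
      cx += h * parabola_vertex(em, e0, ep);
      e0 = eval(cy, cx);
    }
    em = eval(cy - h, cx); ep = eval(cy + h, cx);
    if (R_finite(em) && R_finite(ep) && R_finite(e0)) {
      cy += h * parabola_vertex(em, e0, ep);
      e0 = eval(cy, cx);
    }
  }
}

// Per-detector-pixel displacement update: for each pixel minimize the mean
// squared residual over integer reference-grid shifts within search_radius,
// then refine to sub-pixel by a quadratic fit. Returns du in reference pixels.
// [[Rcpp::export]]
List cpp_update_pixel_map(NumericVector images, NumericMatrix W,
                          LogicalMatrix mask, NumericMatrix ref,
                          IntegerMatrix cov, NumericVector u,
                          NumericMatrix dx, NumericVector origin,
                          double pitch, int radius, int min_frames,
                          double flat_tol) {
  IntegerVector dim = images.attr("dim");
  int nr = dim[0], nc = dim[1], N = dim[2];
  int mr = ref.nrow(), mc = ref.ncol();
  int side = 2 * radius + 1;
  NumericVector du(nr * nc * 2);
  LogicalMatrix flags(nr, nc);
  const double* im = images.begin();
  const double* uu = u.begin();
  const double* rf = ref.begin();
  const int* cv = cov.begin();

  // shift enumeration sorted by radius^2 so ties resolve to smallest shift
  std::vector<int> order(side * side);
  for (int k = 0; k < side * side; ++k) order[k] = k;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    int ay = a / side - radius, ax = a % side - radius;
    int by = b / side - radius, bx = b % side - radius;
    return ay * ay + ax * ax < by * by + bx * bx;
  });

  std::vector<double> err(side * side);
  std::vector<int> nval(side * side);
  std::vector<double> ry0(N), rx0(N);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) { flags(i, j) = true; continue; }
      double w = W(i, j);
      if (!(w > 0)) { flags(i, j) = true; continue; }
      for (int n = 0; n < N; ++n) {
        ry0[n] = (uu[i + nr * j] - dx(n, 0) - origin[0]) / pitch;
        rx0[n] = (uu[i + nr * j + nr * nc] - dx(n, 1) - origin[1]) / pitch;
      }
      for (int k = 0; k < side * side; ++k) { err[k] = 0; nval[k] = 0; }
      for (int sy = -radius; sy <= radius; ++sy) {
        for (int sx = -radius; sx <= radius; ++sx) {
          int k = (sy + radius) * side + (sx + radius);
          double e = 0; int m = 0;
          for (int n = 0; n < N; ++n) {
            double val = im[i + nr * j + (size_t)nr * nc * n];
            if (!R_finite(val)) continue;   // sample excluded (e.g. split-half)
            double pred;
            if (!bilin_read(rf, cv, mr, mc, ry0[n] + sy, rx0[n] + sx, pred))
              continue;
            double r = val - w * pred;
            e += r * r; ++m;
          }
          err[k] = e; nval[k] = m;
        }
      }
      int best = -1; double beste = R_PosInf, maxe = 0;
      for (int q = 0; q < side * side; ++q) {
        int k = order[q];
        if (nval[k] < min_frames) continue;
        double e = err[k] / nval[k];
        if (e < beste) { beste = e; best = k; }
        if (e > maxe) maxe = e;
      }
      if (best < 0) { flags(i, j) = true; continue; }
      // degenerate (flat) error surface: no information, keep previous value
      if (maxe - beste <= flat_tol * maxe) { flags(i, j) = true; continue; }
      int by = best / side - radius, bx = best % side - radius;
      double cy = by, cx = bx;
      if (beste > 0) {
        auto eval = [&](double sy, double sx) -> double {
          double e = 0; int m = 0;
          for (int n = 0; n < N; ++n) {
            double val = im[i + nr * j + (size_t)nr * nc * n];
            if (!R_finite(val)) continue;
            double pred;
            if (!bilin_read(rf, cv, mr, mc, ry0[n] + sy, rx0[n] + sx, pred))
              continue;
            double r = val - w * pred;
            e += r * r; ++m;
          }
          return m >= min_frames ? e / m : R_PosInf;
        };
        refine_subpixel(eval, cy, cx, beste);
      }
      du[i + nr * j] = cy;
      du[i + nr * j + nr * nc] = cx;
    }
  }
  du.attr("dim") = IntegerVector::create(nr, nc, 2);
  return List::create(_["du"] = du, _["flagged"] = flags);
}

// Per-frame global offset minimizing that frame's SSE.
// [[Rcpp::export]]
List cpp_update_translations(NumericVector images, NumericMatrix W,
                             LogicalMatrix mask, NumericMatrix ref,
                             IntegerMatrix cov, NumericVector u,
                             NumericMatrix dx, NumericVector origin,
                             double pitch, int radius) {
  IntegerVector dim = images.attr("dim");
  int nr = dim[0], nc = dim[1], N = dim[2];
  int mr = ref.nrow(), mc = ref.ncol();
  int side = 2 * radius + 1;
  NumericMatrix shift(N, 2);
  LogicalVector flags(N);
  const double* im = images.begin();
  const double* uu = u.begin();
  const double* rf = ref.begin();
  const int* cv = cov.begin();
  std::vector<double> err(side * side);
  std::vector<double> npix(side * side);

  for (int n = 0; n < N; ++n) {
    std::fill(err.begin(), err.end(), 0.0);
    std::fill(npix.begin(), npix.end(), 0.0);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!mask(i, j)) continue;
        double w = W(i, j);
        if (!(w > 0)) continue;
        double ry = (uu[i + nr * j] - dx(n, 0) - origin[0]) / pitch;
        double rx = (uu[i + nr * j + nr * nc] - dx(n, 1) - origin[1]) / pitch;
        double val = im[i + nr * j + (size_t)nr * nc * n];
        for (int sy = -radius; sy <= radius; ++sy)
          for (int sx = -radius; sx <= radius; ++sx) {
            double pred;
            if (!bilin_read(rf, cv, mr, mc, ry + sy, rx + sx, pred)) continue;
            int k = (sy + radius) * side + (sx + radius);
            double r = val - w * pred;
            err[k] += r * r; npix[k] += 1;
          }
      }
    }
    int best = -1; double beste = R_PosInf;
    for (int k = 0; k < side * side; ++k) {
      if (npix[k] < 1) continue;
      double e = err[k] / npix[k];
      if (e < beste) { beste = e; best = k; }
    }
    if (best < 0) { flags[n] = true; continue; }
    int by = best / side - radius, bx = best % side - radius;
    double cy = by, cx = bx;
    if (beste > 0) {
      auto eval = [&](double sy, double sx) -> double {
        double e = 0; double m = 0;
        for (int j = 0; j < nc; ++j)
          for (int i = 0; i < nr; ++i) {
            if (!mask(i, j)) continue;
            double w = W(i, j);
            if (!(w > 0)) continue;
            double ry = (uu[i + nr * j] - dx(n, 0) - origin[0]) / pitch + sy;
            double rx = (uu[i + nr * j + nr * nc] - dx(n, 1) - origin[1]) /
                        pitch + sx;
            double pred;
            if (!bilin_read(rf, cv, mr, mc, ry, rx, pred)) continue;
            double r = im[i + nr * j + (size_t)nr * nc * n] - w * pred;
            e += r * r; m += 1;
          }
        return m >= 1 ? e / m : R_PosInf;
      };
      refine_subpixel(eval, cy, cx, beste);
    }
    shift(n, 0) = cy;
    shift(n, 1) = cx;
  }
  return List::create(_["shift"] = shift, _["flagged"] = flags);
}

// Residual decomposition of the forward model at the current state.
// [[Rcpp::export]]
List cpp_error_map(NumericVector images, NumericMatrix W, LogicalMatrix mask,
                   NumericMatrix ref, IntegerMatrix cov, NumericVector u,
                   NumericMatrix dx, NumericVector origin, double pitch) {
  IntegerVector dim = images.attr("dim");
  int nr = dim[0], nc = dim[1], N = dim[2];
  int mr = ref.nrow(), mc = ref.ncol();
  NumericMatrix pixel_sse(nr, nc);
  NumericVector frame_sse(N);
  double nterms = 0;
  const double* im = images.begin();
  const double* uu = u.begin();
  const double* rf = ref.begin();
  const int* cv = cov.begin();
  double total = 0;
  for (int n = 0; n < N; ++n) {
    double fs = 0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        if (!mask(i, j)) continue;
        double w = W(i, j);
        if (!(w > 0)) continue;
        double ry = (uu[i + nr * j] - dx(n, 0) - origin[0]) / pitch;
        double rx = (uu[i + nr * j + nr * nc] - dx(n, 1) - origin[1]) / pitch;
        double pred;
        if (!bilin_read(rf, cv, mr, mc, ry, rx, pred)) continue;
        double r = im[i + nr * j + (size_t)nr * nc * n] - w * pred;
        pixel_sse(i, j) += r * r;
        fs += r * r;
        nterms += 1;
      }
    frame_sse[n] = fs;
    total += fs;
  }
  return List::create(_["pixel_sse"] = pixel_sse, _["frame_sse"] = frame_sse,
                      _["total"] = total, _["n_terms"] = nterms);
}

// Vectorized bilinear lookup used by the geometric-mode simulator.
// [[Rcpp::export]]
NumericVector cpp_bilinear_lookup(NumericMatrix ref, IntegerMatrix cov,
                                  NumericVector ry, NumericVector rx,
                                  double fill) {
  int n = ry.size();
  int mr = ref.nrow(), mc = ref.ncol();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double v;
    out[k] = bilin_read(ref.begin(), cov.begin(), mr, mc, ry[k], rx[k], v)
               ? v : fill;
  }
  out.attr("dim") = ry.attr("dim");
  return out;
}
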
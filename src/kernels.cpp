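#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic (order-3) uniform B-spline basis on [0,1), four active functions per
// span.  Derivative weights are with respect to the local coordinate t; the
// caller rescales by 1/h (first) or 1/h^2 (second).
static inline void bspl_w(double t, double *w) {
  double t2 = t * t, t3 = t2 * t, mt = 1.0 - t;
  w[0] = mt * mt * mt / 6.0;
  w[1] = (3.0 * t3 - 6.0 * t2 + 4.0) / 6.0;
  w[2] = (-3.0 * t3 + 3.0 * t2 + 3.0 * t + 1.0) / 6.0;
  w[3] = t3 / 6.0;
}
static inline void bspl_dw(double t, double *w) {
  double t2 = t * t, mt = 1.0 - t;
  w[0] = -mt * mt / 2.0;
  w[1] = (3.0 * t2 - 4.0 * t) / 2.0;
  w[2] = (-3.0 * t2 + 2.0 * t + 1.0) / 2.0;
  w[3] = t2 / 2.0;
}
static inline void bspl_ddw(double t, double *w) {
  w[0] = 1.0 - t;
  w[1] = 3.0 * t - 2.0;
  w[2] = 1.0 - 3.0 * t;
  w[3] = t;
}

// Locate the B-spline span for coordinate x on axis with origin o, spacing h,
// K control points.  Returns base control index (0-based, first of 4) and
// local coordinate t in [0,1].  Support requires base >= 0 and base+3 <= K-1.
static inline bool span_locate(double x, double o, double h, int K,
                               int *base, double *t) {
  double u = (x - o) / h;
  int i = (int)std::floor(u);
  double tt = u - i;
  int b = i - 1;
  if (b < 0 || b + 3 > K - 1) return false;
  *base = b;
  *t = tt;
  return true;
}

// [[Rcpp::export]]
NumericMatrix cpp_ffd_disp(NumericMatrix pts, NumericVector origin,
                           NumericVector spacing, IntegerVector shape,
                           NumericMatrix coef) {
  int n = pts.nrow();
  int K1 = shape[0], K2 = shape[1];
  NumericMatrix out(n, 3);
  double w[3][4];
  for (int p = 0; p < n; ++p) {
    int b[3]; double t[3];
    for (int a = 0; a < 3; ++a) {
      if (!span_locate(pts(p, a), origin[a], spacing[a], shape[a], &b[a], &t[a]))
        stop("point %d outside FFD lattice support (axis %d)", p + 1, a + 1);
      bspl_w(t[a], w[a]);
    }
    double acc[3] = {0.0, 0.0, 0.0};
    for (int c = 0; c < 4; ++c) {
      for (int bb = 0; bb < 4; ++bb) {
        double wyz = w[1][bb] * w[2][c];
        int off = (b[1] + bb) * K1 + (b[2] + c) * K1 * K2 + b[0];
        for (int a = 0; a < 4; ++a) {
          double ww = w[0][a] * wyz;
          int idx = off + a;
          acc[0] += ww * coef(idx, 0);
          acc[1] += ww * coef(idx, 1);
          acc[2] += ww * coef(idx, 2);
        }
      }
    }
    out(p, 0) = acc[0]; out(p, 1) = acc[1]; out(p, 2) = acc[2];
  }
  return out;
}

// Accumulate d(cost)/d(coef) from per-point upstream gradients d(cost)/d(T(x)).
// [[Rcpp::export]]
NumericMatrix cpp_ffd_backprop(NumericMatrix pts, NumericMatrix upstream,
                               NumericVector origin, NumericVector spacing,
                               IntegerVector shape) {
  int n = pts.nrow();
  int K1 = shape[0], K2 = shape[1], K3 = shape[2];
  NumericMatrix grad(K1 * K2 * K3, 3);
  double w[3][4];
  for (int p = 0; p < n; ++p) {
    int b[3]; double t[3];
    for (int a = 0; a < 3; ++a) {
      if (!span_locate(pts(p, a), origin[a], spacing[a], shape[a], &b[a], &t[a]))
        stop("point %d outside FFD lattice support (axis %d)", p + 1, a + 1);
      bspl_w(t[a], w[a]);
    }
    double u0 = upstream(p, 0), u1 = upstream(p, 1), u2 = upstream(p, 2);
    for (int c = 0; c < 4; ++c) {
      for (int bb = 0; bb < 4; ++bb) {
        double wyz = w[1][bb] * w[2][c];
        int off = (b[1] + bb) * K1 + (b[2] + c) * K1 * K2 + b[0];
        for (int a = 0; a < 4; ++a) {
          double ww = w[0][a] * wyz;
          int idx = off + a;
          grad(idx, 0) += ww * u0;
          grad(idx, 1) += ww * u1;
          grad(idx, 2) += ww * u2;
        }
      }
    }
  }
  return grad;
}

// Determinant of the spatial gradient of T(x) = A x + t + disp(x):
// grad T = A + d(disp)/dx, with analytic B-spline derivative weights.
// [[Rcpp::export]]
NumericVector cpp_ffd_jacdet(NumericMatrix pts, NumericVector origin,
                             NumericVector spacing, IntegerVector shape,
                             NumericMatrix coef, NumericMatrix affine) {
  int n = pts.nrow();
  int K1 = shape[0], K2 = shape[1];
  NumericVector out(n);
  double w[3][4], dw[3][4];
  for (int p = 0; p < n; ++p) {
    int b[3]; double t[3];
    for (int a = 0; a < 3; ++a) {
      if (!span_locate(pts(p, a), origin[a], spacing[a], shape[a], &b[a], &t[a]))
        stop("point %d outside FFD lattice support (axis %d)", p + 1, a + 1);
      bspl_w(t[a], w[a]);
      bspl_dw(t[a], dw[a]);
    }
    // G[d][j] = d disp_d / d x_j
    double G[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int c = 0; c < 4; ++c) {
      for (int bb = 0; bb < 4; ++bb) {
        int off = (b[1] + bb) * K1 + (b[2] + c) * K1 * K2 + b[0];
        for (int a = 0; a < 4; ++a) {
          int idx = off + a;
          double wj[3];
          wj[0] = dw[0][a] * w[1][bb] * w[2][c] / spacing[0];
          wj[1] = w[0][a] * dw[1][bb] * w[2][c] / spacing[1];
          wj[2] = w[0][a] * w[1][bb] * dw[2][c] / spacing[2];
          for (int d = 0; d < 3; ++d) {
            double cd = coef(idx, d);
            G[d][0] += wj[0] * cd;
            G[d][1] += wj[1] * cd;
            G[d][2] += wj[2] * cd;
          }
        }
      }
    }
    for (int d = 0; d < 3; ++d)
      for (int j = 0; j < 3; ++j)
        G[d][j] += affine(d, j);
    out[p] = G[0][0] * (G[1][1] * G[2][2] - G[1][2] * G[2][1])
           - G[0][1] * (G[1][0] * G[2][2] - G[1][2] * G[2][0])
           + G[0][2] * (G[1][0] * G[2][1] - G[1][1] * G[2][0]);
  }
  return out;
}

// Bending energy: mean over points of the squared Frobenius norm of the
// 3x3x3 second-derivative tensor of the displacement field (the affine part
// has vanishing second derivatives).  Optionally also its gradient w.r.t.
// the control-point coefficients.
// [[Rcpp::export]]
List cpp_ffd_bend(NumericMatrix pts, NumericVector origin,
                  NumericVector spacing, IntegerVector shape,
                  NumericMatrix coef, bool want_grad) {
  int n = pts.nrow();
  int K1 = shape[0], K2 = shape[1], K3 = shape[2];
  NumericMatrix grad(want_grad ? K1 * K2 * K3 : 1, 3);
  double energy = 0.0;
  double w[3][4], dw[3][4], ddw[3][4];
  // the 6 distinct (j,k) second-derivative pairs; off-diagonals count twice
  const int JJ[6] = {0, 1, 2, 0, 0, 1};
  const int KK[6] = {0, 1, 2, 1, 2, 2};
  const double MULT[6] = {1.0, 1.0, 1.0, 2.0, 2.0, 2.0};
  for (int p = 0; p < n; ++p) {
    int b[3]; double t[3];
    for (int a = 0; a < 3; ++a) {
      if (!span_locate(pts(p, a), origin[a], spacing[a], shape[a], &b[a], &t[a]))
        stop("point %d outside FFD lattice support (axis %d)", p + 1, a + 1);
      bspl_w(t[a], w[a]);
      bspl_dw(t[a], dw[a]);
      bspl_ddw(t[a], ddw[a]);
    }
    // H[d][q]: second derivative pair q of displacement component d
    double H[3][6] = {{0, 0, 0, 0, 0, 0}, {0, 0, 0, 0, 0, 0},
                      {0, 0, 0, 0, 0, 0}};
    // per-control second-derivative weights, cached for the gradient pass
    double w2cache[64][6];
    int idxcache[64];
    int m = 0;
    for (int c = 0; c < 4; ++c) {
      for (int bb = 0; bb < 4; ++bb) {
        int off = (b[1] + bb) * K1 + (b[2] + c) * K1 * K2 + b[0];
        for (int a = 0; a < 4; ++a) {
          int idx = off + a;
          double f[3][3]; // f[axis][order]: order 0=w,1=dw,2=ddw
          f[0][0] = w[0][a];  f[0][1] = dw[0][a];  f[0][2] = ddw[0][a];
          f[1][0] = w[1][bb]; f[1][1] = dw[1][bb]; f[1][2] = ddw[1][bb];
          f[2][0] = w[2][c];  f[2][1] = dw[2][c];  f[2][2] = ddw[2][c];
          for (int q = 0; q < 6; ++q) {
            int j = JJ[q], k = KK[q];
            double ww = 1.0;
            for (int ax = 0; ax < 3; ++ax) {
              int ord = (ax == j) + (ax == k);
              ww *= f[ax][ord];
            }
            ww /= spacing[j] * spacing[k];
            w2cache[m][q] = ww;
            for (int d = 0; d < 3; ++d) H[d][q] += ww * coef(idx, d);
          }
          idxcache[m] = idx;
          ++m;
        }
      }
    }
    double e = 0.0;
    for (int d = 0; d < 3; ++d)
      for (int q = 0; q < 6; ++q)
        e += MULT[q] * H[d][q] * H[d][q];
    energy += e;
    if (want_grad) {
      for (int mm = 0; mm < 64; ++mm) {
        int idx = idxcache[mm];
        for (int d = 0; d < 3; ++d) {
          double g = 0.0;
          for (int q = 0; q < 6; ++q)
            g += 2.0 * MULT[q] * H[d][q] * w2cache[mm][q];
          grad(idx, d) += g;
        }
      }
    }
  }
  energy /= n;
  if (want_grad) {
    for (int i = 0; i < grad.nrow(); ++i)
      for (int d = 0; d < 3; ++d)
        grad(i, d) /= n;
  }
  return List::create(_["energy"] = energy, _["grad"] = grad);
}

// Trilinear interpolation of a 3D volume at world points, with optional
// spatial gradient (piecewise-constant per cell per axis).  Out-of-bounds
// points get `fill` and zero gradient.
// [[Rcpp::export]]
List cpp_trilerp(NumericVector vol, IntegerVector dim, NumericVector spacing,
                 NumericVector origin, NumericMatrix pts, double fill,
                 bool want_grad) {
  int n = pts.nrow();
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector val(n);
  NumericMatrix grad(want_grad ? n : 1, 3);
  for (int p = 0; p < n; ++p) {
    double u[3];
    bool inside = true;
    for (int a = 0; a < 3; ++a) {
      u[a] = (pts(p, a) - origin[a]) / spacing[a];
      if (u[a] < 0.0 || u[a] > dim[a] - 1.0) { inside = false; break; }
    }
    if (!inside) { val[p] = fill; continue; }
    int i[3]; double t[3];
    for (int a = 0; a < 3; ++a) {
      i[a] = (int)std::floor(u[a]);
      if (i[a] > dim[a] - 2) i[a] = dim[a] - 2; // u == n-1 edge case
      if (i[a] < 0) i[a] = 0;
      t[a] = u[a] - i[a];
    }
    double c[2][2][2];
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int cc = 0; cc < 2; ++cc)
          c[a][b][cc] = vol[(i[0] + a) + n1 * ((i[1] + b) + n2 * (i[2] + cc))];
    double c00 = c[0][0][0] * (1 - t[0]) + c[1][0][0] * t[0];
    double c10 = c[0][1][0] * (1 - t[0]) + c[1][1][0] * t[0];
    double c01 = c[0][0][1] * (1 - t[0]) + c[1][0][1] * t[0];
    double c11 = c[0][1][1] * (1 - t[0]) + c[1][1][1] * t[0];
    double c0 = c00 * (1 - t[1]) + c10 * t[1];
    double c1 = c01 * (1 - t[1]) + c11 * t[1];
    val[p] = c0 * (1 - t[2]) + c1 * t[2];
    if (want_grad) {
      double dx00 = c[1][0][0] - c[0][0][0], dx10 = c[1][1][0] - c[0][1][0];
      double dx01 = c[1][0][1] - c[0][0][1], dx11 = c[1][1][1] - c[0][1][1];
      double gx = ((dx00 * (1 - t[1]) + dx10 * t[1]) * (1 - t[2]) +
                   (dx01 * (1 - t[1]) + dx11 * t[1]) * t[2]) / spacing[0];
      double gy = ((c10 - c00) * (1 - t[2]) + (c11 - c01) * t[2]) / spacing[1];
      double gz = (c1 - c0) / spacing[2];
      grad(p, 0) = gx; grad(p, 1) = gy; grad(p, 2) = gz;
    }
  }
  return List::create(_["value"] = val, _["grad"] = grad);
}

// Exact minimum distance from a point to a triangle (Eberly's region-based
// closed form on the parameterization P = A + s E0 + u E1, s,u>=0, s+u<=1).
static double point_tri_dist2(const double *p, const double *a,
                              const double *b, const double *c) {
  double E0[3], E1[3], D[3];
  for (int k = 0; k < 3; ++k) {
    E0[k] = b[k] - a[k];
    E1[k] = c[k] - a[k];
    D[k] = a[k] - p[k];
  }
  double a00 = E0[0]*E0[0] + E0[1]*E0[1] + E0[2]*E0[2];
  double a01 = E0[0]*E1[0] + E0[1]*E1[1] + E0[2]*E1[2];
  double a11 = E1[0]*E1[0] + E1[1]*E1[1] + E1[2]*E1[2];
  double b0 = E0[0]*D[0] + E0[1]*D[1] + E0[2]*D[2];
  double b1 = E1[0]*D[0] + E1[1]*D[1] + E1[2]*D[2];
  double cc = D[0]*D[0] + D[1]*D[1] + D[2]*D[2];
  double det = std::fabs(a00 * a11 - a01 * a01);
  double s = a01 * b1 - a11 * b0;
  double u = a01 * b0 - a00 * b1;
  if (s + u <= det) {
    if (s < 0) {
      if (u < 0) { // region 4
        if (b0 < 0) { u = 0; s = (-b0 >= a00 ? 1 : -b0 / a00); }
        else { s = 0; u = (b1 >= 0 ? 0 : (-b1 >= a11 ? 1 : -b1 / a11)); }
      } else { // region 3
        s = 0; u = (b1 >= 0 ? 0 : (-b1 >= a11 ? 1 : -b1 / a11));
      }
    } else if (u < 0) { // region 5
      u = 0; s = (b0 >= 0 ? 0 : (-b0 >= a00 ? 1 : -b0 / a00));
    } else { // region 0
      double inv = 1.0 / det;
      s *= inv; u *= inv;
    }
  } else {
    if (s < 0) { // region 2
      double tmp0 = a01 + b0, tmp1 = a11 + b1;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a00 - 2 * a01 + a11;
        s = (numer >= denom ? 1 : numer / denom); u = 1 - s;
      } else {
        s = 0; u = (tmp1 <= 0 ? 1 : (b1 >= 0 ? 0 : -b1 / a11));
      }
    } else if (u < 0) { // region 6
      double tmp0 = a01 + b1, tmp1 = a00 + b0;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a00 - 2 * a01 + a11;
        u = (numer >= denom ? 1 : numer / denom); s = 1 - u;
      } else {
        u = 0; s = (tmp1 <= 0 ? 1 : (b0 >= 0 ? 0 : -b0 / a00));
      }
    } else { // region 1
      double numer = a11 + b1 - a01 - b0;
      if (numer <= 0) { s = 0; }
      else {
        double denom = a00 - 2 * a01 + a11;
        s = (numer >= denom ? 1 : numer / denom);
      }
      u = 1 - s;
    }
  }
  // distance via the closest point itself: the expanded quadratic form
  // cancels catastrophically for points on or near the triangle
  (void)cc;
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double diff = a[k] + s * E0[k] + u * E1[k] - p[k];
    d2 += diff * diff;
  }
  return d2;
}

// [[Rcpp::export]]
NumericVector cpp_point_surface_dist(NumericMatrix pts, NumericMatrix va,
                                     NumericMatrix vb, NumericMatrix vc) {
  int n = pts.nrow(), m = va.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double pt[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    double best = R_PosInf;
    for (int f = 0; f < m; ++f) {
      double A[3] = {va(f, 0), va(f, 1), va(f, 2)};
      double B[3] = {vb(f, 0), vb(f, 1), vb(f, 2)};
      double C[3] = {vc(f, 0), vc(f, 1), vc(f, 2)};
      double d2 = point_tri_dist2(pt, A, B, C);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
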
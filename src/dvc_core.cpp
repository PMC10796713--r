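// Numerical core: tricubic grey-level interpolation, subset matching
// (integer ZNCC search + Gauss-Newton ZNSSD refinement), separable
// Gaussian smoothing, exact Euclidean distance transform, and the masked
// NCC metric used by rigid registration.
//
// All voxel coordinates at this level are 0-based, column-major
// (index = i + nx*(j + ny*k)), matching R arrays with the first axis
// fastest.

#include <Rcpp.h>
#include <climits>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------
// Piecewise cubic Lagrange interpolation (4-point stencil per axis).
// Interpolating (exact at nodes) and reproduces polynomials up to
// degree 3 exactly; support requires the point to lie in [1, n-2].

static inline void lagrange_weights(double t, double *w) {
  // stencil offsets -1, 0, 1, 2 relative to the cell base
  w[0] = -t * (t - 1.0) * (t - 2.0) / 6.0;
  w[1] = (t + 1.0) * (t - 1.0) * (t - 2.0) / 2.0;
  w[2] = -(t + 1.0) * t * (t - 2.0) / 2.0;
  w[3] = (t + 1.0) * t * (t - 1.0) / 6.0;
}

static inline void lagrange_dweights(double t, double *dw) {
  dw[0] = -(3.0 * t * t - 6.0 * t + 2.0) / 6.0;
  dw[1] = (3.0 * t * t - 4.0 * t - 1.0) / 2.0;
  dw[2] = -(3.0 * t * t - 2.0 * t - 2.0) / 2.0;
  dw[3] = (3.0 * t * t - 1.0) / 6.0;
}

struct Grid {
  const double *v;
  int nx, ny, nz;
  inline double at(int i, int j, int k) const {
    return v[i + (size_t)nx * (j + (size_t)ny * k)];
  }
};

// A point is tricubic-supportable when every coordinate lies in [1, n-2].
static inline bool in_support(const Grid &g, double x, double y, double z) {
  return x >= 1.0 && x <= g.nx - 2.0 && y >= 1.0 && y <= g.ny - 2.0 &&
         z >= 1.0 && z <= g.nz - 2.0;
}

static inline void cell_base(double p, int n, int &b, double &t) {
  b = (int)std::floor(p);
  if (b > n - 3) b = n - 3;  // p == n-2 lands on t = 1 of the last cell
  if (b < 1) b = 1;          // p == 1 boundary safety
  t = p - b;
}

// value only
static double tricubic_val(const Grid &g, double x, double y, double z) {
  int bx, by, bz;
  double tx, ty, tz;
  cell_base(x, g.nx, bx, tx);
  cell_base(y, g.ny, by, ty);
  cell_base(z, g.nz, bz, tz);
  double wx[4], wy[4], wz[4];
  lagrange_weights(tx, wx);
  lagrange_weights(ty, wy);
  lagrange_weights(tz, wz);
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) {
    double accy = 0.0;
    for (int b = 0; b < 4; ++b) {
      double accx = 0.0;
      const double *row =
          g.v + (bx - 1) + (size_t)g.nx * ((by - 1 + b) + (size_t)g.ny * (bz - 1 + c));
      accx = wx[0] * row[0] + wx[1] * row[1] + wx[2] * row[2] + wx[3] * row[3];
      accy += wy[b] * accx;
    }
    acc += wz[c] * accy;
  }
  return acc;
}

// value + gradient (in voxel units)
static double tricubic_valgrad(const Grid &g, double x, double y, double z,
                               double *grad) {
  int bx, by, bz;
  double tx, ty, tz;
  cell_base(x, g.nx, bx, tx);
  cell_base(y, g.ny, by, ty);
  cell_base(z, g.nz, bz, tz);
  double wx[4], wy[4], wz[4], dx[4], dy[4], dz[4];
  lagrange_weights(tx, wx);
  lagrange_weights(ty, wy);
  lagrange_weights(tz, wz);
  lagrange_dweights(tx, dx);
  lagrange_dweights(ty, dy);
  lagrange_dweights(tz, dz);
  double val = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
  for (int c = 0; c < 4; ++c) {
    for (int b = 0; b < 4; ++b) {
      const double *row =
          g.v + (bx - 1) + (size_t)g.nx * ((by - 1 + b) + (size_t)g.ny * (bz - 1 + c));
      double sv = wx[0] * row[0] + wx[1] * row[1] + wx[2] * row[2] + wx[3] * row[3];
      double sd = dx[0] * row[0] + dx[1] * row[1] + dx[2] * row[2] + dx[3] * row[3];
      val += wz[c] * wy[b] * sv;
      gx += wz[c] * wy[b] * sd;
      gy += wz[c] * dy[b] * sv;
      gz += dz[c] * wy[b] * sv;
    }
  }
  grad[0] = gx;
  grad[1] = gy;
  grad[2] = gz;
  return val;
}

static Grid as_grid(const NumericVector &vol, const IntegerVector &dim) {
  Grid g;
  g.v = REAL(vol);
  g.nx = dim[0];
  g.ny = dim[1];
  g.nz = dim[2];
  return g;
}

// [[Rcpp::export(name = ".cpp_tricubic")]]
NumericVector cpp_tricubic(NumericVector vol, IntegerVector dim,
                           NumericMatrix pts) {
  Grid g = as_grid(vol, dim);
  int n = pts.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double x = pts(q, 0), y = pts(q, 1), z = pts(q, 2);
    if (!in_support(g, x, y, z))
      stop("point %d at (%g, %g, %g) is outside the tricubic support region",
           q + 1, x, y, z);
    out[q] = tricubic_val(g, x, y, z);
  }
  return out;
}

// Sampling with a fill value instead of an error; returns values and an
// in-domain flag per point (used by volume warping / resampling).
// [[Rcpp::export(name = ".cpp_tricubic_fill")]]
List cpp_tricubic_fill(NumericVector vol, IntegerVector dim, NumericMatrix pts,
                       double fill) {
  Grid g = as_grid(vol, dim);
  int n = pts.nrow();
  NumericVector out(n);
  LogicalVector ok(n);
  for (int q = 0; q < n; ++q) {
    double x = pts(q, 0), y = pts(q, 1), z = pts(q, 2);
    if (in_support(g, x, y, z)) {
      out[q] = tricubic_val(g, x, y, z);
      ok[q] = true;
    } else {
      out[q] = fill;
      ok[q] = false;
    }
  }
  return List::create(_["values"] = out, _["in_domain"] = ok);
}

// ---------------------------------------------------------------------
// Separable Gaussian smoothing with symmetric (mirror) boundaries.

static void smooth_axis(std::vector<double> &src, std::vector<double> &dst,
                        int nx, int ny, int nz, int axis,
                        const std::vector<double> &ker) {
  int r = ((int)ker.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx3[3] = {i, j, k};
        double acc = 0.0;
        for (int o = -r; o <= r; ++o) {
          int p = idx3[axis] + o;
          while (p < 0 || p >= len) {  // mirror reflection
            if (p < 0) p = -p - 1;
            if (p >= len) p = 2 * len - p - 1;
          }
          int c[3] = {i, j, k};
          c[axis] = p;
          acc += ker[o + r] * src[c[0] + (size_t)nx * (c[1] + (size_t)ny * c[2])];
        }
        dst[i + (size_t)nx * (j + (size_t)ny * k)] = acc;
      }
}

// [[Rcpp::export(name = ".cpp_gauss_smooth")]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(vol.size());
  if (sigma <= 0) {
    std::copy(vol.begin(), vol.end(), out.begin());
    out.attr("dim") = dim;
    return out;
  }
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int o = -r; o <= r; ++o) {
    ker[o + r] = std::exp(-0.5 * o * o / (sigma * sigma));
    s += ker[o + r];
  }
  for (double &w : ker) w /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  smooth_axis(a, b, nx, ny, nz, 0, ker);
  smooth_axis(b, a, nx, ny, nz, 1, ker);
  smooth_axis(a, b, nx, ny, nz, 2, ker);
  std::copy(b.begin(), b.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// squared distances in voxel units; 0 inside the mask.

static void dt1d(const std::vector<double> &f, std::vector<double> &d) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double INF = 1e20;
  std::vector<double> d(n);
  for (size_t q = 0; q < n; ++q) d[q] = mask[q] ? 0.0 : INF;
  std::vector<double> line, out;
  // x pass
  line.resize(nx);
  out.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) line[i] = d[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(line, out);
      for (int i = 0; i < nx; ++i) d[i + (size_t)nx * (j + (size_t)ny * k)] = out[i];
    }
  // y pass
  line.resize(ny);
  out.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) line[j] = d[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(line, out);
      for (int j = 0; j < ny; ++j) d[i + (size_t)nx * (j + (size_t)ny * k)] = out[j];
    }
  // z pass
  line.resize(nz);
  out.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) line[k] = d[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(line, out);
      for (int k = 0; k < nz; ++k) d[i + (size_t)nx * (j + (size_t)ny * k)] = out[k];
    }
  NumericVector res(n);
  std::copy(d.begin(), d.end(), res.begin());
  res.attr("dim") = dim;
  return res;
}

// ---------------------------------------------------------------------
// Subset matching.

struct IntSearchResult {
  int off[3];
  double corr;
  int status;  // 0 ok, 1 textureless reference, 2 window out of bounds
};

// Exhaustive ZNCC argmax over all integer offsets with |o|_2 <= radius.
// Ties broken by smaller Euclidean norm, then lexicographic order.
static IntSearchResult integer_search(const Grid &ref, const Grid &def,
                                      const int *node, int h, int radius) {
  IntSearchResult res;
  res.off[0] = res.off[1] = res.off[2] = 0;
  res.corr = NA_REAL;
  res.status = 0;
  int e = 2 * h + 1;
  size_t nsub = (size_t)e * e * e;
  // bounds: reference subset and full search window inside both volumes
  for (int a = 0; a < 3; ++a) {
    int n = (a == 0) ? ref.nx : (a == 1) ? ref.ny : ref.nz;
    int m = (a == 0) ? def.nx : (a == 1) ? def.ny : def.nz;
    if (node[a] - h < 0 || node[a] + h >= n || node[a] - h - radius < 0 ||
        node[a] + h + radius >= m) {
      res.status = 2;
      return res;
    }
  }
  // contiguous copies: F = reference subset (e^3), G = deformed search
  // region ((e + 2 radius)^3); summed-area tables over G and G^2 give the
  // per-offset sums, and the cross term is accumulated row-wise so the
  // innermost loop runs over contiguous offsets.
  std::vector<double> f(nsub);
  double A = 0.0, B = 0.0;
  {
    size_t q = 0;
    for (int c = -h; c <= h; ++c)
      for (int b = -h; b <= h; ++b)
        for (int a = -h; a <= h; ++a, ++q) {
          double v = ref.at(node[0] + a, node[1] + b, node[2] + c);
          f[q] = v;
          A += v;
          B += v * v;
        }
  }
  double fvar = nsub * B - A * A;
  if (fvar <= 0.0) {
    res.status = 1;
    return res;
  }
  int w = e + 2 * radius;         // search region edge
  int s = 2 * radius + 1;         // offsets per axis
  std::vector<double> G((size_t)w * w * w);
  {
    size_t q = 0;
    for (int c = 0; c < w; ++c)
      for (int b = 0; b < w; ++b) {
        const double *row = def.v + (node[0] - h - radius) +
                            (size_t)def.nx *
                                ((node[1] - h - radius + b) +
                                 (size_t)def.ny * (node[2] - h - radius + c));
        for (int a = 0; a < w; ++a, ++q) G[q] = row[a];
      }
  }
  int W = w + 1;
  std::vector<double> S1((size_t)W * W * W, 0.0), S2((size_t)W * W * W, 0.0);
  for (int c = 0; c < w; ++c)
    for (int b = 0; b < w; ++b)
      for (int a = 0; a < w; ++a) {
        size_t i0 = (size_t)(a + 1) + (size_t)W * ((b + 1) + (size_t)W * (c + 1));
        double gv = G[a + (size_t)w * (b + (size_t)w * c)];
        S1[i0] = gv + S1[i0 - 1] + S1[i0 - W] + S1[i0 - (size_t)W * W] -
                 S1[i0 - 1 - W] - S1[i0 - 1 - (size_t)W * W] -
                 S1[i0 - W - (size_t)W * W] + S1[i0 - 1 - W - (size_t)W * W];
        S2[i0] = gv * gv + S2[i0 - 1] + S2[i0 - W] + S2[i0 - (size_t)W * W] -
                 S2[i0 - 1 - W] - S2[i0 - 1 - (size_t)W * W] -
                 S2[i0 - W - (size_t)W * W] + S2[i0 - 1 - W - (size_t)W * W];
      }
  auto boxSum = [&](const std::vector<double> &S, int x, int y, int z) {
    // sum over [x, x+e) x [y, y+e) x [z, z+e)
    size_t x0 = x, x1 = x + e, y0 = y, y1 = y + e, z0 = z, z1 = z + e;
    auto at = [&](size_t i, size_t j, size_t k) {
      return S[i + (size_t)W * (j + (size_t)W * k)];
    };
    return at(x1, y1, z1) - at(x0, y1, z1) - at(x1, y0, z1) - at(x1, y1, z0) +
           at(x0, y0, z1) + at(x0, y1, z0) + at(x1, y0, z0) - at(x0, y0, z0);
  };
  double bestc = -2.0;
  int besto[3] = {0, 0, 0};
  int bestn2 = INT_MAX;
  int r2 = radius * radius;
  std::vector<double> Evec(s);
  for (int ok_ = -radius; ok_ <= radius; ++ok_)
    for (int oj = -radius; oj <= radius; ++oj) {
      if (ok_ * ok_ + oj * oj > r2) continue;
      std::fill(Evec.begin(), Evec.end(), 0.0);
      for (int c = 0; c < e; ++c)
        for (int b = 0; b < e; ++b) {
          const double *gr =
              &G[(size_t)(oj + radius + b) * w +
                 (size_t)w * w * (ok_ + radius + c)];
          const double *fr = &f[(size_t)c * e * e + (size_t)b * e];
          for (int a = 0; a < e; ++a) {
            double fa = fr[a];
            const double *g2 = gr + a;
            for (int oi = 0; oi < s; ++oi) Evec[oi] += fa * g2[oi];
          }
        }
      for (int oi = -radius; oi <= radius; ++oi) {
        int n2 = oi * oi + oj * oj + ok_ * ok_;
        if (n2 > r2) continue;
        double C = boxSum(S1, oi + radius, oj + radius, ok_ + radius);
        double D = boxSum(S2, oi + radius, oj + radius, ok_ + radius);
        double E = Evec[oi + radius];
        double gvar = nsub * D - C * C;
        if (gvar <= 0.0) continue;
        double corr = (nsub * E - A * C) / std::sqrt(fvar * gvar);
        bool take = false;
        if (corr > bestc) {
          take = true;
        } else if (corr == bestc) {
          if (n2 < bestn2) {
            take = true;
          } else if (n2 == bestn2) {
            if (oi < besto[0] ||
                (oi == besto[0] &&
                 (oj < besto[1] || (oj == besto[1] && ok_ < besto[2]))))
              take = true;
          }
        }
        if (take) {
          bestc = corr;
          besto[0] = oi;
          besto[1] = oj;
          besto[2] = ok_;
          bestn2 = n2;
        }
      }
    }
  res.off[0] = besto[0];
  res.off[1] = besto[1];
  res.off[2] = besto[2];
  res.corr = bestc;
  return res;
}

// [[Rcpp::export(name = ".cpp_integer_search")]]
List cpp_integer_search(NumericVector ref, NumericVector def, IntegerVector dim,
                        IntegerVector node, int h, int radius) {
  Grid rg = as_grid(ref, dim), dg = as_grid(def, dim);
  int nd[3] = {node[0], node[1], node[2]};
  IntSearchResult r = integer_search(rg, dg, nd, h, radius);
  return List::create(_["offset"] = IntegerVector::create(r.off[0], r.off[1], r.off[2]),
                      _["correlation"] = r.corr, _["status"] = r.status);
}

struct RefineResult {
  double u[3];
  double corr;
  int iters;
  bool converged;
  int status;  // 0 ok, 1 textureless, 2 left interpolation support, 3 diverged
};

static void gauss_solve(int n, double *Hm, double *bv) {
  // in-place Gaussian elimination with partial pivoting; H is n x n row-major
  for (int c = 0; c < n; ++c) {
    int piv = c;
    for (int r2 = c + 1; r2 < n; ++r2)
      if (std::fabs(Hm[r2 * n + c]) > std::fabs(Hm[piv * n + c])) piv = r2;
    if (piv != c) {
      for (int q = 0; q < n; ++q) std::swap(Hm[c * n + q], Hm[piv * n + q]);
      std::swap(bv[c], bv[piv]);
    }
    double d = Hm[c * n + c];
    if (std::fabs(d) < 1e-300) d = (d < 0 ? -1e-300 : 1e-300);
    for (int r2 = c + 1; r2 < n; ++r2) {
      double m = Hm[r2 * n + c] / d;
      if (m == 0.0) continue;
      for (int q = c; q < n; ++q) Hm[r2 * n + q] -= m * Hm[c * n + q];
      bv[r2] -= m * bv[c];
    }
  }
  for (int c = n - 1; c >= 0; --c) {
    double s = bv[c];
    for (int q = c + 1; q < n; ++q) s -= Hm[c * n + q] * bv[q];
    double d = Hm[c * n + c];
    if (std::fabs(d) < 1e-300) d = (d < 0 ? -1e-300 : 1e-300);
    bv[c] = s / d;
  }
}

// Gauss-Newton minimisation of the ZNSSD between the (zero-mean,
// unit-normalised) reference subset and the tricubic-sampled deformed
// subset. shape_order 0 optimises a pure subset translation (3 dof);
// shape_order 1 adds a 3x3 displacement-gradient (12 dof). The reported
// translation is the displacement of the subset centre.
static RefineResult refine_subset(const Grid &ref, const Grid &def,
                                  const int *node, const double *init, int h,
                                  double tol, int max_iter, int shape_order) {
  RefineResult res;
  res.u[0] = init[0];
  res.u[1] = init[1];
  res.u[2] = init[2];
  res.corr = NA_REAL;
  res.iters = 0;
  res.converged = false;
  res.status = 0;
  int e = 2 * h + 1;
  size_t nsub = (size_t)e * e * e;
  int npar = (shape_order == 0) ? 3 : 12;

  // frozen normalised reference subset
  std::vector<double> ftil(nsub);
  {
    double A = 0.0;
    size_t q = 0;
    for (int c = -h; c <= h; ++c)
      for (int b = -h; b <= h; ++b)
        for (int a = -h; a <= h; ++a, ++q) {
          ftil[q] = ref.at(node[0] + a, node[1] + b, node[2] + c);
          A += ftil[q];
        }
    double fbar = A / nsub, ss = 0.0;
    for (size_t p = 0; p < nsub; ++p) {
      ftil[p] -= fbar;
      ss += ftil[p] * ftil[p];
    }
    if (ss <= 0.0) {
      res.status = 1;
      return res;
    }
    double inv = 1.0 / std::sqrt(ss);
    for (size_t p = 0; p < nsub; ++p) ftil[p] *= inv;
  }

  std::vector<double> par(12, 0.0);  // u (3) then row-major gradient (9)
  par[0] = init[0];
  par[1] = init[1];
  par[2] = init[2];

  std::vector<double> gval(nsub), grad(3 * nsub), J(nsub * npar);
  double best_cost = std::numeric_limits<double>::infinity();
  std::vector<double> best_par(par);
  double prev_step = std::numeric_limits<double>::infinity();
  int grow_count = 0;

  for (int it = 0; it < max_iter; ++it) {
    res.iters = it + 1;
    // sample deformed subset at warped positions
    bool out = false;
    size_t q = 0;
    for (int c = -h; c <= h && !out; ++c)
      for (int b = -h; b <= h && !out; ++b)
        for (int a = -h; a <= h; ++a, ++q) {
          double dx = a, dy = b, dz = c;
          double wx = par[0], wy = par[1], wz = par[2];
          if (shape_order == 1) {
            wx += par[3] * dx + par[4] * dy + par[5] * dz;
            wy += par[6] * dx + par[7] * dy + par[8] * dz;
            wz += par[9] * dx + par[10] * dy + par[11] * dz;
          }
          double x = node[0] + dx + wx, y = node[1] + dy + wy, z = node[2] + dz + wz;
          if (!in_support(def, x, y, z)) {
            out = true;
            break;
          }
          gval[q] = tricubic_valgrad(def, x, y, z, &grad[3 * q]);
        }
    if (out) {
      res.status = 2;
      break;
    }
    double C = 0.0;
    for (size_t p = 0; p < nsub; ++p) C += gval[p];
    double gbar = C / nsub, ss = 0.0;
    for (size_t p = 0; p < nsub; ++p) {
      double d = gval[p] - gbar;
      ss += d * d;
    }
    if (ss <= 0.0) {
      res.status = 1;
      break;
    }
    double sg = std::sqrt(ss);

    // residual r = ftil - (g - gbar)/sg ; Jacobian of the model term
    // (mean-of-gradient projected out, sg frozen within the step)
    double mg[3] = {0.0, 0.0, 0.0};
    for (size_t p = 0; p < nsub; ++p) {
      mg[0] += grad[3 * p];
      mg[1] += grad[3 * p + 1];
      mg[2] += grad[3 * p + 2];
    }
    mg[0] /= nsub;
    mg[1] /= nsub;
    mg[2] /= nsub;

    double cost = 0.0, corr = 0.0;
    std::vector<double> r(nsub);
    {
      size_t p = 0;
      for (int c = -h; c <= h; ++c)
        for (int b = -h; b <= h; ++b)
          for (int a = -h; a <= h; ++a, ++p) {
            double gn = (gval[p] - gbar) / sg;
            r[p] = ftil[p] - gn;
            cost += r[p] * r[p];
            corr += ftil[p] * gn;
            double jx = (grad[3 * p] - mg[0]) / sg;
            double jy = (grad[3 * p + 1] - mg[1]) / sg;
            double jz = (grad[3 * p + 2] - mg[2]) / sg;
            double *row = &J[p * npar];
            row[0] = jx;
            row[1] = jy;
            row[2] = jz;
            if (shape_order == 1) {
              row[3] = jx * a;
              row[4] = jx * b;
              row[5] = jx * c;
              row[6] = jy * a;
              row[7] = jy * b;
              row[8] = jy * c;
              row[9] = jz * a;
              row[10] = jz * b;
              row[11] = jz * c;
            }
          }
    }
    if (cost < best_cost) {
      best_cost = cost;
      best_par = par;
    }

    // normal equations
    std::vector<double> Hm(npar * npar, 0.0), bv(npar, 0.0);
    for (size_t p = 0; p < nsub; ++p) {
      const double *row = &J[p * npar];
      for (int a = 0; a < npar; ++a) {
        bv[a] += row[a] * r[p];
        for (int b = a; b < npar; ++b) Hm[a * npar + b] += row[a] * row[b];
      }
    }
    for (int a = 0; a < npar; ++a)
      for (int b = 0; b < a; ++b) Hm[a * npar + b] = Hm[b * npar + a];
    gauss_solve(npar, Hm.data(), bv.data());

    double step = 0.0;
    for (int a = 0; a < npar; ++a) {
      par[a] += bv[a];
      step += bv[a] * bv[a];
    }
    step = std::sqrt(step);
    if (!std::isfinite(step)) {
      res.status = 3;
      break;
    }
    if (step < tol) {
      res.converged = true;
      best_par = par;  // accept the converged iterate
      // final correlation is recomputed below
      break;
    }
    if (step > prev_step) {
      if (++grow_count >= 3) {
        res.status = 3;
        break;
      }
    } else {
      grow_count = 0;
    }
    prev_step = step;
  }

  par = best_par;
  res.u[0] = par[0];
  res.u[1] = par[1];
  res.u[2] = par[2];

  // final ZNCC at the reported iterate
  {
    bool out = false;
    size_t q = 0;
    double C = 0.0;
    for (int c = -h; c <= h && !out; ++c)
      for (int b = -h; b <= h && !out; ++b)
        for (int a = -h; a <= h; ++a, ++q) {
          double dx = a, dy = b, dz = c;
          double wx = par[0], wy = par[1], wz = par[2];
          if (shape_order == 1) {
            wx += par[3] * dx + par[4] * dy + par[5] * dz;
            wy += par[6] * dx + par[7] * dy + par[8] * dz;
            wz += par[9] * dx + par[10] * dy + par[11] * dz;
          }
          double x = node[0] + dx + wx, y = node[1] + dy + wy, z = node[2] + dz + wz;
          if (!in_support(def, x, y, z)) {
            out = true;
            break;
          }
          gval[q] = tricubic_val(def, x, y, z);
          C += gval[q];
        }
    if (!out) {
      double gbar = C / nsub, ss = 0.0;
      for (size_t p = 0; p < nsub; ++p) {
        double d = gval[p] - gbar;
        ss += d * d;
      }
      if (ss > 0.0) {
        double corr = 0.0, sg = std::sqrt(ss);
        for (size_t p = 0; p < nsub; ++p) corr += ftil[p] * (gval[p] - gbar) / sg;
        res.corr = corr;
      }
    } else if (res.status == 0) {
      res.status = 2;
    }
  }
  if (res.status != 0) res.converged = false;
  return res;
}

// [[Rcpp::export(name = ".cpp_refine")]]
List cpp_refine(NumericVector ref, NumericVector def, IntegerVector dim,
                IntegerVector node, NumericVector init, int h, double tol,
                int max_iter, int shape_order) {
  Grid rg = as_grid(ref, dim), dg = as_grid(def, dim);
  int nd[3] = {node[0], node[1], node[2]};
  double u0[3] = {init[0], init[1], init[2]};
  RefineResult r = refine_subset(rg, dg, nd, u0, h, tol, max_iter, shape_order);
  return List::create(_["u"] = NumericVector::create(r.u[0], r.u[1], r.u[2]),
                      _["correlation"] = r.corr, _["iterations"] = r.iters,
                      _["converged"] = r.converged, _["status"] = r.status);
}

// Batch per-node correlation: integer search then subvoxel refinement.
// Returns one row per node:
//   uint_x uint_y uint_z ux uy uz corr iters converged status
// [[Rcpp::export(name = ".cpp_dvc_nodes")]]
NumericMatrix cpp_dvc_nodes(NumericVector ref, NumericVector def,
                            IntegerVector dim, IntegerMatrix nodes, int h,
                            int radius, double tol, int max_iter,
                            int shape_order) {
  Grid rg = as_grid(ref, dim), dg = as_grid(def, dim);
  int n = nodes.nrow();
  NumericMatrix out(n, 10);
  for (int q = 0; q < n; ++q) {
    int nd[3] = {nodes(q, 0), nodes(q, 1), nodes(q, 2)};
    IntSearchResult is = integer_search(rg, dg, nd, h, radius);
    out(q, 0) = is.off[0];
    out(q, 1) = is.off[1];
    out(q, 2) = is.off[2];
    if (is.status != 0) {
      out(q, 3) = NA_REAL;
      out(q, 4) = NA_REAL;
      out(q, 5) = NA_REAL;
      out(q, 6) = NA_REAL;
      out(q, 7) = 0;
      out(q, 8) = 0;
      out(q, 9) = is.status == 1 ? 1 : 3;
      continue;
    }
    double u0[3] = {(double)is.off[0], (double)is.off[1], (double)is.off[2]};
    RefineResult r = refine_subset(rg, dg, nd, u0, h, tol, max_iter, shape_order);
    out(q, 3) = r.u[0];
    out(q, 4) = r.u[1];
    out(q, 5) = r.u[2];
    out(q, 6) = r.corr;
    out(q, 7) = r.iters;
    out(q, 8) = r.converged ? 1 : 0;
    out(q, 9) = r.status;
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------
// Masked NCC between fixed reference samples and the moving volume
// sampled at transformed points (registration metric). Out-of-support
// points are dropped from the sums.
// [[Rcpp::export(name = ".cpp_masked_ncc")]]
List cpp_masked_ncc(NumericVector refVals, NumericVector mov, IntegerVector dim,
                    NumericMatrix pts) {
  Grid g = as_grid(mov, dim);
  int n = pts.nrow();
  double A = 0, B = 0, C = 0, D = 0, E = 0;
  int m = 0;
  for (int q = 0; q < n; ++q) {
    double x = pts(q, 0), y = pts(q, 1), z = pts(q, 2);
    if (!in_support(g, x, y, z)) continue;
    double gv = tricubic_val(g, x, y, z);
    double fv = refVals[q];
    A += fv;
    B += fv * fv;
    C += gv;
    D += gv * gv;
    E += fv * gv;
    ++m;
  }
  double ncc = NA_REAL;
  if (m > 1) {
    double fvar = m * B - A * A, gvar = m * D - C * C;
    if (fvar > 0 && gvar > 0) ncc = (m * E - A * C) / std::sqrt(fvar * gvar);
  }
  return List::create(_["ncc"] = ncc, _["n_used"] = m, _["n_total"] = n);
}
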
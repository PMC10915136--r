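#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 1D convolution along one axis of a 3D array, replicate padding.
// kernel length must be odd; dim is 0 (x), 1 (y) or 2 (z) in array index order.
// [[Rcpp::export(name = ".conv3d_axis")]]
NumericVector conv3d_axis(NumericVector arr, NumericVector kernel, int dim) {
  IntegerVector d = arr.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int kh = kl / 2;
  NumericVector out(arr.size());
  out.attr("dim") = d;
  const double *in = arr.begin(), *kw = kernel.begin();
  double *o = out.begin();
  const int n[3] = {nx, ny, nz};
  const long stride[3] = {1, (long)nx, (long)nx * ny};
  const int na = n[dim];
  const long sa = stride[dim];
  // iterate over all lines along axis `dim`
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int idx3[3] = {i, j, k};
        if (idx3[dim] != 0) continue; // line anchors only
        long base = (long)i + (long)j * nx + (long)k * nx * ny;
        for (int p = 0; p < na; ++p) {
          double acc = 0.0;
          for (int q = -kh; q <= kh; ++q) {
            int pp = p + q;
            if (pp < 0) pp = 0;
            if (pp >= na) pp = na - 1;
            acc += kw[q + kh] * in[base + (long)pp * sa];
          }
          o[base + (long)p * sa] = acc;
        }
      }
    }
  }
  return out;
}

// Local mean over a (2*hw+1)^2 window with replicate padding (integral image).
// [[Rcpp::export(name = ".boxmean2d")]]
NumericMatrix boxmean2d(NumericMatrix x, int hw) {
  const int nr = x.nrow(), nc = x.ncol();
  const int pr = nr + 2 * hw, pc = nc + 2 * hw;
  // padded integral image, (pr+1) x (pc+1)
  std::vector<double> ii((size_t)(pr + 1) * (pc + 1), 0.0);
  for (int j = 0; j < pc; ++j) {
    int sj = j - hw; if (sj < 0) sj = 0; if (sj >= nc) sj = nc - 1;
    for (int i = 0; i < pr; ++i) {
      int si = i - hw; if (si < 0) si = 0; if (si >= nr) si = nr - 1;
      ii[(size_t)(i + 1) + (size_t)(j + 1) * (pr + 1)] = x(si, sj)
        + ii[(size_t)i + (size_t)(j + 1) * (pr + 1)]
        + ii[(size_t)(i + 1) + (size_t)j * (pr + 1)]
        - ii[(size_t)i + (size_t)j * (pr + 1)];
    }
  }
  NumericMatrix out(nr, nc);
  const double w = (2.0 * hw + 1) * (2.0 * hw + 1);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int i0 = i, j0 = j, i1 = i + 2 * hw + 1, j1 = j + 2 * hw + 1;
      double s = ii[(size_t)i1 + (size_t)j1 * (pr + 1)]
        - ii[(size_t)i0 + (size_t)j1 * (pr + 1)]
        - ii[(size_t)i1 + (size_t)j0 * (pr + 1)]
        + ii[(size_t)i0 + (size_t)j0 * (pr + 1)];
      out(i, j) = s / w;
    }
  }
  return out;
}

static inline void interp_pt(const double *pa, const double *pb, double fa,
                             double fb, double level, double *out) {
  double t = (level - fa) / (fb - fa);
  for (int c = 0; c < 3; ++c) out[c] = pa[c] + t * (pb[c] - pa[c]);
}

static inline double tri_area(const double *a, const double *b, const double *c) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w0 = u[1] * v[2] - u[2] * v[1];
  double w1 = u[2] * v[0] - u[0] * v[2];
  double w2 = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(w0 * w0 + w1 * w1 + w2 * w2);
}

// Isosurface area of a scalar field at `level`, via marching tetrahedra on the
// Freudenthal (Kuhn) 6-tetrahedra subdivision of each grid cell. Vertex
// positions in voxel units; multiply by voxel_size^2 outside for physical area.
// [[Rcpp::export(name = ".surface_area_mt")]]
double surface_area_mt(NumericVector field, double level) {
  IntegerVector d = field.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  const int nx = d[0], ny = d[1], nz = d[2];
  const double *f = field.begin();
  // the 6 permutations of axis insertion order defining the Kuhn subdivision
  static const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  double total = 0.0;
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        for (int p = 0; p < 6; ++p) {
          // tet vertices: start corner, then add unit steps along perm axes
          int vx[4] = {i, 0, 0, 0}, vy[4] = {j, 0, 0, 0}, vz[4] = {k, 0, 0, 0};
          int cx = i, cy = j, cz = k;
          for (int s = 0; s < 3; ++s) {
            if (perms[p][s] == 0) cx++;
            else if (perms[p][s] == 1) cy++;
            else cz++;
            vx[s + 1] = cx; vy[s + 1] = cy; vz[s + 1] = cz;
          }
          double fv[4]; double pv[4][3]; int inside[4]; int nin = 0;
          for (int v = 0; v < 4; ++v) {
            fv[v] = f[(long)vx[v] + (long)vy[v] * nx + (long)vz[v] * nx * ny];
            pv[v][0] = vx[v]; pv[v][1] = vy[v]; pv[v][2] = vz[v];
            inside[v] = fv[v] > level;
            nin += inside[v];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int lone = -1;
            for (int v = 0; v < 4; ++v)
              if (inside[v] == (nin == 1 ? 1 : 0)) lone = v;
            double tri[3][3]; int t = 0;
            for (int v = 0; v < 4; ++v) {
              if (v == lone) continue;
              interp_pt(pv[lone], pv[v], fv[lone], fv[v], level, tri[t++]);
            }
            total += tri_area(tri[0], tri[1], tri[2]);
          } else { // nin == 2: quad split into two triangles
            int a = -1, b = -1, c = -1, e = -1;
            for (int v = 0; v < 4; ++v) {
              if (inside[v]) { if (a < 0) a = v; else b = v; }
              else { if (c < 0) c = v; else e = v; }
            }
            double pac[3], pae[3], pbc[3], pbe[3];
            interp_pt(pv[a], pv[c], fv[a], fv[c], level, pac);
            interp_pt(pv[a], pv[e], fv[a], fv[e], level, pae);
            interp_pt(pv[b], pv[c], fv[b], fv[c], level, pbc);
            interp_pt(pv[b], pv[e], fv[b], fv[e], level, pbe);
            // quad order: ac, ae, be, bc
            total += tri_area(pac, pae, pbe);
            total += tri_area(pac, pbe, pbc);
          }
        }
      }
    }
  }
  return total;
}

// 1D squared-distance transform (lower envelope of parabolas)
static void dt1d(const double *f, double *d, int n, int *v, double *z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean squared distance transform of a 3D binary field: distance
// from every voxel to the nearest zero voxel (Felzenszwalb-Huttenlocher).
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(NumericVector mask) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  const int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out(mask.size());
  out.attr("dim") = d;
  const double INF = 1e20;
  double *o = out.begin();
  const double *m = mask.begin();
  for (R_xlen_t i = 0; i < mask.size(); ++i) o[i] = m[i] != 0 ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      long base = (long)j * nx + (long)k * nx * ny;
      for (int i = 0; i < nx; ++i) f[i] = o[base + i];
      dt1d(f.data(), dd.data(), nx, v.data(), z.data());
      for (int i = 0; i < nx; ++i) o[base + i] = dd[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      long base = (long)i + (long)k * nx * ny;
      for (int j = 0; j < ny; ++j) f[j] = o[base + (long)j * nx];
      dt1d(f.data(), dd.data(), ny, v.data(), z.data());
      for (int j = 0; j < ny; ++j) o[base + (long)j * nx] = dd[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      long base = (long)i + (long)j * nx;
      for (int k = 0; k < nz; ++k) f[k] = o[base + (long)k * nx * ny];
      dt1d(f.data(), dd.data(), nz, v.data(), z.data());
      for (int k = 0; k < nz; ++k) o[base + (long)k * nx * ny] = dd[k];
    }
  return out;
}
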
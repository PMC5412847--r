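#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---- windowed min/max filter -------------------------------------------------

// Local min and max over a ball (Euclidean radius) or cube (Chebyshev radius)
// window, clipped at the volume boundary: the extrema are taken over the
// intersection of the window with the volume.
// [[Rcpp::export]]
List cpp_minmax_filter(NumericVector vol, int nx, int ny, int nz,
                       int radius, bool ball) {
  std::vector<int> ox, oy, oz;
  const double r2 = (double)radius * radius;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx) {
        if (ball && (double)(dx*dx + dy*dy + dz*dz) > r2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int no = (int)ox.size();
  NumericVector vmin(vol.size()), vmax(vol.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double lo = R_PosInf, hi = R_NegInf;
        for (int k = 0; k < no; ++k) {
          int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          double v = vol[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        vmin[i] = lo; vmax[i] = hi;
      }
  return List::create(_["min"] = vmin, _["max"] = vmax);
}

// ---- squared Euclidean distance transform (Felzenszwalb & Huttenlocher) ------

static const double DT_INF = 1e20;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0; z[0] = -DT_INF; z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared distance from each voxel to the nearest background (FALSE) voxel
// centre. Voxels outside the grid are not counted as background, so a phase
// touching the boundary behaves as if continued beyond it.
// [[Rcpp::export]]
NumericVector cpp_sq_edt(LogicalVector fg, int nx, int ny, int nz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] ? DT_INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, dd, v, z, nx);
      for (int x = 0; x < nx; ++x) d[base + x] = dd[x];
    }
  // y pass
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)nx * y];
      dt1d(f, dd, v, z, ny);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)nx * y] = dd[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int zz = 0; zz < nz; ++zz) f[zz] = d[base + stride * zz];
      dt1d(f, dd, v, z, nz);
      for (int zz = 0; zz < nz; ++zz) d[base + stride * zz] = dd[zz];
    }
  return d;
}

// ---- local thickness (maximal inscribed spheres) -----------------------------

// Hildebrand-Ruegsegger local thickness: th(q) = 2 * max{ r(p) : |q-p| <= r(p) }
// where r(p) is the distance-transform radius at foreground voxel p. Direct
// sphere painting from every foreground voxel in decreasing radius order.
// Works for 2D inputs by passing nz = 1 (spheres degenerate to discs).
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector fg, int nx, int ny, int nz) {
  NumericVector sq = cpp_sq_edt(fg, nx, ny, nz);
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n, NA_REAL);
  std::vector<R_xlen_t> idx;
  idx.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i)
    if (fg[i]) { idx.push_back(i); th[i] = 0.0; }
  std::sort(idx.begin(), idx.end(),
            [&](R_xlen_t a, R_xlen_t b) { return sq[a] > sq[b]; });
  for (R_xlen_t pi : idx) {
    double r2 = sq[pi];
    double r = std::sqrt(r2);
    double diam = 2.0 * r;
    int x0 = (int)(pi % nx);
    int y0 = (int)((pi / nx) % ny);
    int z0 = (int)(pi / ((R_xlen_t)nx * ny));
    int ri = (int)std::floor(r);
    int zlo = std::max(0, z0 - ri), zhi = std::min(nz - 1, z0 + ri);
    for (int zz = zlo; zz <= zhi; ++zz) {
      double rz2 = r2 - (double)(zz - z0) * (zz - z0);
      if (rz2 < 0) continue;
      int ry = (int)std::floor(std::sqrt(rz2));
      int ylo = std::max(0, y0 - ry), yhi = std::min(ny - 1, y0 + ry);
      for (int yy = ylo; yy <= yhi; ++yy) {
        double rx2 = rz2 - (double)(yy - y0) * (yy - y0);
        if (rx2 < 0) continue;
        int rx = (int)std::floor(std::sqrt(rx2));
        int xlo = std::max(0, x0 - rx), xhi = std::min(nx - 1, x0 + rx);
        R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        for (int xx = xlo; xx <= xhi; ++xx) {
          R_xlen_t qi = base + xx;
          if (fg[qi] && th[qi] < diam) th[qi] = diam;
        }
      }
    }
  }
  return th;
}

// ---- marching tetrahedra isosurface area -------------------------------------

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double v[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static inline void edge_point(const double p[3], const double q[3],
                              double vp, double vq, double iso, double out[3]) {
  double t = (iso - vp) / (vq - vp);
  out[0] = p[0] + t * (q[0] - p[0]);
  out[1] = p[1] + t * (q[1] - p[1]);
  out[2] = p[2] + t * (q[2] - p[2]);
}

// Total area (voxel units squared) of the iso-surface extracted by marching
// tetrahedra: each cell is split into 6 tetrahedra sharing the main diagonal,
// crossing points are linearly interpolated along edges. No padding is added,
// so phases cut by the volume boundary are left open there.
// [[Rcpp::export]]
double cpp_mt_area(NumericVector vol, int nx, int ny, int nz, double iso) {
  // cube corner offsets, index bit order (x, y, z)
  static const int CO[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };
  // 6-tet decomposition around diagonal corner0 - corner7
  static const int TET[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}
  };
  double area = 0.0;
  double cv[8];
  double cp[8][3];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int xx = x + CO[c][0], yy = y + CO[c][1], zz = z + CO[c][2];
          cv[c] = vol[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          cp[c][0] = xx; cp[c][1] = yy; cp[c][2] = zz;
          if (cv[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = { TET[t][0], TET[t][1], TET[t][2], TET[t][3] };
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (cv[vi[k]] > iso) in[nin++] = vi[k];
            else out[nout++] = vi[k];
          }
          if (nin == 0 || nin == 4) continue;
          double e1[3], e2[3], e3[3], e4[3];
          if (nin == 1 || nin == 3) {
            int a = (nin == 1) ? in[0] : out[0];
            int *rest = (nin == 1) ? out : in;
            edge_point(cp[a], cp[rest[0]], cv[a], cv[rest[0]], iso, e1);
            edge_point(cp[a], cp[rest[1]], cv[a], cv[rest[1]], iso, e2);
            edge_point(cp[a], cp[rest[2]], cv[a], cv[rest[2]], iso, e3);
            area += tri_area(e1, e2, e3);
          } else {  // nin == 2: quad split into two triangles
            edge_point(cp[in[0]], cp[out[0]], cv[in[0]], cv[out[0]], iso, e1);
            edge_point(cp[in[0]], cp[out[1]], cv[in[0]], cv[out[1]], iso, e2);
            edge_point(cp[in[1]], cp[out[0]], cv[in[1]], cv[out[0]], iso, e3);
            edge_point(cp[in[1]], cp[out[1]], cv[in[1]], cv[out[1]], iso, e4);
            area += tri_area(e1, e2, e3) + tri_area(e2, e4, e3);
          }
        }
      }
  return area;
}
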
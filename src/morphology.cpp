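// 3D binary morphology support for depth-shell construction.
//
// City-block (L1) distance transform: exact via two raster passes over the
// 6-neighbourhood; thresholding it at k reproduces k iterations of
// 6-connected binary erosion, which is how shells are peeled.
//
// Euclidean distance transform: Felzenszwalb-Huttenlocher separable
// lower-envelope algorithm, exact squared distances; used for the mean
// depth-from-inner-skull coordinate of each shell.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".cityblock_dt_cpp")]]
IntegerVector cityblock_dt_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  const int INF = INT_MAX / 4;
  std::vector<int> d(n);
  const int* m = INTEGER(mask);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = m[i] ? INF : 0;

  // out-of-grid space places no constraint: a mask clipped by the field
  // of view does not erode at the clip plane
  auto idx = [nx, ny](int x, int y, int z) {
    return (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  };

  // forward pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx(x, y, z);
        if (d[i] == 0) continue;
        int best = d[i];
        if (x > 0) best = std::min(best, d[idx(x - 1, y, z)] + 1);
        if (y > 0) best = std::min(best, d[idx(x, y - 1, z)] + 1);
        if (z > 0) best = std::min(best, d[idx(x, y, z - 1)] + 1);
        d[i] = best;
      }
  // backward pass
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        R_xlen_t i = idx(x, y, z);
        if (d[i] == 0) continue;
        int best = d[i];
        if (x < nx - 1) best = std::min(best, d[idx(x + 1, y, z)] + 1);
        if (y < ny - 1) best = std::min(best, d[idx(x, y + 1, z)] + 1);
        if (z < nz - 1) best = std::min(best, d[idx(x, y, z + 1)] + 1);
        d[i] = best;
      }

  IntegerVector out(n);
  std::copy(d.begin(), d.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Chebyshev (L-inf) distance, capped at max_iter: iterated separable
// 3-wide min filters; d[i] = iteration at which voxel i is eroded by a
// 26-connected structuring element. Exact up to the cap.
// [[Rcpp::export(name = ".chebyshev_dt_cpp")]]
IntegerVector chebyshev_dt_cpp(IntegerVector mask, IntegerVector dims,
                               int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<unsigned char> cur(n), nxt(n), tmp(n);
  const int* m = INTEGER(mask);
  std::vector<int> d(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) { cur[i] = m[i] ? 1 : 0; d[i] = 0; }
  auto idx = [nx, ny](int x, int y, int z) {
    return (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  };
  for (int it = 1; it <= max_iter; ++it) {
    bool any = false;
    // min filter along x (out-of-grid places no constraint)
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          unsigned char v = cur[idx(x, y, z)];
          if (v && x > 0) v = std::min(v, cur[idx(x - 1, y, z)]);
          if (v && x < nx - 1) v = std::min(v, cur[idx(x + 1, y, z)]);
          tmp[idx(x, y, z)] = v;
        }
    // along y
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          unsigned char v = tmp[idx(x, y, z)];
          if (v && y > 0) v = std::min(v, tmp[idx(x, y - 1, z)]);
          if (v && y < ny - 1) v = std::min(v, tmp[idx(x, y + 1, z)]);
          nxt[idx(x, y, z)] = v;
        }
    // along z
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          unsigned char v = nxt[idx(x, y, z)];
          if (v && z > 0) v = std::min(v, nxt[idx(x, y, z - 1)]);
          if (v && z < nz - 1) v = std::min(v, nxt[idx(x, y, z + 1)]);
          tmp[idx(x, y, z)] = v;
        }
    for (R_xlen_t i = 0; i < n; ++i) {
      if (cur[i] && tmp[i]) { d[i] = it + 1; any = true; }  // survives step it
      else if (cur[i] && !tmp[i] && d[i] == 0) d[i] = it;   // eroded at step it
    }
    std::swap(cur, tmp);
    if (!any) break;
  }
  // d now holds, for original foreground voxels, the erosion step at which
  // the voxel disappears (capped at max_iter + 1); background stays 0
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] ? std::min(d[i], max_iter + 1) : 0;
  out.attr("dim") = dims;
  return out;
}

static void edt_1d(std::vector<double>& f, std::vector<double>& out,
                   std::vector<int>& v, std::vector<double>& zb, int n) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    out[q] = dq * dq + f[v[k]];
  }
}

// squared Euclidean distance (in voxels) from each foreground voxel to the
// nearest background voxel (out-of-grid space places no constraint)
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  const double INF = 1e18;
  std::vector<double> d(n);
  const int* m = INTEGER(mask);
  auto idx = [nx, ny](int x, int y, int z) {
    return (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  };
  for (R_xlen_t i = 0; i < n; ++i) d[i] = m[i] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out1(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[idx(x, y, z)];
      edt_1d(f, out1, v, zb, nx);
      for (int x = 0; x < nx; ++x) d[idx(x, y, z)] = out1[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[idx(x, y, z)];
      edt_1d(f, out1, v, zb, ny);
      for (int y = 0; y < ny; ++y) d[idx(x, y, z)] = out1[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[idx(x, y, z)];
      edt_1d(f, out1, v, zb, nz);
      for (int z = 0; z < nz; ++z) d[idx(x, y, z)] = out1[z];
    }

  NumericVector out(n);
  std::copy(d.begin(), d.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}
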
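// Voxel Monte Carlo photon transport.
//
// Photons carry a survival weight that decays by Beer-Lambert absorption
// along every voxel-resolved path segment; scattering lengths are sampled
// from an exponential distribution in dimensionless optical depth so that
// crossing into a tissue with a different scattering coefficient rescales
// the remaining depth (MCML convention) rather than resampling. Fluence is
// scored with the path-length estimator: each traversed voxel accrues
// w * segment_length (weight taken at segment entry).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// xoshiro256+ seeded through splitmix64; deterministic given a 64-bit seed.

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]: never returns 0 so -log(u) is finite
  inline double u01_open0() {
    return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
  // uniform on [0, 1)
  inline double u01() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// ------------------------------------------------------------- helpers ----

static inline double hg_cos(double g, double u) {
  // Henyey-Greenstein cosine of the deflection angle; isotropic limit at g~0
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - s * s) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static inline void rotate_direction(double& dx, double& dy, double& dz,
                                    double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(dz) > 0.99999) {
    dx = sint * cosp;
    dy = sint * sinp;
    dz = cost * (dz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - dz * dz);
    double nx = sint * (dx * dz * cosp - dy * sinp) / den + dx * cost;
    double ny = sint * (dy * dz * cosp + dx * sinp) / den + dy * cost;
    double nz = -sint * cosp * den + dz * cost;
    dx = nx; dy = ny; dz = nz;
  }
  double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
  dx /= nrm; dy /= nrm; dz /= nrm;
}

static inline double fresnel_unpolarized(double n1, double n2, double ci) {
  // unpolarized reflectance for incidence cosine ci from medium n1 into n2;
  // returns 1 beyond the critical angle
  if (ci > 1.0) ci = 1.0;
  if (ci < 0.0) ci = 0.0;
  if (n1 == n2) return 0.0;
  double si2 = 1.0 - ci * ci;
  double st2 = (n1 / n2) * (n1 / n2) * si2;  // sin^2 of transmitted angle
  if (st2 >= 1.0) return 1.0;                // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export(name = ".fresnel_cpp")]]
double fresnel_cpp(double n1, double n2, double cos_incident) {
  return fresnel_unpolarized(n1, n2, cos_incident);
}

// [[Rcpp::export(name = ".sample_hg_cpp")]]
NumericVector sample_hg_cpp(int n, double g, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g, rng.u01());
  return out;
}

// [[Rcpp::export(name = ".sample_step_cpp")]]
NumericVector sample_step_cpp(int n, double mu_s, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = -std::log(rng.u01_open0()) / mu_s;
  return out;
}

// ------------------------------------------------------------ transport ----

// Labels are 0=air, 1..5 tissue; optics vectors are indexed by label (length 6).
// Grid geometry: voxel (i,j,k) (0-based) is the axis-aligned unit cube
// [i,i+1)x[j,j+1)x[k,k+1) in voxel units; mm = voxel units * h. The caller
// converts mm positions to voxel units.
//
// [[Rcpp::export(name = ".run_mc_cpp")]]
List run_mc_cpp(IntegerVector labels, IntegerVector dims, double h,
                NumericVector mu_a, NumericVector mu_s,
                NumericVector g_par, NumericVector n_par,
                NumericVector src_pos_v, NumericVector src_dir,
                NumericMatrix detectors_v, double det_radius_mm,
                double n_photons, double seed,
                double max_path_mm, double w_min, double roulette_p) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int* lab = INTEGER(labels);
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<double> flu(nvox, 0.0);

  const int ndet = detectors_v.nrow();
  std::vector< std::vector<double> > det_rows(ndet);  // w, 5 tissue paths
  const double det_r2_v = (det_radius_mm / h) * (det_radius_mm / h);

  Xoshiro rng(static_cast<uint64_t>(seed));

  double exit_total = 0.0, absorbed_total = 0.0, inflight_total = 0.0;
  double roulette_net = 0.0;
  long geometry_errors = 0;

  const double max_path_v = max_path_mm / h;  // work in voxel units

  for (double ip = 0; ip < n_photons; ip += 1.0) {
    double px = src_pos_v[0], py = src_pos_v[1], pz = src_pos_v[2];
    double dx = src_dir[0], dy = src_dir[1], dz = src_dir[2];
    int ix = (int)std::floor(px), iy = (int)std::floor(py), iz = (int)std::floor(pz);
    double w = 1.0;
    double path_v = 0.0;                       // cumulative path, voxel units
    double tp[5] = {0, 0, 0, 0, 0};            // per-tissue path, voxel units
    double tau = -std::log(rng.u01_open0());   // scattering optical depth

    bool alive = true;
    while (alive) {
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
        ++geometry_errors;  // left the grid without touching air
        absorbed_total += w;
        break;
      }
      R_xlen_t cell = (R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
      int t = lab[cell];
      if (t < 0 || t > 5) stop("label outside 0..5 encountered");
      if (t == 0) { ++geometry_errors; absorbed_total += w; break; }

      const double mus_v = mu_s[t] * h;  // per voxel unit
      const double mua_v = mu_a[t] * h;

      // distance to the next voxel face along dir (voxel units)
      double tb = 1e300; int axis = -1; int stepdir = 0;
      if (dx > 0)      { double tt = ((double)ix + 1.0 - px) / dx; if (tt < tb) { tb = tt; axis = 0; stepdir = 1; } }
      else if (dx < 0) { double tt = ((double)ix - px) / dx;       if (tt < tb) { tb = tt; axis = 0; stepdir = -1; } }
      if (dy > 0)      { double tt = ((double)iy + 1.0 - py) / dy; if (tt < tb) { tb = tt; axis = 1; stepdir = 1; } }
      else if (dy < 0) { double tt = ((double)iy - py) / dy;       if (tt < tb) { tb = tt; axis = 1; stepdir = -1; } }
      if (dz > 0)      { double tt = ((double)iz + 1.0 - pz) / dz; if (tt < tb) { tb = tt; axis = 2; stepdir = 1; } }
      else if (dz < 0) { double tt = ((double)iz - pz) / dz;       if (tt < tb) { tb = tt; axis = 2; stepdir = -1; } }
      if (tb < 0) tb = 0;

      double ts = (mus_v > 0) ? tau / mus_v : 1e300;  // to next scatter
      double tt_left = max_path_v - path_v;           // to time cutoff

      int event;  // 0 = boundary, 1 = scatter, 2 = timeout
      double ell = tb; event = 0;
      if (ts < ell) { ell = ts; event = 1; }
      if (tt_left <= ell) { ell = tt_left; event = 2; }
      if (ell < 0) ell = 0;

      // score and absorb over the segment
      flu[cell] += w * ell * h;  // fluence scored in weight * mm
      double att = std::exp(-mua_v * ell);
      absorbed_total += w * (1.0 - att);
      w *= att;
      tau -= ell * mus_v;
      path_v += ell;
      tp[t - 1] += ell;

      px += ell * dx; py += ell * dy; pz += ell * dz;

      if (event == 2) { inflight_total += w; break; }

      if (event == 0) {
        // snap onto the face and peek at the neighbour cell
        int nix = ix, niy = iy, niz = iz;
        if (axis == 0) { nix += stepdir; px = (stepdir > 0) ? (double)(ix + 1) : (double)ix; }
        if (axis == 1) { niy += stepdir; py = (stepdir > 0) ? (double)(iy + 1) : (double)iy; }
        if (axis == 2) { niz += stepdir; pz = (stepdir > 0) ? (double)(iz + 1) : (double)iz; }
        bool outside = (nix < 0 || niy < 0 || niz < 0 ||
                        nix >= nx || niy >= ny || niz >= nz);
        int nt = 0;
        if (!outside) {
          R_xlen_t nc = (R_xlen_t)nix + nx * ((R_xlen_t)niy + (R_xlen_t)ny * niz);
          nt = lab[nc];
        }
        if (outside) { ++geometry_errors; absorbed_total += w; break; }
        if (nt == 0) {
          // tissue-air boundary: Fresnel internal-reflection test
          double ci = (axis == 0) ? std::fabs(dx) : (axis == 1) ? std::fabs(dy) : std::fabs(dz);
          double R = fresnel_unpolarized(n_par[t], n_par[0], ci);
          if (R > 0 && rng.u01() < R) {
            if (axis == 0) dx = -dx;
            if (axis == 1) dy = -dy;
            if (axis == 2) dz = -dz;
            // remain in the current cell; position sits on the face
          } else {
            exit_total += w;
            for (int d = 0; d < ndet; ++d) {
              double ex = px - detectors_v(d, 0);
              double ey = py - detectors_v(d, 1);
              double ez = pz - detectors_v(d, 2);
              if (ex * ex + ey * ey + ez * ez <= det_r2_v) {
                std::vector<double>& rows = det_rows[d];
                rows.push_back(w);
                for (int q = 0; q < 5; ++q) rows.push_back(tp[q] * h);
              }
            }
            break;
          }
        } else {
          ix = nix; iy = niy; iz = niz;
        }
      } else {  // scatter
        double cost = hg_cos(g_par[t], rng.u01());
        double phi = 2.0 * M_PI * rng.u01();
        rotate_direction(dx, dy, dz, cost, phi);
        tau = -std::log(rng.u01_open0());
      }

      if (w < w_min) {  // Russian roulette: unbiased low-weight termination
        if (rng.u01() < roulette_p) {
          double gained = w / roulette_p - w;
          roulette_net -= gained;
          w /= roulette_p;
        } else {
          roulette_net += w;
          break;
        }
      }
    }
  }

  NumericVector flu_out(nvox);
  std::copy(flu.begin(), flu.end(), flu_out.begin());
  flu_out.attr("dim") = dims;

  List hist(ndet);
  for (int d = 0; d < ndet; ++d) {
    const std::vector<double>& rows = det_rows[d];
    int nrow = (int)(rows.size() / 6);
    NumericMatrix m(nrow, 6);
    for (int r = 0; r < nrow; ++r)
      for (int c = 0; c < 6; ++c) m(r, c) = rows[(size_t)r * 6 + c];
    hist[d] = m;
  }

  return List::create(
    _["fluence"] = flu_out,
    _["exit_weight"] = exit_total,
    _["absorbed_weight"] = absorbed_total,
    _["inflight_weight"] = inflight_total,
    _["roulette_net"] = roulette_net,
    _["geometry_errors"] = (double)geometry_errors,
    _["history"] = hist);
}
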
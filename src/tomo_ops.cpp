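// Parallel-beam tomography kernels: discrete voxel Radon projector, the
// closed-form sinogram of the parametric cube+spheres phantom, and the
// backprojection half of filtered backprojection.
//
// Geometry: detector coordinate t = (x - c)cos(th) + (y - c)sin(th) + c with
// c = (n-1)/2, angles counter-clockwise in degrees, 0 deg along +x (so the
// 0-deg projection integrates along y). Detector pixel pitch equals voxel
// pitch; linear interpolation/splatting between the two neighbouring bins.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// V: size^3 voxel cube (x fastest), angles in degrees.
// Returns projections (size x size x K) indexed [z, t, k].
// [[Rcpp::export]]
arma::cube cpp_forward_project(const arma::cube& V,
                               const arma::vec& angles_deg) {
  const int S = V.n_rows, K = angles_deg.n_elem;
  const double c0 = (S - 1) / 2.0;
  cube P(S, S, K, fill::zeros);
  std::vector<int> j0((size_t)S * S);
  std::vector<double> w((size_t)S * S);
  for (int k = 0; k < K; ++k) {
    const double th = angles_deg[k] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    for (int y = 0; y < S; ++y)
      for (int x = 0; x < S; ++x) {
        const double t = (x - c0) * ct + (y - c0) * st + c0;
        const int j = (int)std::floor(t);
        j0[(size_t)y * S + x] = j;
        w[(size_t)y * S + x] = t - j;
      }
    for (int z = 0; z < S; ++z) {
      double* pk = P.slice_colptr(k, 0);  // P(z, t, k): index z + t*S
      for (int y = 0; y < S; ++y) {
        const double* vz = &V(0, y, z);
        for (int x = 0; x < S; ++x) {
          const double v = vz[x];
          if (v == 0.0) continue;
          const int j = j0[(size_t)y * S + x];
          const double ww = w[(size_t)y * S + x];
          if (j >= 0 && j < S) pk[(size_t)j * S + z] += (1.0 - ww) * v;
          if (j + 1 >= 0 && j + 1 < S) pk[(size_t)(j + 1) * S + z] += ww * v;
        }
      }
    }
  }
  return P;
}

// Closed-form sinogram of one z-slice of the cube+spheres phantom.
// spheres: n x 4 matrix (cx, cy, cz, r) in voxel-centre coordinates.
// Cube occupies [lo, hi] voxel indices -> continuous extent
// [lo-0.5, hi+0.5], value cube_val; spheres overwrite to sphere_val
// (chords added as cube_val*cube + (sphere_val-cube_val)*spheres).
// Returns nt x K sinogram.
// [[Rcpp::export]]
arma::mat cpp_analytic_sino(const arma::mat& spheres, double lo, double hi,
                            double cube_val, double sphere_val, double z,
                            const arma::vec& angles_deg, int nt) {
  const int K = angles_deg.n_elem, ns = spheres.n_rows;
  const double c0 = (nt - 1) / 2.0;
  const double L = hi - lo + 1.0, cc = (lo + hi) / 2.0;
  const bool in_cube_z = (z >= lo - 0.5 && z <= hi + 0.5);
  mat sino(nt, K, fill::zeros);
  for (int k = 0; k < K; ++k) {
    const double th = angles_deg[k] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    double* col = sino.colptr(k);
    if (in_cube_z) {
      const double A = L * std::fabs(ct), B = L * std::fabs(st);
      const double d = (cc - c0) * (ct + st);  // projected square centre
      if (std::min(std::fabs(ct), std::fabs(st)) < 1e-9) {
        for (int j = 0; j < nt; ++j) {
          const double u = (j - c0) - d;
          if (std::fabs(u) <= L / 2.0) col[j] += cube_val * L;
        }
      } else {
        const double den = std::fabs(ct * st);
        for (int j = 0; j < nt; ++j) {
          const double u = std::fabs((j - c0) - d);
          double ov = std::min(std::min(A, B), (A + B) / 2.0 - u);
          if (ov > 0) col[j] += cube_val * ov / den;
        }
      }
    }
    for (int i = 0; i < ns; ++i) {
      const double dz = z - spheres(i, 2), r = spheres(i, 3);
      const double rz2 = r * r - dz * dz;
      if (rz2 <= 0) continue;
      const double rz = std::sqrt(rz2);
      const double tc =
          (spheres(i, 0) - c0) * ct + (spheres(i, 1) - c0) * st + c0;
      const int jlo = std::max(0, (int)std::ceil(tc - rz));
      const int jhi = std::min(nt - 1, (int)std::floor(tc + rz));
      const double dv = sphere_val - cube_val;
      for (int j = jlo; j <= jhi; ++j) {
        const double u = j - tc;
        col[j] += dv * 2.0 * std::sqrt(std::max(0.0, rz2 - u * u));
      }
    }
  }
  return sino;
}

// x-range [xlo, xhi] for which t(x) = t0 + x*ct stays within [0, nt-1-eps],
// so the interpolation loop needs no per-pixel bounds check
static inline void x_range(double t0, double ct, int nt, int& xlo, int& xhi) {
  const double tmax = nt - 1.000001;
  if (std::fabs(ct) < 1e-12) {
    if (t0 >= 0 && t0 <= tmax) { xlo = 0; xhi = nt - 1; }
    else { xlo = 1; xhi = 0; }
    return;
  }
  double a = -t0 / ct, b = (tmax - t0) / ct;
  if (a > b) std::swap(a, b);
  xlo = std::max(0, (int)std::ceil(a));
  xhi = std::min(nt - 1, (int)std::floor(b));
  while (xlo <= xhi && (t0 + xlo * ct < 0 || t0 + xlo * ct > tmax)) ++xlo;
  while (xhi >= xlo && (t0 + xhi * ct < 0 || t0 + xhi * ct > tmax)) --xhi;
}

// Backprojection of a filtered sinogram (nt x K) onto an nt x nt slice.
// Caller applies the pi/(2K) filtered-backprojection scaling.
// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& sino, const arma::vec& angles_deg,
                          double center) {
  const int nt = sino.n_rows, K = sino.n_cols;
  const double cc = (nt - 1) / 2.0;
  mat out(nt, nt, fill::zeros);
  for (int k = 0; k < K; ++k) {
    const double th = angles_deg[k] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    const double* p = sino.colptr(k);
    for (int y = 0; y < nt; ++y) {
      double* o = out.colptr(y);
      const double t0 = (y - cc) * st - cc * ct + center;
      int xlo, xhi;
      x_range(t0, ct, nt, xlo, xhi);
      double t = t0 + xlo * ct;
      for (int x = xlo; x <= xhi; ++x, t += ct) {
        const int j = (int)t;
        const double w = t - j;
        o[x] += p[j] + w * (p[j + 1] - p[j]);
      }
    }
  }
  return out;
}

// Backproject two sinograms that share the geometry (e.g. clean and noisy
// versions of one slice) in a single pass over the index arithmetic.
// [[Rcpp::export]]
Rcpp::List cpp_backproject_pair(const arma::mat& sa, const arma::mat& sb,
                                const arma::vec& angles_deg, double center) {
  const int nt = sa.n_rows, K = sa.n_cols;
  const double cc = (nt - 1) / 2.0;
  mat oa(nt, nt, fill::zeros), ob(nt, nt, fill::zeros);
  for (int k = 0; k < K; ++k) {
    const double th = angles_deg[k] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    const double* pa = sa.colptr(k);
    const double* pb = sb.colptr(k);
    for (int y = 0; y < nt; ++y) {
      double* qa = oa.colptr(y);
      double* qb = ob.colptr(y);
      const double t0 = (y - cc) * st - cc * ct + center;
      int xlo, xhi;
      x_range(t0, ct, nt, xlo, xhi);
      double t = t0 + xlo * ct;
      for (int x = xlo; x <= xhi; ++x, t += ct) {
        const int j = (int)t;
        const double w = t - j;
        qa[x] += pa[j] + w * (pa[j + 1] - pa[j]);
        qb[x] += pb[j] + w * (pb[j + 1] - pb[j]);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("a") = oa, Rcpp::Named("b") = ob);
}
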
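// Core numerical kernels: containment labeling, analytic dipole-field
// superposition, Monte Carlo diffusion steps, and periodic separable
// convolution for the deterministic-diffusion backend.
//
// Perturber parameter matrices use fixed column layouts (kept in step with
// the R-side data frames, see R/geometry.R):
//   cylinders_2d (kind 1): radius, cx, cy, theta, phi0, dchi, perm
//   cylinders_3d (kind 2): radius, px, py, pz, dx, dy, dz, dchi, perm
//   spheres_3d   (kind 3): radius, cx, cy, cz, dchi, perm

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double EPS_DIR = 1e-14;

// ---- containment -----------------------------------------------------------

inline bool inside_cyl2d(double x, double y, const double* P, int i, int np) {
  double dx = x - P[np + i], dy = y - P[2 * np + i];
  double R = P[i];
  return dx * dx + dy * dy <= R * R;
}

inline bool inside_cyl3d(double x, double y, double z, const double* P, int i,
                         int np) {
  double ux = x - P[np + i], uy = y - P[2 * np + i], uz = z - P[3 * np + i];
  double ax = P[4 * np + i], ay = P[5 * np + i], az = P[6 * np + i];
  double proj = ux * ax + uy * ay + uz * az;
  double rx = ux - proj * ax, ry = uy - proj * ay, rz = uz - proj * az;
  double R = P[i];
  return rx * rx + ry * ry + rz * rz <= R * R;
}

inline bool inside_sph3d(double x, double y, double z, const double* P, int i,
                         int np) {
  double ux = x - P[np + i], uy = y - P[2 * np + i], uz = z - P[3 * np + i];
  double R = P[i];
  return ux * ux + uy * uy + uz * uz <= R * R;
}

// first containing perturber id (1-based), 0 if none
inline int label_one(const double* pt, int ndim, const double* P, int np,
                     int kind) {
  for (int i = 0; i < np; ++i) {
    bool in = false;
    if (kind == 1)
      in = inside_cyl2d(pt[0], pt[1], P, i, np);
    else if (kind == 2)
      in = inside_cyl3d(pt[0], pt[1], pt[2], P, i, np);
    else
      in = inside_sph3d(pt[0], pt[1], pt[2], P, i, np);
    if (in) return i + 1;
  }
  return 0;
}

// [[Rcpp::export]]
IntegerVector label_points_cpp(NumericMatrix pts, NumericMatrix P, int kind) {
  int n = pts.nrow(), ndim = pts.ncol(), np = P.nrow();
  IntegerVector out(n);
  double pt[3] = {0.0, 0.0, 0.0};
  for (int j = 0; j < n; ++j) {
    for (int d = 0; d < ndim; ++d) pt[d] = pts(j, d);
    out[j] = np == 0 ? 0 : label_one(pt, ndim, P.begin(), np, kind);
  }
  return out;
}

inline int grid_index(const double* pt, int ndim, int N, double W) {
  double dx = W / N;
  int idx = 0, stride = 1;
  for (int d = 0; d < ndim; ++d) {
    int i = (int)std::floor(pt[d] / dx);
    if (i < 0) i = 0;
    if (i >= N) i = N - 1;
    idx += stride * i;
    stride *= N;
  }
  return idx;
}

// [[Rcpp::export]]
IntegerVector label_points_grid_cpp(NumericMatrix pts, IntegerVector lab,
                                    int N, double W) {
  int n = pts.nrow(), ndim = pts.ncol();
  IntegerVector out(n);
  double pt[3] = {0.0, 0.0, 0.0};
  for (int j = 0; j < n; ++j) {
    for (int d = 0; d < ndim; ++d) pt[d] = pts(j, d);
    out[j] = lab[grid_index(pt, ndim, N, W)];
  }
  return out;
}

// ---- analytic dipole fields ------------------------------------------------

inline double field_cyl2d_one(double x, double y, const double* P, int i,
                              int np, double B0) {
  double R = P[i];
  double rx = x - P[np + i], ry = y - P[2 * np + i];
  double theta = P[3 * np + i], phi0 = P[4 * np + i], dchi = P[5 * np + i];
  double r2 = rx * rx + ry * ry;
  double c = std::cos(theta);
  if (r2 < R * R) return B0 * dchi / 6.0 * (3.0 * c * c - 1.0);
  double s2 = 1.0 - c * c;
  if (s2 <= 0.0) return 0.0;
  double phi = std::atan2(ry, rx) - phi0;
  return 0.5 * B0 * dchi * (R * R / r2) * std::cos(2.0 * phi) * s2;
}

inline double field_cyl3d_one(double x, double y, double z, const double* P,
                              int i, int np, double B0, const double* b) {
  double R = P[i], dchi = P[7 * np + i];
  double ax = P[4 * np + i], ay = P[5 * np + i], az = P[6 * np + i];
  double ux = x - P[np + i], uy = y - P[2 * np + i], uz = z - P[3 * np + i];
  double proj = ux * ax + uy * ay + uz * az;
  double rx = ux - proj * ax, ry = uy - proj * ay, rz = uz - proj * az;
  double r2 = rx * rx + ry * ry + rz * rz;
  double ct = b[0] * ax + b[1] * ay + b[2] * az;  // cos(theta)
  if (r2 < R * R) return B0 * dchi / 6.0 * (3.0 * ct * ct - 1.0);
  double s2 = 1.0 - ct * ct;  // sin^2(theta)
  if (s2 <= EPS_DIR) return 0.0;
  // B0 projection onto the plane orthogonal to the axis
  double bpx = b[0] - ct * ax, bpy = b[1] - ct * ay, bpz = b[2] - ct * az;
  double nb = std::sqrt(bpx * bpx + bpy * bpy + bpz * bpz);
  double r = std::sqrt(r2);
  double cphi = (rx * bpx + ry * bpy + rz * bpz) / (r * nb);
  double c2phi = 2.0 * cphi * cphi - 1.0;
  return 0.5 * B0 * dchi * (R * R / r2) * c2phi * s2;
}

inline double field_sph3d_one(double x, double y, double z, const double* P,
                              int i, int np, double B0, const double* b) {
  double R = P[i], dchi = P[4 * np + i];
  double ux = x - P[np + i], uy = y - P[2 * np + i], uz = z - P[3 * np + i];
  double r2 = ux * ux + uy * uy + uz * uz;
  if (r2 < R * R) return 0.0;  // no field offset inside a sphere
  double r = std::sqrt(r2);
  double ct = (ux * b[0] + uy * b[1] + uz * b[2]) / r;
  double R_over_r = R / r;
  return B0 * dchi / 3.0 * R_over_r * R_over_r * R_over_r *
         (3.0 * ct * ct - 1.0);
}

// [[Rcpp::export]]
NumericVector field_points_cpp(NumericMatrix pts, NumericMatrix P, int kind,
                               double B0, NumericVector b) {
  int n = pts.nrow(), np = P.nrow();
  NumericVector out(n);
  const double* Pp = P.begin();
  double bv[3] = {0.0, 0.0, 1.0};
  if (b.size() == 3) { bv[0] = b[0]; bv[1] = b[1]; bv[2] = b[2]; }
  if (kind == 1) {
    // hoist per-cylinder constants; cos(2 phi) is expanded through the
    // double-angle identity so the inner loop is transcendental-free
    std::vector<double> cx(np), cy(np), R2(np), inval(np), coef(np),
        c2p(np), s2p(np);
    for (int i = 0; i < np; ++i) {
      cx[i] = Pp[np + i];
      cy[i] = Pp[2 * np + i];
      double R = Pp[i], theta = Pp[3 * np + i], phi0 = Pp[4 * np + i];
      double dchi = Pp[5 * np + i], c = std::cos(theta);
      R2[i] = R * R;
      inval[i] = B0 * dchi / 6.0 * (3.0 * c * c - 1.0);
      coef[i] = 0.5 * B0 * dchi * R * R * (1.0 - c * c);
      c2p[i] = std::cos(2.0 * phi0);
      s2p[i] = std::sin(2.0 * phi0);
    }
    for (int j = 0; j < n; ++j) {
      double x = pts(j, 0), y = pts(j, 1), acc = 0.0;
      for (int i = 0; i < np; ++i) {
        double rx = x - cx[i], ry = y - cy[i];
        double r2 = rx * rx + ry * ry;
        if (r2 < R2[i]) {
          acc += inval[i];
        } else if (r2 > 0.0) {
          // cos(2(a - phi0)) with cos(2a) = (rx^2-ry^2)/r^2,
          // sin(2a) = 2 rx ry / r^2
          double c2a = (rx * rx - ry * ry) / r2, s2a = 2.0 * rx * ry / r2;
          acc += coef[i] * (c2a * c2p[i] + s2a * s2p[i]) / r2;
        }
      }
      out[j] = acc;
    }
    return out;
  }
  for (int j = 0; j < n; ++j) {
    double x = pts(j, 0), y = pts(j, 1);
    double z = pts.ncol() > 2 ? pts(j, 2) : 0.0;
    double acc = 0.0;
    for (int i = 0; i < np; ++i) {
      if (kind == 2)
        acc += field_cyl3d_one(x, y, z, Pp, i, np, B0, bv);
      else
        acc += field_sph3d_one(x, y, z, Pp, i, np, B0, bv);
    }
    out[j] = acc;
  }
  return out;
}

// ---- Monte Carlo diffusion step --------------------------------------------

inline double perm_of(int lab, const double* perm) {
  return lab == 0 ? 1.0 : perm[lab - 1];
}

// One diffusion step for all spins. Geometry is either an analytic perturber
// set (kind 1..3, perm per perturber) or a label grid (kind 4, perm per
// label id). Positions wrap periodically on [0, W). A step whose endpoint
// label differs from the start is a wall crossing: one Bernoulli permeation
// roll per attempted crossing; on failure the step is resampled until a
// non-crossing one is found (up to maxRetry, then the spin stays put).
// [[Rcpp::export]]
List mc_step_cpp(NumericMatrix pos, IntegerVector lab, double sigma, double W,
                 int kind, NumericMatrix P, IntegerVector grid, int N,
                 NumericVector perm, int maxRetry) {
  int n = pos.nrow(), ndim = pos.ncol();
  int np = P.nrow();
  NumericMatrix newpos(n, ndim), disp(n, ndim);
  IntegerVector newlab(n);
  int n_stuck = 0;
  const double* Pp = P.begin();
  const double* pv = perm.begin();
  double cand[3], step[3];

  for (int j = 0; j < n; ++j) {
    int l0 = lab[j];
    bool accepted = false, rolled = false;
    int nl = l0;
    for (int attempt = 0; attempt <= maxRetry; ++attempt) {
      for (int d = 0; d < ndim; ++d) {
        step[d] = sigma * norm_rand();
        double x = pos(j, d) + step[d];
        x -= W * std::floor(x / W);  // periodic wrap onto [0, W)
        cand[d] = x;
      }
      if (kind == 4)
        nl = grid[grid_index(cand, ndim, N, W)];
      else
        nl = np == 0 ? 0 : label_one(cand, ndim, Pp, np, kind);
      if (nl == l0) {
        accepted = true;
        break;
      }
      // attempted wall crossing
      if (!rolled) {
        rolled = true;
        double p = std::min(perm_of(l0, pv), perm_of(nl, pv));
        if (p > 0.0 && unif_rand() < p) {
          accepted = true;  // permeation succeeds
          break;
        }
      }
      // else: resample until a non-crossing step is found
    }
    if (accepted) {
      for (int d = 0; d < ndim; ++d) {
        newpos(j, d) = cand[d];
        disp(j, d) = step[d];
      }
      newlab[j] = nl;
    } else {
      for (int d = 0; d < ndim; ++d) {
        newpos(j, d) = pos(j, d);
        disp(j, d) = 0.0;
      }
      newlab[j] = l0;
      ++n_stuck;
    }
  }
  return List::create(_["pos"] = newpos, _["label"] = newlab,
                      _["disp"] = disp, _["n_stuck"] = n_stuck);
}

// ---- periodic separable convolution (deterministic diffusion) --------------

// Circular convolution of a 2D grid with a symmetric 1D kernel applied along
// both axes (separable construction of the 2D product kernel).
// [[Rcpp::export]]
arma::cx_mat conv_sep_periodic_cx(const arma::cx_mat& M,
                                  const arma::vec& w) {
  int h = ((int)w.n_elem - 1) / 2;
  int nr = M.n_rows, nc = M.n_cols;
  arma::cx_mat tmp(nr, nc), out(nr, nc, arma::fill::zeros);
  // along rows (dim 1): tmp(i,j) = sum_k w[k] M((i-k) mod nr, j);
  // tap-inner loops over contiguous column data keep this in cache
  for (int j = 0; j < nc; ++j) {
    const arma::cx_double* src = M.colptr(j);
    arma::cx_double* dst = tmp.colptr(j);
    int lo = std::min(h, nr), hi = std::max(nr - h, lo);
    for (int i = 0; i < lo; ++i) {
      arma::cx_double acc(0.0, 0.0);
      for (int k = -h; k <= h; ++k)
        acc += w[k + h] * src[(((i - k) % nr) + nr) % nr];
      dst[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      arma::cx_double acc(0.0, 0.0);
      for (int k = -h; k <= h; ++k) acc += w[k + h] * src[i - k];
      dst[i] = acc;
    }
    for (int i = hi; i < nr; ++i) {
      arma::cx_double acc(0.0, 0.0);
      for (int k = -h; k <= h; ++k)
        acc += w[k + h] * src[(((i - k) % nr) + nr) % nr];
      dst[i] = acc;
    }
  }
  // along columns (dim 2): contiguous-column axpy per tap
  for (int j = 0; j < nc; ++j) {
    arma::cx_double* dst = out.colptr(j);
    for (int k = -h; k <= h; ++k) {
      double wk = w[k + h];
      const arma::cx_double* src = tmp.colptr((((j - k) % nc) + nc) % nc);
      for (int i = 0; i < nr; ++i) dst[i] += wk * src[i];
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat conv_sep_periodic_re(const arma::mat& M, const arma::vec& w) {
  arma::cx_mat Mc(M, arma::zeros<arma::mat>(M.n_rows, M.n_cols));
  return arma::real(conv_sep_periodic_cx(Mc, w));
}
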
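#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Radiological depth from a point source to each target point, by ray
// marching through a voxelized density grid (nearest-neighbour sampling).
//
// The march is restricted to the grid bounding box (density outside is
// treated as ~0, i.e. air). Depth is returned in mm of water-equivalent
// path length (integral of density over geometric path).
//
// density: nx*ny*nz array (column-major, x fastest), g/cm^3
// origin:  coordinates (mm) of the centre of voxel [1,1,1]
// vox:     voxel size (mm) per axis
// step:    marching step (mm)
// [[Rcpp::export(name = ".ray_depth_cpp")]]
NumericVector ray_depth_cpp(NumericVector px, NumericVector py, NumericVector pz,
                            double sx, double sy, double sz,
                            NumericVector density, IntegerVector dims,
                            NumericVector origin, NumericVector vox,
                            double step) {
  const int n = px.size();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double dx = vox[0], dy = vox[1], dz = vox[2];
  // grid bounding box (outer faces of edge voxels)
  const double x0 = ox - 0.5 * dx, x1 = ox + (nx - 0.5) * dx;
  const double y0 = oy - 0.5 * dy, y1 = oy + (ny - 0.5) * dy;
  const double z0 = oz - 0.5 * dz, z1 = oz + (nz - 0.5) * dz;
  NumericVector out(n);

  for (int i = 0; i < n; ++i) {
    double rx = px[i] - sx, ry = py[i] - sy, rz = pz[i] - sz;
    double L = std::sqrt(rx * rx + ry * ry + rz * rz);
    if (L <= 0) { out[i] = 0.0; continue; }
    rx /= L; ry /= L; rz /= L;
    // slab intersection of ray [0, L] with bounding box
    double tmin = 0.0, tmax = L;
    const double dirs[3] = {rx, ry, rz};
    const double s0[3] = {sx, sy, sz};
    const double lo[3] = {x0, y0, z0};
    const double hi[3] = {x1, y1, z1};
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(dirs[a]) < 1e-12) {
        if (s0[a] < lo[a] || s0[a] > hi[a]) { miss = true; break; }
      } else {
        double t1 = (lo[a] - s0[a]) / dirs[a];
        double t2 = (hi[a] - s0[a]) / dirs[a];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
      }
    }
    if (miss || tmax <= tmin) { out[i] = 0.0; continue; }
    // midpoint-rule march
    double depth = 0.0;
    int nstep = (int)std::ceil((tmax - tmin) / step);
    if (nstep < 1) nstep = 1;
    double h = (tmax - tmin) / nstep;
    for (int k = 0; k < nstep; ++k) {
      double t = tmin + (k + 0.5) * h;
      double qx = sx + t * rx, qy = sy + t * ry, qz = sz + t * rz;
      int ix = (int)std::lround((qx - ox) / dx);
      int iy = (int)std::lround((qy - oy) / dy);
      int iz = (int)std::lround((qz - oz) / dz);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
        continue;
      depth += density[ix + nx * (iy + (long)ny * iz)] * h;
    }
    out[i] = depth;
  }
  return out;
}

// Exhaustive gamma-index search: for every evaluated pixel, minimize over
// ALL points of the (already upsampled) reference grid. Serves as the
// brute-force oracle for the capped/vectorized R implementation.
//
// de:   evaluated dose, ne_r x ne_c (column-major)
// dr:   upsampled reference dose, nr_r x nr_c
// er0, ec0: 0-based row/col positions (in upsampled-grid units) of the
//           evaluated pixels' coordinates
// sp_r, sp_c: spacing (mm) of the upsampled reference grid
// dd_abs: dose criterion in Gy (dd% of normalization dose)
// dta: distance criterion (mm)
// eval_mask: 1 = compute, 0 = skip (returns NA)
// [[Rcpp::export(name = ".gamma_exhaustive_cpp")]]
NumericVector gamma_exhaustive_cpp(NumericVector de, IntegerVector de_dim,
                                   NumericVector dr, IntegerVector dr_dim,
                                   NumericVector er0, NumericVector ec0,
                                   double sp_r, double sp_c,
                                   double dd_abs, double dta,
                                   IntegerVector eval_mask) {
  const int ne = de.size();
  const int nrr = dr_dim[0], nrc = dr_dim[1];
  const double inv_dta2 = 1.0 / (dta * dta);
  const double inv_dd2 = 1.0 / (dd_abs * dd_abs);
  NumericVector out(ne);

  for (int i = 0; i < ne; ++i) {
    if (!eval_mask[i]) { out[i] = NA_REAL; continue; }
    const double Dv = de[i];
    const double r0 = er0[i], c0 = ec0[i];
    double best = R_PosInf;
    for (int c = 0; c < nrc; ++c) {
      double dc = (c - c0) * sp_c;
      double dc2 = dc * dc;
      for (int r = 0; r < nrr; ++r) {
        double drr = (r - r0) * sp_r;
        double dD = Dv - dr[r + (long)nrr * c];
        double g2 = (drr * drr + dc2) * inv_dta2 + dD * dD * inv_dd2;
        if (g2 < best) best = g2;
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
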
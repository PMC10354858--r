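// Hot numerical loops: dose accumulation over control points, trilinear
// resampling, gamma-index search and phantom-shift search. All geometry is in
// mm, right-handed, isocenter at the origin, y = gantry rotation (couch) axis.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Smooth algebraic step, ~N(0,1) CDF shape but cheap; sstep(0)=0.5.
static inline double sstep(double u) {
  return 0.5 * (1.0 + u / std::sqrt(1.0 + u * u));
}

// Accumulate dose on a regular 3D grid from arc control points.
// Fluence model: per-leaf-row gate with algebraic penumbra of width sigma_x
// along the leaf-travel (BEV lateral) axis, soft row weighting of width
// sigma_y along the leaf-index (couch) axis, leaf transmission `trans`,
// exponential attenuation exp(-mu_att * depth) with depth measured from the
// phantom surface toward the source.
// leaf_a/leaf_b: n_cp x n_rows matrices of bank A/B positions (a <= b, mm at
// isocenter); row_edges: n_rows+1 boundaries along y.
// [[Rcpp::export]]
NumericVector cpp_accumulate_dose(NumericVector xs, NumericVector ys,
                                  NumericVector zs, NumericVector gantry_deg,
                                  NumericVector mu_w, NumericMatrix leaf_a,
                                  NumericMatrix leaf_b, NumericVector row_edges,
                                  double sigma_x, double sigma_y, double trans,
                                  double mu_att, double phantom_radius) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  const int ncp = gantry_deg.size(), nrow = leaf_a.ncol();
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);

  // Row weights per y-grid index: soft membership w_j(y); depends only on the
  // grid, so precompute (sparse: a few rows per y).
  std::vector<std::vector<std::pair<int, double>>> wy(ny);
  const double reach = 4.0 * sigma_y;
  for (int iy = 0; iy < ny; ++iy) {
    const double y = ys[iy];
    for (int j = 0; j < nrow; ++j) {
      const double lo = row_edges[j], hi = row_edges[j + 1];
      if (y < lo - reach || y > hi + reach) continue;
      const double w = sstep((y - lo) / sigma_y) - sstep((y - hi) / sigma_y);
      if (w > 1e-8) wy[iy].emplace_back(j, w);
    }
  }

  std::vector<double> gate(nrow);
  for (int cp = 0; cp < ncp; ++cp) {
    const double phi = gantry_deg[cp] * M_PI / 180.0;
    const double cph = std::cos(phi), sph = std::sin(phi), w_cp = mu_w[cp];
    for (int iz = 0; iz < nz; ++iz) {
      const double z = zs[iz];
      for (int ix = 0; ix < nx; ++ix) {
        const double x = xs[ix];
        const double xb = x * cph - z * sph;       // BEV lateral coordinate
        const double proj = x * sph + z * cph;     // toward the source
        double depth = phantom_radius - proj;
        if (depth < 0.0) depth = 0.0;
        const double att = w_cp * std::exp(-mu_att * depth);
        for (int j = 0; j < nrow; ++j) {
          const double a = leaf_a(cp, j), b = leaf_b(cp, j);
          // aperture indicator convolved with the penumbra kernel: vanishes
          // for a zero-width opening, saturates inside a wide one
          double open = sstep((xb - a) / sigma_x) - sstep((xb - b) / sigma_x);
          if (open < 0.0) open = 0.0;
          gate[j] = trans + (1.0 - trans) * open;
        }
        const R_xlen_t base = ix + static_cast<R_xlen_t>(nx) * ny * iz;
        for (int iy = 0; iy < ny; ++iy) {
          double f = 0.0;
          for (const auto& jw : wy[iy]) f += jw.second * gate[jw.first];
          out[base + static_cast<R_xlen_t>(nx) * iy] += att * f;
        }
      }
    }
  }
  return out;
}

static inline double tri_at(const double* v, int nx, int ny, int nz,
                            double ox, double oy, double oz, double hx,
                            double hy, double hz, double px, double py,
                            double pz) {
  double fx = (px - ox) / hx, fy = (py - oy) / hy, fz = (pz - oz) / hz;
  if (fx < 0) fx = 0; if (fx > nx - 1) fx = nx - 1;
  if (fy < 0) fy = 0; if (fy > ny - 1) fy = ny - 1;
  if (fz < 0) fz = 0; if (fz > nz - 1) fz = nz - 1;
  int i0 = static_cast<int>(fx), j0 = static_cast<int>(fy),
      k0 = static_cast<int>(fz);
  if (i0 > nx - 2) i0 = nx - 2; if (j0 > ny - 2) j0 = ny - 2;
  if (k0 > nz - 2) k0 = nz - 2;
  if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
  const double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  const R_xlen_t sx = 1, sy = nx, sz = static_cast<R_xlen_t>(nx) * ny;
  const R_xlen_t b = i0 * sx + j0 * sy + k0 * sz;
  const int dx = (nx > 1), dy = (ny > 1), dz = (nz > 1);
  const double c000 = v[b], c100 = v[b + dx * sx], c010 = v[b + dy * sy],
               c110 = v[b + dx * sx + dy * sy], c001 = v[b + dz * sz],
               c101 = v[b + dx * sx + dz * sz], c011 = v[b + dy * sy + dz * sz],
               c111 = v[b + dx * sx + dy * sy + dz * sz];
  const double c00 = c000 * (1 - tx) + c100 * tx,
               c10 = c010 * (1 - tx) + c110 * tx,
               c01 = c001 * (1 - tx) + c101 * tx,
               c11 = c011 * (1 - tx) + c111 * tx;
  const double c0 = c00 * (1 - ty) + c10 * ty, c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// Trilinear interpolation of a 3D grid at arbitrary points (edge-clamped).
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vals, IntegerVector dim,
                            NumericVector origin, NumericVector spacing,
                            NumericMatrix pts) {
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = tri_at(vals.begin(), dim[0], dim[1], dim[2], origin[0], origin[1],
                    origin[2], spacing[0], spacing[1], spacing[2], pts(i, 0),
                    pts(i, 1), pts(i, 2));
  return out;
}

// Resample a grid under the affine map p -> R p + t: out(p) = in(R p + t).
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vals, IntegerVector dim,
                                  NumericVector origin, NumericVector spacing,
                                  NumericMatrix rot, NumericVector trans) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double z = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      const double y = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double x = origin[0] + i * spacing[0];
        const double qx = rot(0, 0) * x + rot(0, 1) * y + rot(0, 2) * z + trans[0];
        const double qy = rot(1, 0) * x + rot(1, 1) * y + rot(1, 2) * z + trans[1];
        const double qz = rot(2, 0) * x + rot(2, 1) * y + rot(2, 2) * z + trans[2];
        out[idx] = tri_at(vals.begin(), nx, ny, nz, origin[0], origin[1],
                          origin[2], spacing[0], spacing[1], spacing[2], qx, qy,
                          qz);
      }
    }
  }
  return out;
}

static inline double bilin_at(const double* v, int nx, int ny, double ox,
                              double oy, double h, double px, double py) {
  double fx = (px - ox) / h, fy = (py - oy) / h;
  if (fx < 0) fx = 0; if (fx > nx - 1) fx = nx - 1;
  if (fy < 0) fy = 0; if (fy > ny - 1) fy = ny - 1;
  int i0 = static_cast<int>(fx), j0 = static_cast<int>(fy);
  if (i0 > nx - 2) i0 = nx - 2; if (j0 > ny - 2) j0 = ny - 2;
  if (nx == 1) i0 = 0; if (ny == 1) j0 = 0;
  const double tx = fx - i0, ty = fy - j0;
  const int dx = (nx > 1), dy = (ny > 1);
  const double c00 = v[i0 + nx * j0], c10 = v[i0 + dx + nx * j0],
               c01 = v[i0 + nx * (j0 + dy)], c11 = v[i0 + dx + nx * (j0 + dy)];
  return (c00 * (1 - tx) + c10 * tx) * (1 - ty) +
         (c01 * (1 - tx) + c11 * tx) * ty;
}

struct Offset { double dx, dy, r2; };

static std::vector<Offset> make_offsets(double radius, double step) {
  std::vector<Offset> off;
  const int m = static_cast<int>(std::floor(radius / step));
  for (int i = -m; i <= m; ++i)
    for (int j = -m; j <= m; ++j) {
      const double dx = i * step, dy = j * step, r2 = dx * dx + dy * dy;
      if (r2 <= radius * radius + 1e-12) off.push_back({dx, dy, r2});
    }
  std::sort(off.begin(), off.end(),
            [](const Offset& a, const Offset& b) { return a.r2 < b.r2; });
  return off;
}

// Gamma index per reference point against an evaluated distribution given on
// a regular in-plane grid (values in column-major nx x ny, square step h).
// dd_abs = absolute dose tolerance (dd% of the global normalization dose).
// Search lattice step = dta/step_div over radius radius_factor*dta, sorted by
// radius with the standard early-stop (distance term alone exceeds current
// minimum).
// [[Rcpp::export]]
NumericVector cpp_gamma_plane(NumericMatrix ref_pts, NumericVector ref_dose,
                              NumericVector eval_vals, int nx, int ny,
                              double ox, double oy, double h, double dd_abs,
                              double dta, double radius_factor,
                              double step_div) {
  const double step = dta / step_div;
  const std::vector<Offset> off = make_offsets(radius_factor * dta, step);
  const int n = ref_pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = ref_pts(i, 0), py = ref_pts(i, 1), d0 = ref_dose[i];
    double best = R_PosInf, bx = 0.0, by = 0.0;
    for (const auto& o : off) {
      const double dist2 = o.r2 / (dta * dta);
      if (dist2 >= best) break;  // offsets sorted by radius
      const double d = bilin_at(eval_vals.begin(), nx, ny, ox, oy, h,
                                px + o.dx, py + o.dy);
      const double gd = (d - d0) / dd_abs;
      const double g2 = gd * gd + dist2;
      if (g2 < best) { best = g2; bx = o.dx; by = o.dy; }
    }
    // local refinement around the lattice minimum removes most of the
    // discretization error of the coarse step
    double st = step;
    for (int level = 0; level < 3; ++level) {
      st /= 4.0;
      double nbx = bx, nby = by;
      for (int di = -4; di <= 4; ++di)
        for (int dj = -4; dj <= 4; ++dj) {
          const double cx = bx + di * st, cy = by + dj * st;
          const double dist2 = (cx * cx + cy * cy) / (dta * dta);
          if (dist2 >= best) continue;
          const double d = bilin_at(eval_vals.begin(), nx, ny, ox, oy, h,
                                    px + cx, py + cy);
          const double gd = (d - d0) / dd_abs;
          const double g2 = gd * gd + dist2;
          if (g2 < best) { best = g2; nbx = cx; nby = cy; }
        }
      bx = nbx; by = nby;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Phantom-shift search: for each candidate 3D shift, count diodes passing the
// gamma criterion (in-plane DTA search around the shifted position, evaluated
// trilinearly in the 3D calculated grid) and accumulate |dose difference| at
// zero offset. e1/e2 span the detector plane of the supplied points.
// Returns m x 2: (n_pass, sum |dd| at offset 0).
// [[Rcpp::export]]
NumericMatrix cpp_shift_objective(NumericVector vals, IntegerVector dim,
                                  NumericVector origin, NumericVector spacing,
                                  NumericMatrix pts, NumericVector meas,
                                  NumericVector e1, NumericVector e2,
                                  double dd_abs, double dta,
                                  NumericMatrix shifts) {
  // pass/fail only needs offsets with |r| <= dta
  const std::vector<Offset> off = make_offsets(dta, dta / 10.0);
  const int n = pts.nrow(), m = shifts.nrow();
  NumericMatrix out(m, 2);
  for (int s = 0; s < m; ++s) {
    const double sx = shifts(s, 0), sy = shifts(s, 1), sz = shifts(s, 2);
    int npass = 0;
    double sumdd = 0.0;
    for (int i = 0; i < n; ++i) {
      const double bx = pts(i, 0) + sx, by = pts(i, 1) + sy,
                   bz = pts(i, 2) + sz;
      bool pass = false;
      for (const auto& o : off) {
        const double dist2 = o.r2 / (dta * dta);
        if (dist2 > 1.0) break;
        const double d = tri_at(vals.begin(), dim[0], dim[1], dim[2], origin[0],
                                origin[1], origin[2], spacing[0], spacing[1],
                                spacing[2], bx + o.dx * e1[0] + o.dy * e2[0],
                                by + o.dx * e1[1] + o.dy * e2[1],
                                bz + o.dx * e1[2] + o.dy * e2[2]);
        const double gd = (d - meas[i]) / dd_abs;
        if (o.dx == 0.0 && o.dy == 0.0) sumdd += std::fabs(d - meas[i]);
        if (gd * gd + dist2 <= 1.0) { pass = true; break; }
      }
      if (pass) {
        npass++;
        // still need the zero-offset |dd| if the early break skipped it:
        // offset (0,0) is always first in the sorted list, so it was visited.
      }
    }
    out(s, 0) = npass;
    out(s, 1) = sumdd;
  }
  return out;
}

// Mean |measured - calculated(p + shift)| per candidate shift (refinement
// objective; sharp minimum at exact alignment).
// [[Rcpp::export]]
NumericVector cpp_shift_dd(NumericVector vals, IntegerVector dim,
                           NumericVector origin, NumericVector spacing,
                           NumericMatrix pts, NumericVector meas,
                           NumericMatrix shifts) {
  const int n = pts.nrow(), m = shifts.nrow();
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d = tri_at(vals.begin(), dim[0], dim[1], dim[2], origin[0],
                              origin[1], origin[2], spacing[0], spacing[1],
                              spacing[2], pts(i, 0) + shifts(s, 0),
                              pts(i, 1) + shifts(s, 1), pts(i, 2) + shifts(s, 2));
      acc += std::fabs(meas[i] - d);
    }
    out[s] = acc / n;
  }
  return out;
}
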
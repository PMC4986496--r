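// Numerical cores: exact voxel-boundary (Siddon-style) ray tracing,
// the per-fraction dose summation loop, the Chan-Vese level-set descent,
// the 3%/3mm box-index search and a bilinear sampler.
//
// Geometry convention (shared with the R side): a volume is an R array
// [row, col, slice]; x runs along columns (patient left +), y along rows
// (posterior +), z along slices (superior +).  The voxel value sits at the
// voxel centre; voxel [1,1,1] (R indexing) is centred at `origin`.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double rho_of(double hu, double offset, double slope) {
  double r = 1.0 + (hu - offset) / slope;
  return r > 0.0 ? r : 0.0;
}

struct Grid {
  const double* v;
  int ny, nx, nz;            // rows, cols, slices
  double bx, by, bz;         // lower boundary (origin - half voxel)
  double sx, sy, sz;         // spacings: x=col, y=row, z=slice
  double offset, slope;      // HU calibration for this volume
};

// WEPL (mm) of the segment p0 -> p1 through one volume; regions outside the
// volume contribute zero density.  Incremental Siddon traversal.
static double siddon_wepl(const Grid& g,
                          double p0x, double p0y, double p0z,
                          double p1x, double p1y, double p1z) {
  const double dx = p1x - p0x, dy = p1y - p0y, dz = p1z - p0z;
  const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (L <= 0.0) return 0.0;

  // clip [0,1] parameter range to the volume's bounding box
  double t0 = 0.0, t1 = 1.0;
  const double lo[3] = { g.bx, g.by, g.bz };
  const double hi[3] = { g.bx + g.nx * g.sx, g.by + g.ny * g.sy,
                         g.bz + g.nz * g.sz };
  const double p0[3] = { p0x, p0y, p0z };
  const double d[3]  = { dx, dy, dz };
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p0[a] <= lo[a] || p0[a] >= hi[a]) return 0.0;
    } else {
      double ta = (lo[a] - p0[a]) / d[a];
      double tb = (hi[a] - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return 0.0;

  // entry voxel (nudge inside to avoid landing exactly on a boundary)
  const double tin = t0 + 1e-10 * (t1 - t0);
  int ix = (int)std::floor((p0x + tin * dx - g.bx) / g.sx);
  int iy = (int)std::floor((p0y + tin * dy - g.by) / g.sy);
  int iz = (int)std::floor((p0z + tin * dz - g.bz) / g.sz);
  if (ix < 0) ix = 0;
  if (ix >= g.nx) ix = g.nx - 1;
  if (iy < 0) iy = 0;
  if (iy >= g.ny) iy = g.ny - 1;
  if (iz < 0) iz = 0;
  if (iz >= g.nz) iz = g.nz - 1;

  // per-axis parametric step and next-crossing parameter
  double tstep[3], tnext[3];
  int istep[3], idx[3] = { ix, iy, iz };
  const double sp[3] = { g.sx, g.sy, g.sz };
  const double b[3]  = { g.bx, g.by, g.bz };
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      tstep[a] = 0.0; tnext[a] = 2.0; istep[a] = 0;
    } else {
      tstep[a] = sp[a] / std::fabs(d[a]);
      istep[a] = d[a] > 0 ? 1 : -1;
      double bound = b[a] + (idx[a] + (d[a] > 0 ? 1 : 0)) * sp[a];
      tnext[a] = (bound - p0[a]) / d[a];
      if (tnext[a] < t0) tnext[a] += tstep[a];
    }
  }

  const int strideC = g.ny, strideS = g.ny * g.nx;
  double wepl = 0.0, tcur = t0;
  while (tcur < t1 - 1e-14) {
    int amin = 0;
    if (tnext[1] < tnext[amin]) amin = 1;
    if (tnext[2] < tnext[amin]) amin = 2;
    double tn = tnext[amin] < t1 ? tnext[amin] : t1;
    double seg = (tn - tcur) * L;
    if (seg > 0 && idx[0] >= 0 && idx[0] < g.nx &&
        idx[1] >= 0 && idx[1] < g.ny && idx[2] >= 0 && idx[2] < g.nz) {
      double hu = g.v[idx[1] + idx[0] * strideC + idx[2] * strideS];
      wepl += rho_of(hu, g.offset, g.slope) * seg;
    }
    tcur = tn;
    if (tnext[amin] <= t1) {
      idx[amin] += istep[amin];
      tnext[amin] += tstep[amin];
    }
    if (idx[amin] < 0 || (amin == 0 && idx[0] >= g.nx) ||
        (amin == 1 && idx[1] >= g.ny) || (amin == 2 && idx[2] >= g.nz)) break;
  }
  return wepl;
}

static Grid make_grid(const NumericVector& vol, const NumericVector& origin,
                      const NumericVector& spacing, double offset,
                      double slope) {
  IntegerVector dm = vol.attr("dim");
  Grid g;
  g.v = REAL(vol);
  g.ny = dm[0]; g.nx = dm[1]; g.nz = dm[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.bx = origin[0] - g.sx / 2.0;
  g.by = origin[1] - g.sy / 2.0;
  g.bz = origin[2] - g.sz / 2.0;
  g.offset = offset; g.slope = slope;
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_wepl(NumericVector vol, NumericVector origin,
                       NumericVector spacing, NumericMatrix p0,
                       NumericMatrix p1, double offset, double slope) {
  Grid g = make_grid(vol, origin, spacing, offset, slope);
  int n = p0.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = siddon_wepl(g, p0(i, 0), p0(i, 1), p0(i, 2),
                         p1(i, 0), p1(i, 1), p1(i, 2));
  return out;
}

// Per-fraction dose: sum the simplified beamlet model over control points.
// Control points carry gantry angle (radians, roll already applied), couch z
// (mm), weight, and a row of leaf-open fractions.
// [[Rcpp::export]]
NumericVector cpp_fraction_dose(NumericMatrix pts,
                                NumericVector angles, NumericVector couch_z,
                                NumericVector weights, NumericMatrix leaf_open,
                                List beam,
                                NumericVector mv_vol, NumericVector mv_origin,
                                NumericVector mv_spacing, double mv_offset,
                                double mv_slope,
                                bool use_kv,
                                NumericVector kv_vol, NumericVector kv_origin,
                                NumericVector kv_spacing, double kv_offset,
                                double kv_slope) {
  const double sad = beam["sad"];
  const double mu_cm = beam["mu_cm"];
  const double of = beam["output_factor"];
  const double dscale = beam["dose_scale"];
  const int nl = beam["n_leaves"];
  const double lw = beam["leaf_width"];
  const double fan = beam["fan_extent"];
  const double isox = beam["iso_x"];
  const double isoy = beam["iso_y"];
  const double sigma = lw / 2.355;          // FWHM = leaf width
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double lat_lim = nl * lw / 2.0 + 4.0 * sigma;

  Grid gmv = make_grid(mv_vol, mv_origin, mv_spacing, mv_offset, mv_slope);
  Grid gkv;
  if (use_kv) gkv = make_grid(kv_vol, kv_origin, kv_spacing, kv_offset,
                              kv_slope);

  const int npt = pts.nrow(), ncp = angles.size();
  NumericVector dose(npt);
  std::vector<double> sx(ncp), sy(ncp);
  for (int c = 0; c < ncp; ++c) {
    sx[c] = isox + sad * std::sin(angles[c]);
    sy[c] = isoy - sad * std::cos(angles[c]);
  }

  for (int i = 0; i < npt; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double acc = 0.0;
    for (int c = 0; c < ncp; ++c) {
      const double Sx = sx[c], Sy = sy[c], Sz = couch_z[c];
      // unit central-axis direction (source -> isocentre, in-plane)
      const double ux = (isox - Sx) / sad, uy = (isoy - Sy) / sad;
      const double dxp = px - Sx, dyp = py - Sy;
      const double t2d = dxp * ux + dyp * uy;   // in-plane depth along axis
      if (t2d <= 1e-6) continue;
      const double mag = sad / t2d;             // project to isocentre plane
      const double zoff = (pz - Sz) * mag;
      if (std::fabs(zoff) > fan / 2.0) continue;       // outside SI fan
      const double lat = (-dxp * uy + dyp * ux) * mag; // signed lateral @ iso
      if (std::fabs(lat) > lat_lim) continue;
      // effective open fraction: Gaussian leaf profiles
      double eff = 0.0;
      const double half = (nl - 1) / 2.0;
      int l0 = (int)std::floor(half + (lat - 4.0 * sigma) / lw);
      int l1 = (int)std::ceil(half + (lat + 4.0 * sigma) / lw);
      if (l0 < 0) l0 = 0;
      if (l1 > nl - 1) l1 = nl - 1;
      for (int l = l0; l <= l1; ++l) {
        double op = leaf_open(c, l);
        if (op <= 0.0) continue;
        double u = lat - (l - half) * lw;
        eff += op * std::exp(-u * u * inv2s2);
      }
      if (eff < 1e-8) continue;
      const double dz = pz - Sz;
      const double dist = std::sqrt(dxp * dxp + dyp * dyp + dz * dz);
      double wepl = siddon_wepl(gmv, Sx, Sy, Sz, px, py, pz);
      if (use_kv) wepl += siddon_wepl(gkv, Sx, Sy, Sz, px, py, pz);
      acc += weights[c] * eff * std::exp(-mu_cm * wepl / 10.0) *
             (sad / dist) * (sad / dist);
    }
    dose[i] = acc * of * dscale;
  }
  return dose;
}

// chamfer (3-4 style) distance to the set marked true in `sel`
static NumericMatrix chamfer_dist(const IntegerMatrix& sel) {
  const int nr = sel.nrow(), nc = sel.ncol();
  const double BIG = 1e9, DIAG = 1.41421356;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) d(i, j) = sel(i, j) ? 0.0 : BIG;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = d(i, j);
      if (i > 0 && d(i - 1, j) + 1 < v) v = d(i - 1, j) + 1;
      if (j > 0 && d(i, j - 1) + 1 < v) v = d(i, j - 1) + 1;
      if (i > 0 && j > 0 && d(i - 1, j - 1) + DIAG < v)
        v = d(i - 1, j - 1) + DIAG;
      if (i > 0 && j < nc - 1 && d(i - 1, j + 1) + DIAG < v)
        v = d(i - 1, j + 1) + DIAG;
      d(i, j) = v;
    }
  for (int j = nc - 1; j >= 0; --j)
    for (int i = nr - 1; i >= 0; --i) {
      double v = d(i, j);
      if (i < nr - 1 && d(i + 1, j) + 1 < v) v = d(i + 1, j) + 1;
      if (j < nc - 1 && d(i, j + 1) + 1 < v) v = d(i, j + 1) + 1;
      if (i < nr - 1 && j < nc - 1 && d(i + 1, j + 1) + DIAG < v)
        v = d(i + 1, j + 1) + DIAG;
      if (i < nr - 1 && j > 0 && d(i + 1, j - 1) + DIAG < v)
        v = d(i + 1, j - 1) + DIAG;
      d(i, j) = v;
    }
  return d;
}

// signed distance from a mask (positive inside, half-pixel offset)
static NumericMatrix signed_dist(const NumericMatrix& phi) {
  const int nr = phi.nrow(), nc = phi.ncol();
  IntegerMatrix cur(nr, nc), inv(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      cur(i, j) = phi(i, j) >= 0 ? 1 : 0;
      inv(i, j) = 1 - cur(i, j);
    }
  NumericMatrix df = chamfer_dist(cur), db = chamfer_dist(inv);
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = cur(i, j) ? db(i, j) - 0.5 : -(df(i, j) - 0.5);
  return out;
}

// Two-phase piecewise-constant Chan-Vese level set: signed-distance init,
// semi-implicit Gauss-Seidel descent, regularised delta banded around the
// current boundary (so the contour evolves locally from the seed), and
// periodic reinitialisation that restores the far-field signed distance
// while preserving phi near the boundary -- slow front advances through
// weakly contrasted tissue are kept, not reset.  Convergence: the 0-level
// mask stops changing and the update has settled.  Returns the init mask
// if the result would be empty.
// [[Rcpp::export]]
IntegerMatrix cpp_chan_vese(NumericMatrix img, IntegerMatrix init,
                            double mu, double lambda1, double lambda2,
                            int max_iter, double dt, double eps) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix phi(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      phi(i, j) = init(i, j) ? 1.0 : -1.0;
  phi = signed_dist(phi);

  const double eta2 = 1.0;   // bounds mu/|grad phi| on plateaus
  IntegerMatrix mask(nr, nc), prev(nr, nc);
  int stable = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) prev(i, j) = init(i, j);

  for (int it = 0; it < max_iter; ++it) {
    if (it > 0 && it % 20 == 0) {
      NumericMatrix sd = signed_dist(phi);
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i)
          if (std::fabs(sd(i, j)) >= 1.5) phi(i, j) = sd(i, j);
    }
    // region means over current sign of phi
    double s1 = 0, s2 = 0; long n1 = 0, n2 = 0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        if (phi(i, j) >= 0) { s1 += img(i, j); ++n1; }
        else { s2 += img(i, j); ++n2; }
      }
    if (n1 == 0 || n2 == 0) break;
    const double c1 = s1 / n1, c2 = s2 / n2;

    double maxd = 0.0;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const double p = phi(i, j);
        const double pE = phi(i, j < nc - 1 ? j + 1 : j);
        const double pW = phi(i, j > 0 ? j - 1 : j);
        const double pS = phi(i < nr - 1 ? i + 1 : i, j);
        const double pN = phi(i > 0 ? i - 1 : i, j);
        const double A = mu / std::sqrt(eta2 + (pE - p) * (pE - p) +
                                        (pS - pN) * (pS - pN) / 4.0);
        const double B = mu / std::sqrt(eta2 + (pE - pW) * (pE - pW) / 4.0 +
                                        (pS - p) * (pS - p));
        const double AW = mu / std::sqrt(eta2 + (p - pW) * (p - pW) +
                                         (pS - pN) * (pS - pN) / 4.0);
        const double BN = mu / std::sqrt(eta2 + (pE - pW) * (pE - pW) / 4.0 +
                                         (p - pN) * (p - pN));
        const double del = eps > 0 ?
          eps / (M_PI * (eps * eps + p * p)) : 1.0;
        const double diff = img(i, j);
        const double force = -lambda1 * (diff - c1) * (diff - c1) +
                              lambda2 * (diff - c2) * (diff - c2);
        const double num = p + dt * del *
          (A * pE + AW * pW + B * pS + BN * pN + force);
        const double den = 1.0 + dt * del * (A + AW + B + BN);
        const double nv = num / den;
        if (std::fabs(nv - p) > maxd) maxd = std::fabs(nv - p);
        phi(i, j) = nv;
      }
    }

    int changed = 0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        mask(i, j) = phi(i, j) >= 0 ? 1 : 0;
        if (mask(i, j) != prev(i, j)) ++changed;
        prev(i, j) = mask(i, j);
      }
    // converged: boundary static and the update settled
    stable = changed == 0 ? stable + 1 : 0;
    if (stable >= 3 && maxd < 1e-4) break;
  }

  long fg = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) fg += mask(i, j);
  if (fg == 0) return init;
  return mask;
}

// Box-index pass test: an evaluated point passes when some reference voxel
// within the distance box holds a dose within tol_abs of it.
// [[Rcpp::export]]
List cpp_box_index(NumericVector ref, NumericVector eval,
                   NumericVector spacing, double tol_abs, double dist_mm,
                   LogicalVector eligible) {
  IntegerVector dm = ref.attr("dim");
  const int ny = dm[0], nx = dm[1], nz = dm[2];
  const int rx = (int)std::floor(dist_mm / spacing[0] + 1e-9);
  const int ry = (int)std::floor(dist_mm / spacing[1] + 1e-9);
  const int rz = (int)std::floor(dist_mm / spacing[2] + 1e-9);
  const double* R = REAL(ref);
  const double* E = REAL(eval);
  const int* el = LOGICAL(eligible);
  long n_eval = 0, n_pass = 0;
  const int sc = ny, ss = ny * nx;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        long idx = y + x * sc + z * ss;
        if (!el[idx]) continue;
        ++n_eval;
        double ev = E[idx];
        bool pass = false;
        for (int zz = z - rz; zz <= z + rz && !pass; ++zz) {
          if (zz < 0 || zz >= nz) continue;
          for (int xx = x - rx; xx <= x + rx && !pass; ++xx) {
            if (xx < 0 || xx >= nx) continue;
            for (int yy = y - ry; yy <= y + ry; ++yy) {
              if (yy < 0 || yy >= ny) continue;
              if (std::fabs(R[yy + xx * sc + zz * ss] - ev) <= tol_abs) {
                pass = true; break;
              }
            }
          }
        }
        if (pass) ++n_pass;
      }
  return List::create(_["n_eval"] = (double)n_eval,
                      _["n_pass"] = (double)n_pass);
}

// Bilinear sampling of a matrix at fractional (row, col) positions
// (0-based index units); positions outside the matrix return `fill`.
// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix m, NumericVector row,
                           NumericVector col, double fill) {
  const int nr = m.nrow(), nc = m.ncol(), n = row.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double r = row[k], c = col[k];
    if (r < 0 || c < 0 || r > nr - 1 || c > nc - 1) { out[k] = fill; continue; }
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    if (r0 >= nr - 1) r0 = nr - 2;
    if (r0 < 0) r0 = 0;
    if (c0 >= nc - 1) c0 = nc - 2;
    if (c0 < 0) c0 = 0;
    double fr = r - r0, fc = c - c0;
    if (nr == 1) { r0 = 0; fr = 0; }
    if (nc == 1) { c0 = 0; fc = 0; }
    int r1 = nr == 1 ? r0 : r0 + 1, c1 = nc == 1 ? c0 : c0 + 1;
    out[k] = m(r0, c0) * (1 - fr) * (1 - fc) + m(r1, c0) * fr * (1 - fc) +
             m(r0, c1) * (1 - fr) * fc + m(r1, c1) * fr * fc;
  }
  return out;
}
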
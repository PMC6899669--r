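// Ray-driven forward projection, voxel-driven back projection and their
// exact transposes for parallel-, fan- and cone-beam CT, plus primitive
// rasterization.  All kernels work in double precision on flattened
// column-major arrays.  Conventions (documented in the R help pages):
//   * world frame in mm, isocenter at the origin, circular orbit in z = 0;
//   * view angle b: central ray direction d = (-sin b, cos b), detector
//     axis u = (cos b, sin b); 3D adds v along +z;
//   * fan/cone source at -SID * d;
//   * detector coordinate of pixel i: s = (i - (n-1)/2)*spacing + offset;
//   * voxel i center at origin + i*spacing; samples outside any grid
//     contribute zero (zero-padding semantics).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// bilinear read with zero padding; exact grid points return the grid value
inline double sample2(const double* v, int nx, int ny, double fx, double fy) {
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy);
    double ax = fx - i0, ay = fy - j0, acc = 0.0;
    for (int dj = 0; dj < 2; ++dj) {
        int j = j0 + dj;
        if (j < 0 || j >= ny) continue;
        double wy = dj ? ay : 1.0 - ay;
        if (wy == 0.0) continue;
        for (int di = 0; di < 2; ++di) {
            int i = i0 + di;
            if (i < 0 || i >= nx) continue;
            double w = (di ? ax : 1.0 - ax) * wy;
            acc += w * v[i + (R_xlen_t)nx * j];
        }
    }
    return acc;
}

inline void splat2(double* v, int nx, int ny, double fx, double fy, double val) {
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy);
    double ax = fx - i0, ay = fy - j0;
    for (int dj = 0; dj < 2; ++dj) {
        int j = j0 + dj;
        if (j < 0 || j >= ny) continue;
        double wy = dj ? ay : 1.0 - ay;
        if (wy == 0.0) continue;
        for (int di = 0; di < 2; ++di) {
            int i = i0 + di;
            if (i < 0 || i >= nx) continue;
            v[i + (R_xlen_t)nx * j] += (di ? ax : 1.0 - ax) * wy * val;
        }
    }
}

inline double sample3(const double* v, int nx, int ny, int nz,
                      double fx, double fy, double fz) {
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
    double ax = fx - i0, ay = fy - j0, az = fz - k0, acc = 0.0;
    for (int dk = 0; dk < 2; ++dk) {
        int k = k0 + dk;
        if (k < 0 || k >= nz) continue;
        double wz = dk ? az : 1.0 - az;
        if (wz == 0.0) continue;
        for (int dj = 0; dj < 2; ++dj) {
            int j = j0 + dj;
            if (j < 0 || j >= ny) continue;
            double wyz = (dj ? ay : 1.0 - ay) * wz;
            if (wyz == 0.0) continue;
            for (int di = 0; di < 2; ++di) {
                int i = i0 + di;
                if (i < 0 || i >= nx) continue;
                acc += (di ? ax : 1.0 - ax) * wyz *
                       v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
            }
        }
    }
    return acc;
}

inline void splat3(double* v, int nx, int ny, int nz,
                   double fx, double fy, double fz, double val) {
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
    double ax = fx - i0, ay = fy - j0, az = fz - k0;
    for (int dk = 0; dk < 2; ++dk) {
        int k = k0 + dk;
        if (k < 0 || k >= nz) continue;
        double wz = dk ? az : 1.0 - az;
        if (wz == 0.0) continue;
        for (int dj = 0; dj < 2; ++dj) {
            int j = j0 + dj;
            if (j < 0 || j >= ny) continue;
            double wyz = (dj ? ay : 1.0 - ay) * wz;
            if (wyz == 0.0) continue;
            for (int di = 0; di < 2; ++di) {
                int i = i0 + di;
                if (i < 0 || i >= nx) continue;
                v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] +=
                    (di ? ax : 1.0 - ax) * wyz * val;
            }
        }
    }
}

// clip parametric ray o + t*dir against the slab [lo, hi]; false if empty
inline bool clip_axis(double o, double dir, double lo, double hi,
                      double& t0, double& t1) {
    if (std::fabs(dir) < 1e-12) return o >= lo && o <= hi;
    double ta = (lo - o) / dir, tb = (hi - o) / dir;
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
    return t0 < t1;
}

} // namespace

// Ray-march 2D projector (parallel: beam = 0, fan: beam = 1).
// transpose = false: gather vol -> sino;  true: scatter sino -> vol.
// The two modes traverse identical sample positions with identical weights,
// so the scatter mode is the exact transpose of the gather mode.
// [[Rcpp::export]]
void cpp_ray2d(NumericVector vol, IntegerVector vshape, NumericVector vspacing,
               NumericVector vorigin, NumericVector angles,
               int nd, double ds, double doff,
               int beam, double sid, double sdd, double step_mm,
               NumericMatrix sino, bool transpose) {
    const int nx = vshape[0], ny = vshape[1], n_views = angles.size();
    const double sx = vspacing[0], sy = vspacing[1];
    const double ox = vorigin[0], oy = vorigin[1];
    const double xlo = ox - 0.5 * sx, xhi = ox + (nx - 0.5) * sx;
    const double ylo = oy - 0.5 * sy, yhi = oy + (ny - 0.5) * sy;
    double* vp = vol.begin();
    const double c0 = 0.5 * (nd - 1);

    for (int v = 0; v < n_views; ++v) {
        const double cb = std::cos(angles[v]), sb = std::sin(angles[v]);
        const double dx0 = -sb, dy0 = cb;      // central ray direction
        const double ux = cb, uy = sb;         // detector axis
        for (int i = 0; i < nd; ++i) {
            const double s = (i - c0) * ds + doff;
            double px, py, dx, dy;
            if (beam == 0) {                   // parallel
                px = s * ux; py = s * uy; dx = dx0; dy = dy0;
            } else {                           // fan: source -> detector pixel
                px = sid * sb; py = -sid * cb;
                double qx = (sdd - sid) * dx0 + s * ux;
                double qy = (sdd - sid) * dy0 + s * uy;
                dx = qx - px; dy = qy - py;
                double nrm = std::sqrt(dx * dx + dy * dy);
                dx /= nrm; dy /= nrm;
            }
            double t0 = -1e30, t1 = 1e30;
            if (!clip_axis(px, dx, xlo, xhi, t0, t1)) continue;
            if (!clip_axis(py, dy, ylo, yhi, t0, t1)) continue;
            if (t1 <= t0) continue;
            const double len = t1 - t0;
            const int m = std::max(1, (int)std::ceil(len / step_mm));
            const double h = len / m;
            if (!transpose) {
                double acc = 0.0;
                for (int k = 0; k < m; ++k) {
                    const double t = t0 + (k + 0.5) * h;
                    acc += sample2(vp, nx, ny,
                                   (px + t * dx - ox) / sx,
                                   (py + t * dy - oy) / sy);
                }
                sino(v, i) += acc * h;
            } else {
                const double g = sino(v, i) * h;
                if (g == 0.0) continue;
                for (int k = 0; k < m; ++k) {
                    const double t = t0 + (k + 0.5) * h;
                    splat2(vp, nx, ny,
                           (px + t * dx - ox) / sx,
                           (py + t * dy - oy) / sy, g);
                }
            }
        }
    }
}

// Voxel-driven 2D back projector and its exact transpose.
// gather (transpose = false): sino -> vol, each voxel accumulates the
// linearly interpolated sinogram value at its detector coordinate, times
// dbeta and (optionally, fan) the FDK distance weight (SID/U_depth)^2.
// [[Rcpp::export]]
void cpp_backproject2d(NumericMatrix sino, NumericVector angles,
                       int nd, double ds, double doff,
                       int beam, double sid, double sdd,
                       NumericVector vol, IntegerVector vshape,
                       NumericVector vspacing, NumericVector vorigin,
                       bool weighted, double dbeta, bool transpose) {
    const int nx = vshape[0], ny = vshape[1], n_views = angles.size();
    const double sx = vspacing[0], sy = vspacing[1];
    const double ox = vorigin[0], oy = vorigin[1];
    const double c0 = 0.5 * (nd - 1);
    double* vp = vol.begin();

    for (int v = 0; v < n_views; ++v) {
        const double cb = std::cos(angles[v]), sb = std::sin(angles[v]);
        const double dx0 = -sb, dy0 = cb, ux = cb, uy = sb;
        for (int iy = 0; iy < ny; ++iy) {
            const double Y = oy + iy * sy;
            for (int ix = 0; ix < nx; ++ix) {
                const double X = ox + ix * sx;
                double c, w = 1.0;
                if (beam == 0) {
                    c = (X * ux + Y * uy - doff) / ds + c0;
                } else {
                    const double zc = sid + X * dx0 + Y * dy0; // depth along principal ray
                    if (zc < 1e-9) continue;
                    const double uphys = sdd * (X * ux + Y * uy) / zc;
                    c = (uphys - doff) / ds + c0;
                    if (weighted) { const double U = zc / sid; w = 1.0 / (U * U); }
                }
                const int i0 = (int)std::floor(c);
                const double a = c - i0;
                const R_xlen_t vi = ix + (R_xlen_t)nx * iy;
                if (!transpose) {
                    double val = 0.0;
                    if (i0 >= 0 && i0 < nd && (1.0 - a) > 0.0) val += (1.0 - a) * sino(v, i0);
                    if (i0 + 1 >= 0 && i0 + 1 < nd && a > 0.0) val += a * sino(v, i0 + 1);
                    vp[vi] += dbeta * w * val;
                } else {
                    const double g = dbeta * w * vp[vi];
                    if (g == 0.0) continue;
                    if (i0 >= 0 && i0 < nd && (1.0 - a) > 0.0) sino(v, i0) += (1.0 - a) * g;
                    if (i0 + 1 >= 0 && i0 + 1 < nd && a > 0.0) sino(v, i0 + 1) += a * g;
                }
            }
        }
    }
}

// Ray-march cone-beam projector driven by projection matrices.
// srcs: n_views x 3 camera centers; minvs: n_views x 9 row-major inverses of
// the 3x3 left blocks. Ray for pixel (i,j): dir = M^-1 (i, j, 1)^T from the
// source. proj is a flattened (n_views, nu, nv) array.
// [[Rcpp::export]]
void cpp_raycone(NumericVector vol, IntegerVector vshape, NumericVector vspacing,
                 NumericVector vorigin, NumericMatrix srcs, NumericMatrix minvs,
                 int nu, int nv, NumericVector proj, double step_mm,
                 bool transpose) {
    const int nx = vshape[0], ny = vshape[1], nz = vshape[2];
    const int n_views = srcs.nrow();
    const double sx = vspacing[0], sy = vspacing[1], sz = vspacing[2];
    const double ox = vorigin[0], oy = vorigin[1], oz = vorigin[2];
    const double xlo = ox - 0.5 * sx, xhi = ox + (nx - 0.5) * sx;
    const double ylo = oy - 0.5 * sy, yhi = oy + (ny - 0.5) * sy;
    const double zlo = oz - 0.5 * sz, zhi = oz + (nz - 0.5) * sz;
    double* vp = vol.begin();
    double* pp = proj.begin();

    for (int v = 0; v < n_views; ++v) {
        const double cx = srcs(v, 0), cy = srcs(v, 1), cz = srcs(v, 2);
        double M[9];
        for (int k = 0; k < 9; ++k) M[k] = minvs(v, k);
        for (int j = 0; j < nv; ++j) {
            for (int i = 0; i < nu; ++i) {
                double dx = M[0] * i + M[1] * j + M[2];
                double dy = M[3] * i + M[4] * j + M[5];
                double dz = M[6] * i + M[7] * j + M[8];
                const double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
                dx /= nrm; dy /= nrm; dz /= nrm;
                double t0 = -1e30, t1 = 1e30;
                if (!clip_axis(cx, dx, xlo, xhi, t0, t1)) continue;
                if (!clip_axis(cy, dy, ylo, yhi, t0, t1)) continue;
                if (!clip_axis(cz, dz, zlo, zhi, t0, t1)) continue;
                if (t1 <= t0) continue;
                const double len = t1 - t0;
                const int m = std::max(1, (int)std::ceil(len / step_mm));
                const double h = len / m;
                const R_xlen_t pi = v + (R_xlen_t)n_views * (i + (R_xlen_t)nu * j);
                if (!transpose) {
                    double acc = 0.0;
                    for (int k = 0; k < m; ++k) {
                        const double t = t0 + (k + 0.5) * h;
                        acc += sample3(vp, nx, ny, nz,
                                       (cx + t * dx - ox) / sx,
                                       (cy + t * dy - oy) / sy,
                                       (cz + t * dz - oz) / sz);
                    }
                    pp[pi] += acc * h;
                } else {
                    const double g = pp[pi] * h;
                    if (g == 0.0) continue;
                    for (int k = 0; k < m; ++k) {
                        const double t = t0 + (k + 0.5) * h;
                        splat3(vp, nx, ny, nz,
                               (cx + t * dx - ox) / sx,
                               (cy + t * dy - oy) / sy,
                               (cz + t * dz - oz) / sz, g);
                    }
                }
            }
        }
    }
}

// Voxel-driven cone back projector via 3x4 projection matrices (and exact
// transpose).  pmats: n_views x 12, row-major.  weighted: multiply by the
// FDK distance weight (SID/w)^2 where w is the homogeneous depth in mm
// (true for matrices built by cone_projection_matrices; calibrated matrices
// must be normalized the same way).
// [[Rcpp::export]]
void cpp_backcone(NumericVector proj, NumericMatrix pmats, int nu, int nv,
                  NumericVector vol, IntegerVector vshape, NumericVector vspacing,
                  NumericVector vorigin, bool weighted, double sid, double dbeta,
                  bool transpose) {
    const int nx = vshape[0], ny = vshape[1], nz = vshape[2];
    const int n_views = pmats.nrow();
    const double sx = vspacing[0], sy = vspacing[1], sz = vspacing[2];
    const double ox = vorigin[0], oy = vorigin[1], oz = vorigin[2];
    double* vp = vol.begin();
    double* pp = proj.begin();

    for (int v = 0; v < n_views; ++v) {
        double P[12];
        for (int k = 0; k < 12; ++k) P[k] = pmats(v, k);
        for (int iz = 0; iz < nz; ++iz) {
            const double Z = oz + iz * sz;
            for (int iy = 0; iy < ny; ++iy) {
                const double Y = oy + iy * sy;
                for (int ix = 0; ix < nx; ++ix) {
                    const double X = ox + ix * sx;
                    const double w = P[8] * X + P[9] * Y + P[10] * Z + P[11];
                    if (w < 1e-9) continue;
                    const double u = (P[0] * X + P[1] * Y + P[2] * Z + P[3]) / w;
                    const double q = (P[4] * X + P[5] * Y + P[6] * Z + P[7]) / w;
                    double wt = dbeta;
                    if (weighted) { const double U = w / sid; wt /= (U * U); }
                    const R_xlen_t vi =
                        ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
                    // bilinear on the (nu, nv) image of view v,
                    // flattened as view + n_views*(i + nu*j)
                    int i0 = (int)std::floor(u), j0 = (int)std::floor(q);
                    double au = u - i0, aq = q - j0;
                    if (!transpose) {
                        double val = 0.0;
                        for (int djj = 0; djj < 2; ++djj) {
                            int jj = j0 + djj;
                            if (jj < 0 || jj >= nv) continue;
                            double wj = djj ? aq : 1.0 - aq;
                            if (wj == 0.0) continue;
                            for (int dii = 0; dii < 2; ++dii) {
                                int ii = i0 + dii;
                                if (ii < 0 || ii >= nu) continue;
                                val += (dii ? au : 1.0 - au) * wj *
                                    pp[v + (R_xlen_t)n_views * (ii + (R_xlen_t)nu * jj)];
                            }
                        }
                        vp[vi] += wt * val;
                    } else {
                        const double g = wt * vp[vi];
                        if (g == 0.0) continue;
                        for (int djj = 0; djj < 2; ++djj) {
                            int jj = j0 + djj;
                            if (jj < 0 || jj >= nv) continue;
                            double wj = djj ? aq : 1.0 - aq;
                            if (wj == 0.0) continue;
                            for (int dii = 0; dii < 2; ++dii) {
                                int ii = i0 + dii;
                                if (ii < 0 || ii >= nu) continue;
                                pp[v + (R_xlen_t)n_views * (ii + (R_xlen_t)nu * jj)] +=
                                    (dii ? au : 1.0 - au) * wj * g;
                            }
                        }
                    }
                }
            }
        }
    }
}

// Rasterize additive primitives on a 2D/3D grid with supersampling.
// prims rows: type (0 = ellipse/ellipsoid rotated about z, 1 = axis-aligned
// box), cx, cy, cz, ax, ay, az, phi, value.
// [[Rcpp::export]]
NumericVector cpp_rasterize(NumericMatrix prims, IntegerVector shape,
                            NumericVector spacing, NumericVector origin,
                            int ss, int ndim) {
    const int nx = shape[0], ny = shape[1], nz = (ndim == 3) ? shape[2] : 1;
    const double sx = spacing[0], sy = spacing[1],
                 sz = (ndim == 3) ? spacing[2] : 1.0;
    const double ox = origin[0], oy = origin[1],
                 oz = (ndim == 3) ? origin[2] : 0.0;
    const int np = prims.nrow();
    NumericVector out((R_xlen_t)nx * ny * nz);
    double* op = out.begin();

    std::vector<double> offs(ss);
    for (int k = 0; k < ss; ++k) offs[k] = (k + 0.5) / ss - 0.5;
    const int ssz = (ndim == 3) ? ss : 1;
    const double frac = 1.0 / ((double)ss * ss * ssz);

    for (int p = 0; p < np; ++p) {
        const int type = (int)prims(p, 0);
        const double cx = prims(p, 1), cy = prims(p, 2), cz = prims(p, 3);
        const double ax = prims(p, 4), ay = prims(p, 5), az = prims(p, 6);
        const double phi = prims(p, 7), val = prims(p, 8);
        const double cph = std::cos(phi), sph = std::sin(phi);
        for (int iz = 0; iz < nz; ++iz) {
            for (int iy = 0; iy < ny; ++iy) {
                for (int ix = 0; ix < nx; ++ix) {
                    double hit = 0.0;
                    for (int kz = 0; kz < ssz; ++kz) {
                        const double z = (ndim == 3)
                            ? oz + (iz + offs[kz]) * sz - cz : 0.0;
                        for (int ky = 0; ky < ss; ++ky) {
                            const double y = oy + (iy + offs[ky]) * sy - cy;
                            for (int kx = 0; kx < ss; ++kx) {
                                const double x = ox + (ix + offs[kx]) * sx - cx;
                                bool inside;
                                if (type == 0) {
                                    // rotate by -phi about z
                                    const double qx = cph * x + sph * y;
                                    const double qy = -sph * x + cph * y;
                                    double r = (qx / ax) * (qx / ax) +
                                               (qy / ay) * (qy / ay);
                                    if (ndim == 3) r += (z / az) * (z / az);
                                    inside = r <= 1.0;
                                } else {
                                    inside = std::fabs(x) <= ax &&
                                             std::fabs(y) <= ay &&
                                             (ndim == 2 || std::fabs(z) <= az);
                                }
                                if (inside) hit += 1.0;
                            }
                        }
                    }
                    if (hit > 0.0)
                        op[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] +=
                            val * hit * frac;
                }
            }
        }
    }
    return out;
}
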
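// Geometry kernels: closest-point queries against triangle meshes and point
// clouds, farthest-point subsampling, an implicit moving-least-squares (IMLS)
// signed field over oriented points with a narrow-band marching-tetrahedra
// isosurfacer, and the mean per-particle distance matrix used by specificity.
#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <limits>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 vadd(const Vec3 &a, const Vec3 &b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 vscale(const Vec3 &a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double vnorm2(const Vec3 &a) { return vdot(a, a); }

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p.
Vec3 closestPtTriangle(const Vec3 &p, const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return vadd(a, vscale(ab, v));
  }
  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return vadd(a, vscale(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(b, vscale(vsub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
}

struct TriGrid {
  double ox, oy, oz, cell;
  int nx, ny, nz;
  std::vector<int> cellStart;     // CSR offsets, size nx*ny*nz+1
  std::vector<int> cellTris;      // triangle ids
  std::vector<double> tri;        // 9 doubles per triangle (a, b, c)

  inline int clampi(int v, int lo, int hi) const { return v < lo ? lo : (v > hi ? hi : v); }
  inline int cidx(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }

  void build(const NumericMatrix &Vm, const IntegerMatrix &Fm) {
    int nv = Vm.nrow(), nf = Fm.nrow();
    tri.resize((size_t)nf * 9);
    for (int t = 0; t < nf; ++t)
      for (int k = 0; k < 3; ++k)
        for (int d = 0; d < 3; ++d)
          tri[(size_t)t * 9 + k * 3 + d] = Vm(Fm(t, k), d);
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < nv; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = Vm(i, d);
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
    // aim for ~2 triangles per occupied cell on a 2-manifold
    double target = ext / std::max(4.0, std::min(96.0, std::sqrt((double)nf / 2.0)));
    cell = std::max(target, 1e-6);
    ox = lo[0] - 0.5 * cell; oy = lo[1] - 0.5 * cell; oz = lo[2] - 0.5 * cell;
    nx = (int)std::floor((hi[0] - ox) / cell) + 2;
    ny = (int)std::floor((hi[1] - oy) / cell) + 2;
    nz = (int)std::floor((hi[2] - oz) / cell) + 2;
    std::vector<int> count((size_t)nx * ny * nz, 0);
    std::vector<int> lox(nf), loy(nf), loz(nf), hix(nf), hiy(nf), hiz(nf);
    for (int t = 0; t < nf; ++t) {
      double bx0 = R_PosInf, by0 = R_PosInf, bz0 = R_PosInf;
      double bx1 = R_NegInf, by1 = R_NegInf, bz1 = R_NegInf;
      for (int k = 0; k < 3; ++k) {
        int vi = Fm(t, k);
        double x = Vm(vi, 0), y = Vm(vi, 1), z = Vm(vi, 2);
        bx0 = std::min(bx0, x); by0 = std::min(by0, y); bz0 = std::min(bz0, z);
        bx1 = std::max(bx1, x); by1 = std::max(by1, y); bz1 = std::max(bz1, z);
      }
      lox[t] = clampi((int)((bx0 - ox) / cell), 0, nx - 1);
      loy[t] = clampi((int)((by0 - oy) / cell), 0, ny - 1);
      loz[t] = clampi((int)((bz0 - oz) / cell), 0, nz - 1);
      hix[t] = clampi((int)((bx1 - ox) / cell), 0, nx - 1);
      hiy[t] = clampi((int)((by1 - oy) / cell), 0, ny - 1);
      hiz[t] = clampi((int)((bz1 - oz) / cell), 0, nz - 1);
      for (int iz = loz[t]; iz <= hiz[t]; ++iz)
        for (int iy = loy[t]; iy <= hiy[t]; ++iy)
          for (int ix = lox[t]; ix <= hix[t]; ++ix) count[cidx(ix, iy, iz)]++;
    }
    cellStart.assign(count.size() + 1, 0);
    for (size_t i = 0; i < count.size(); ++i) cellStart[i + 1] = cellStart[i] + count[i];
    cellTris.resize(cellStart.back());
    std::vector<int> cursor(cellStart.begin(), cellStart.end() - 1);
    for (int t = 0; t < nf; ++t)
      for (int iz = loz[t]; iz <= hiz[t]; ++iz)
        for (int iy = loy[t]; iy <= hiy[t]; ++iy)
          for (int ix = lox[t]; ix <= hix[t]; ++ix) cellTris[cursor[cidx(ix, iy, iz)]++] = t;
  }

  void query(const Vec3 &p, Vec3 &best, double &bestD, int &bestT) const {
    bestD = R_PosInf; bestT = -1;
    int px = clampi((int)((p.x - ox) / cell), 0, nx - 1);
    int py = clampi((int)((p.y - oy) / cell), 0, ny - 1);
    int pz = clampi((int)((p.z - oz) / cell), 0, nz - 1);
    int maxShell = std::max({nx, ny, nz});
    for (int s = 0; s <= maxShell; ++s) {
      // once the closest possible point in this shell is farther than best, stop
      if (bestT >= 0 && bestD <= (double)(s - 1) * cell) break;
      int x0 = px - s, x1 = px + s, y0 = py - s, y1 = py + s, z0 = pz - s, z1 = pz + s;
      for (int iz = std::max(z0, 0); iz <= std::min(z1, nz - 1); ++iz)
        for (int iy = std::max(y0, 0); iy <= std::min(y1, ny - 1); ++iy)
          for (int ix = std::max(x0, 0); ix <= std::min(x1, nx - 1); ++ix) {
            bool onShell = (ix == x0 || ix == x1 || iy == y0 || iy == y1 || iz == z0 || iz == z1);
            if (!onShell) continue;
            int ci = cidx(ix, iy, iz);
            for (int k = cellStart[ci]; k < cellStart[ci + 1]; ++k) {
              int t = cellTris[k];
              const double *T = &tri[(size_t)t * 9];
              Vec3 a = {T[0], T[1], T[2]};
              Vec3 b = {T[3], T[4], T[5]};
              Vec3 c = {T[6], T[7], T[8]};
              Vec3 q = closestPtTriangle(p, a, b, c);
              double d2 = vnorm2(vsub(p, q));
              if (d2 < bestD * bestD || bestT < 0) {
                double d = std::sqrt(d2);
                if (d < bestD) { bestD = d; best = q; bestT = t; }
              }
            }
          }
    }
  }
};

struct PointGrid {
  double ox, oy, oz, cell;
  int nx, ny, nz;
  std::vector<int> cellStart;
  std::vector<int> cellPts;
  std::vector<double> pts;   // 3 doubles per point

  inline int clampi(int v, int lo, int hi) const { return v < lo ? lo : (v > hi ? hi : v); }
  inline int cidx(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }

  inline Vec3 pt(int i) const {
    return {pts[(size_t)i * 3], pts[(size_t)i * 3 + 1], pts[(size_t)i * 3 + 2]};
  }

  void build(const NumericMatrix &Pm, double cellSize) {
    int n = Pm.nrow();
    pts.resize((size_t)n * 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) pts[(size_t)i * 3 + d] = Pm(i, d);
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = Pm(i, d);
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    cell = std::max(cellSize, 1e-9);
    ox = lo[0] - 0.5 * cell; oy = lo[1] - 0.5 * cell; oz = lo[2] - 0.5 * cell;
    nx = (int)std::floor((hi[0] - ox) / cell) + 2;
    ny = (int)std::floor((hi[1] - oy) / cell) + 2;
    nz = (int)std::floor((hi[2] - oz) / cell) + 2;
    std::vector<int> count((size_t)nx * ny * nz, 0);
    std::vector<int> ci(n);
    for (int i = 0; i < n; ++i) {
      int ix = clampi((int)((Pm(i, 0) - ox) / cell), 0, nx - 1);
      int iy = clampi((int)((Pm(i, 1) - oy) / cell), 0, ny - 1);
      int iz = clampi((int)((Pm(i, 2) - oz) / cell), 0, nz - 1);
      ci[i] = cidx(ix, iy, iz);
      count[ci[i]]++;
    }
    cellStart.assign(count.size() + 1, 0);
    for (size_t i = 0; i < count.size(); ++i) cellStart[i + 1] = cellStart[i] + count[i];
    cellPts.resize(n);
    std::vector<int> cursor(cellStart.begin(), cellStart.end() - 1);
    for (int i = 0; i < n; ++i) cellPts[cursor[ci[i]]++] = i;
  }

  int nearest(const Vec3 &p, double &bestD) const {
    bestD = R_PosInf;
    int bestI = -1;
    int px = clampi((int)((p.x - ox) / cell), 0, nx - 1);
    int py = clampi((int)((p.y - oy) / cell), 0, ny - 1);
    int pz = clampi((int)((p.z - oz) / cell), 0, nz - 1);
    int maxShell = std::max({nx, ny, nz});
    for (int s = 0; s <= maxShell; ++s) {
      if (bestI >= 0 && bestD <= (double)(s - 1) * cell) break;
      int x0 = px - s, x1 = px + s, y0 = py - s, y1 = py + s, z0 = pz - s, z1 = pz + s;
      for (int iz = std::max(z0, 0); iz <= std::min(z1, nz - 1); ++iz)
        for (int iy = std::max(y0, 0); iy <= std::min(y1, ny - 1); ++iy)
          for (int ix = std::max(x0, 0); ix <= std::min(x1, nx - 1); ++ix) {
            bool onShell = (ix == x0 || ix == x1 || iy == y0 || iy == y1 || iz == z0 || iz == z1);
            if (!onShell) continue;
            int c = cidx(ix, iy, iz);
            for (int k = cellStart[c]; k < cellStart[c + 1]; ++k) {
              int i = cellPts[k];
              double d = std::sqrt(vnorm2(vsub(p, pt(i))));
              if (d < bestD) { bestD = d; bestI = i; }
            }
          }
    }
    return bestI;
  }

  template <typename Fn>
  void forNeighbors(const Vec3 &p, double radius, Fn fn) const {
    int r = (int)std::ceil(radius / cell);
    int px = clampi((int)((p.x - ox) / cell), 0, nx - 1);
    int py = clampi((int)((p.y - oy) / cell), 0, ny - 1);
    int pz = clampi((int)((p.z - oz) / cell), 0, nz - 1);
    double r2 = radius * radius;
    for (int iz = std::max(pz - r, 0); iz <= std::min(pz + r, nz - 1); ++iz)
      for (int iy = std::max(py - r, 0); iy <= std::min(py + r, ny - 1); ++iy)
        for (int ix = std::max(px - r, 0); ix <= std::min(px + r, nx - 1); ++ix) {
          int c = cidx(ix, iy, iz);
          for (int k = cellStart[c]; k < cellStart[c + 1]; ++k) {
            int i = cellPts[k];
            double d2 = vnorm2(vsub(p, pt(i)));
            if (d2 <= r2) fn(i, d2);
          }
        }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_closest_point_mesh(const NumericMatrix &P, const NumericMatrix &V, const IntegerMatrix &F) {
  TriGrid grid;
  grid.build(V, F);
  int n = P.nrow();
  NumericMatrix out(n, 3);
  NumericVector dist(n), sgn(n);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p = {P(i, 0), P(i, 1), P(i, 2)}, best;
    double d; int t;
    grid.query(p, best, d, t);
    out(i, 0) = best.x; out(i, 1) = best.y; out(i, 2) = best.z;
    dist[i] = d; face[i] = t + 1;
    Vec3 a = {V(F(t, 0), 0), V(F(t, 0), 1), V(F(t, 0), 2)};
    Vec3 b = {V(F(t, 1), 0), V(F(t, 1), 1), V(F(t, 1), 2)};
    Vec3 c = {V(F(t, 2), 0), V(F(t, 2), 1), V(F(t, 2), 2)};
    Vec3 nrm = vcross(vsub(b, a), vsub(c, a));
    sgn[i] = (vdot(nrm, vsub(p, best)) >= 0.0) ? 1.0 : -1.0;
  }
  return List::create(_["point"] = out, _["dist"] = dist, _["face"] = face, _["sign"] = sgn);
}

// [[Rcpp::export]]
List cpp_nn_points(const NumericMatrix &Q, const NumericMatrix &P, double cellHint,
                   bool skip_self = false) {
  PointGrid grid;
  grid.build(P, cellHint);
  int n = Q.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    Vec3 q = {Q(i, 0), Q(i, 1), Q(i, 2)};
    double d;
    int best = -1;
    if (!skip_self) {
      best = grid.nearest(q, d);
    } else {
      // nearest strictly positive-distance neighbour (spacing estimation)
      d = R_PosInf;
      double searchR = grid.cell;
      while (best < 0 && searchR < 1e9) {
        grid.forNeighbors(q, searchR, [&](int j, double d2) {
          if (d2 > 1e-24 && d2 < d * d) { d = std::sqrt(d2); best = j; }
        });
        searchR *= 2.0;
      }
    }
    idx[i] = best + 1;
    dist[i] = d;
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Farthest-point subsampling; deterministic given the start index (1-based).
// [[Rcpp::export]]
IntegerVector cpp_farthest_point_sampling(const NumericMatrix &P, int k, int start) {
  int n = P.nrow();
  if (k > n) stop("k exceeds number of points");
  std::vector<double> minD((size_t)n, R_PosInf);
  IntegerVector sel(k);
  int cur = start - 1;
  for (int j = 0; j < k; ++j) {
    sel[j] = cur + 1;
    Vec3 c = {P(cur, 0), P(cur, 1), P(cur, 2)};
    double bestD = -1.0;
    int bestI = 0;
    for (int i = 0; i < n; ++i) {
      Vec3 p = {P(i, 0), P(i, 1), P(i, 2)};
      double d = vnorm2(vsub(p, c));
      if (d < minD[i]) minD[i] = d;
      if (minD[i] > bestD) { bestD = minD[i]; bestI = i; }
    }
    cur = bestI;
  }
  return sel;
}

// Mean per-particle Euclidean distance between every row of Y and every row of
// X, both (n x 3K) flattened particle sets: D[a, i] = mean_k |y_ak - x_ik|.
// [[Rcpp::export]]
NumericMatrix cpp_mean_particle_dist(const NumericMatrix &Y, const NumericMatrix &X, int K) {
  int M = Y.nrow(), n = X.nrow(), cols = Y.ncol();
  if (cols != X.ncol() || cols != 3 * K) stop("dimension mismatch");
  NumericMatrix D(M, n);
  for (int a = 0; a < M; ++a)
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        double dx = Y(a, 3 * k) - X(i, 3 * k);
        double dy = Y(a, 3 * k + 1) - X(i, 3 * k + 1);
        double dz = Y(a, 3 * k + 2) - X(i, 3 * k + 2);
        acc += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      D(a, i) = acc / (double)K;
    }
  return D;
}

namespace {

// IMLS signed field at x: Gaussian-weighted average of point-plane offsets.
struct IMLSField {
  std::vector<double> nrm;   // 3 doubles per point
  PointGrid grid;
  double hs, rcut;

  void setNormals(const NumericMatrix &Nm) {
    int n = Nm.nrow();
    nrm.resize((size_t)n * 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) nrm[(size_t)i * 3 + d] = Nm(i, d);
  }

  // algebraic-sphere field (APSS, Guennebaud & Gross): fit the weighted
  // algebraic sphere u0 + u.p + u4 |p|^2 constrained by the sample normals,
  // and return the normalised field value at x. Averaging positions and
  // normals suppresses the tilt noise of detailed surfaces, and the sphere
  // term removes the curvature bias a plane fit suffers at tips and bends.
  double eval(const Vec3 &x) const {
    double sw = 0.0, spn = 0.0, spp = 0.0;
    Vec3 sp = {0, 0, 0}, sn = {0, 0, 0};
    double inv_h2 = 1.0 / (hs * hs);
    grid.forNeighbors(x, rcut, [&](int i, double d2) {
      double w = std::exp(-d2 * inv_h2);
      Vec3 pi = grid.pt(i);
      Vec3 ni = {nrm[(size_t)i * 3], nrm[(size_t)i * 3 + 1], nrm[(size_t)i * 3 + 2]};
      sp = vadd(sp, vscale(pi, w));
      sn = vadd(sn, vscale(ni, w));
      spn += w * vdot(pi, ni);
      spp += w * vnorm2(pi);
      sw += w;
    });
    if (sw > 1e-300 && vnorm2(sn) > 1e-12 * sw * sw) {
      Vec3 pbar = vscale(sp, 1.0 / sw);
      Vec3 nbar = vscale(sn, 1.0 / sw);
      double pnbar = spn / sw, ppbar = spp / sw;
      double denom = ppbar - vnorm2(pbar);
      double u4 = 0.0;
      if (denom > 1e-9 * hs * hs)
        u4 = 0.5 * (pnbar - vdot(pbar, nbar)) / denom;
      // keep the sphere radius bounded away from zero for stability
      double u4max = 0.5 / hs;
      if (u4 > u4max) u4 = u4max;
      if (u4 < -u4max) u4 = -u4max;
      Vec3 u123 = vsub(nbar, vscale(pbar, 2.0 * u4));
      double u0 = -vdot(pbar, u123) - u4 * ppbar;
      double fval = u0 + vdot(u123, x) + u4 * vnorm2(x);
      Vec3 gradv = vadd(u123, vscale(x, 2.0 * u4));
      double gl = std::sqrt(vnorm2(gradv));
      if (gl > 1e-12) return fval / gl;
    }
    double d;
    int i = grid.nearest(x, d);
    Vec3 ni = {nrm[(size_t)i * 3], nrm[(size_t)i * 3 + 1], nrm[(size_t)i * 3 + 2]};
    return vdot(ni, vsub(x, grid.pt(i)));
  }
};

struct MTMesh {
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  std::unordered_map<uint64_t, int> edgeVert;
};

}  // namespace

// Narrow-band marching-tetrahedra isosurface of the IMLS field of an oriented
// point set. voxel = cube edge length; hs = Gaussian support; band = dilation
// radius around occupied point cubes, in cube units.
// [[Rcpp::export]]
List cpp_imls_reconstruct(const NumericMatrix &P, const NumericMatrix &N,
                          double voxel, double hs, int band) {
  int np = P.nrow();
  if (np < 4) stop("too few points for reconstruction");
  IMLSField field;
  field.setNormals(N);
  field.hs = hs; field.rcut = 2.2 * hs;
  field.grid.build(P, std::max(hs, voxel));

  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < np; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = P(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double pad = (band + 2) * voxel;
  double ox = lo[0] - pad, oy = lo[1] - pad, oz = lo[2] - pad;
  int nx = (int)std::ceil((hi[0] + pad - ox) / voxel) + 1;
  int ny = (int)std::ceil((hi[1] + pad - oy) / voxel) + 1;
  int nz = (int)std::ceil((hi[2] + pad - oz) / voxel) + 1;
  size_t ncubes = (size_t)nx * ny * nz;
  if (ncubes > (size_t)6e8) stop("reconstruction grid too large");

  // occupancy + separable dilation by `band` cubes
  std::vector<uint8_t> occ(ncubes, 0);
  auto C = [&](int ix, int iy, int iz) -> size_t { return ((size_t)iz * ny + iy) * nx + ix; };
  for (int i = 0; i < np; ++i) {
    int ix = (int)((P(i, 0) - ox) / voxel), iy = (int)((P(i, 1) - oy) / voxel), iz = (int)((P(i, 2) - oz) / voxel);
    if (ix >= 0 && iy >= 0 && iz >= 0 && ix < nx && iy < ny && iz < nz) occ[C(ix, iy, iz)] = 1;
  }
  {
    std::vector<uint8_t> tmp(ncubes, 0);
    // x pass
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          uint8_t v = 0;
          for (int d = -band; d <= band; ++d) {
            int j = ix + d;
            if (j >= 0 && j < nx && occ[C(j, iy, iz)]) { v = 1; break; }
          }
          tmp[C(ix, iy, iz)] = v;
        }
    // y pass
    for (int iz = 0; iz < nz; ++iz)
      for (int ix = 0; ix < nx; ++ix)
        for (int iy = 0; iy < ny; ++iy) {
          uint8_t v = 0;
          for (int d = -band; d <= band; ++d) {
            int j = iy + d;
            if (j >= 0 && j < ny && tmp[C(ix, j, iz)]) { v = 1; break; }
          }
          occ[C(ix, iy, iz)] = v;
        }
    // z pass
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix)
        for (int iz = 0; iz < nz; ++iz) {
          uint8_t v = 0;
          for (int d = -band; d <= band; ++d) {
            int j = iz + d;
            if (j >= 0 && j < nz && occ[C(ix, iy, j)]) { v = 1; break; }
          }
          tmp[C(ix, iy, iz)] = v;
        }
    occ.swap(tmp);
  }

  // lazily evaluated corner field
  int cx = nx + 1, cy = ny + 1;
  std::unordered_map<uint64_t, double> cornerVal;
  cornerVal.reserve(1 << 18);
  auto cornerId = [&](int ix, int iy, int iz) -> uint64_t {
    return ((uint64_t)iz * cy + iy) * (uint64_t)cx + ix;
  };
  auto cornerF = [&](int ix, int iy, int iz) -> double {
    uint64_t id = cornerId(ix, iy, iz);
    auto it = cornerVal.find(id);
    if (it != cornerVal.end()) return it->second;
    Vec3 x = {ox + ix * voxel, oy + iy * voxel, oz + iz * voxel};
    double f = field.eval(x);
    if (std::fabs(f) < 1e-12) f = 1e-12;  // never exactly on the isosurface
    cornerVal.emplace(id, f);
    return f;
  };

  // 6-tet decomposition of a cube along the 0-6 diagonal; cube corners in
  // (x,y,z)-bit order: 0:(0,0,0) 1:(1,0,0) 2:(1,1,0) 3:(0,1,0) 4:(0,0,1)
  // 5:(1,0,1) 6:(1,1,1) 7:(0,1,1)
  static const int tets[6][4] = {
      {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  static const int cdx[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  static const int cdy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int cdz[8] = {0, 0, 0, 0, 1, 1, 1, 1};

  MTMesh mesh;
  auto edgePoint = [&](uint64_t idA, uint64_t idB, const Vec3 &pa, const Vec3 &pb,
                       double fa, double fb) -> int {
    uint64_t lo_ = std::min(idA, idB), hi_ = std::max(idA, idB);
    // ids fit in well under 2^32 for admissible grids
    uint64_t key = (lo_ << 32) | hi_;
    auto it = mesh.edgeVert.find(key);
    if (it != mesh.edgeVert.end()) return it->second;
    double t = fa / (fa - fb);
    t = std::min(std::max(t, 0.0), 1.0);
    int vi = (int)mesh.vx.size();
    mesh.vx.push_back(pa.x + t * (pb.x - pa.x));
    mesh.vy.push_back(pa.y + t * (pb.y - pa.y));
    mesh.vz.push_back(pa.z + t * (pb.z - pa.z));
    mesh.edgeVert.emplace(key, vi);
    return vi;
  };

  auto emitTri = [&](int a, int b, int c, const Vec3 &grad) {
    if (a == b || b == c || a == c) return;
    Vec3 pa = {mesh.vx[a], mesh.vy[a], mesh.vz[a]};
    Vec3 pb = {mesh.vx[b], mesh.vy[b], mesh.vz[b]};
    Vec3 pc = {mesh.vx[c], mesh.vy[c], mesh.vz[c]};
    Vec3 nrm = vcross(vsub(pb, pa), vsub(pc, pa));
    if (vnorm2(nrm) < 1e-30) return;
    // orient faces so normals point toward increasing field (outside)
    if (vdot(nrm, grad) >= 0) { mesh.fa.push_back(a); mesh.fb.push_back(b); mesh.fc.push_back(c); }
    else                      { mesh.fa.push_back(a); mesh.fb.push_back(c); mesh.fc.push_back(b); }
  };

  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        if (!occ[C(ix, iy, iz)]) continue;
        double f[8];
        Vec3 pc_[8];
        uint64_t cid[8];
        bool anyNeg = false, anyPos = false;
        for (int k = 0; k < 8; ++k) {
          int jx = ix + cdx[k], jy = iy + cdy[k], jz = iz + cdz[k];
          f[k] = cornerF(jx, jy, jz);
          pc_[k] = {ox + jx * voxel, oy + jy * voxel, oz + jz * voxel};
          cid[k] = cornerId(jx, jy, jz);
          (f[k] < 0 ? anyNeg : anyPos) = true;
        }
        if (!anyNeg || !anyPos) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int inIdx[4], outIdx[4], nin = 0, nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (f[tv[k]] < 0) inIdx[nin++] = tv[k];
            else outIdx[nout++] = tv[k];
          }
          if (nin == 0 || nin == 4) continue;
          // constant gradient of the linear interpolant over the tet
          Vec3 e1 = vsub(pc_[tv[1]], pc_[tv[0]]);
          Vec3 e2 = vsub(pc_[tv[2]], pc_[tv[0]]);
          Vec3 e3 = vsub(pc_[tv[3]], pc_[tv[0]]);
          double b1 = f[tv[1]] - f[tv[0]], b2 = f[tv[2]] - f[tv[0]], b3 = f[tv[3]] - f[tv[0]];
          // solve [e1;e2;e3] g = b via Cramer
          double det = vdot(e1, vcross(e2, e3));
          Vec3 grad = {0, 0, 1e-12};
          if (std::fabs(det) > 1e-30) {
            Vec3 c23 = vcross(e2, e3), c31 = vcross(e3, e1), c12 = vcross(e1, e2);
            grad = vadd(vadd(vscale(c23, b1 / det), vscale(c31, b2 / det)), vscale(c12, b3 / det));
          }
          if (nin == 1) {
            int a = inIdx[0];
            int p0 = edgePoint(cid[a], cid[outIdx[0]], pc_[a], pc_[outIdx[0]], f[a], f[outIdx[0]]);
            int p1 = edgePoint(cid[a], cid[outIdx[1]], pc_[a], pc_[outIdx[1]], f[a], f[outIdx[1]]);
            int p2 = edgePoint(cid[a], cid[outIdx[2]], pc_[a], pc_[outIdx[2]], f[a], f[outIdx[2]]);
            emitTri(p0, p1, p2, grad);
          } else if (nin == 3) {
            int a = outIdx[0];
            int p0 = edgePoint(cid[a], cid[inIdx[0]], pc_[a], pc_[inIdx[0]], f[a], f[inIdx[0]]);
            int p1 = edgePoint(cid[a], cid[inIdx[1]], pc_[a], pc_[inIdx[1]], f[a], f[inIdx[1]]);
            int p2 = edgePoint(cid[a], cid[inIdx[2]], pc_[a], pc_[inIdx[2]], f[a], f[inIdx[2]]);
            emitTri(p0, p1, p2, grad);
          } else {  // 2 in / 2 out: quad split into two triangles
            int a = inIdx[0], b = inIdx[1], c = outIdx[0], d = outIdx[1];
            int pac = edgePoint(cid[a], cid[c], pc_[a], pc_[c], f[a], f[c]);
            int pad = edgePoint(cid[a], cid[d], pc_[a], pc_[d], f[a], f[d]);
            int pbc = edgePoint(cid[b], cid[c], pc_[b], pc_[c], f[b], f[c]);
            int pbd = edgePoint(cid[b], cid[d], pc_[b], pc_[d], f[b], f[d]);
            emitTri(pac, pad, pbd, grad);
            emitTri(pac, pbd, pbc, grad);
          }
        }
      }

  int nv = (int)mesh.vx.size(), nf = (int)mesh.fa.size();
  if (nf == 0) stop("reconstruction produced an empty surface");

  // keep the largest connected component (union-find over shared vertices)
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[a] = b;
  };
  for (int t = 0; t < nf; ++t) { unite(mesh.fa[t], mesh.fb[t]); unite(mesh.fb[t], mesh.fc[t]); }
  std::unordered_map<int, int> compFaces;
  for (int t = 0; t < nf; ++t) compFaces[find(mesh.fa[t])]++;
  int bestComp = -1, bestCount = -1;
  for (auto &kv : compFaces)
    if (kv.second > bestCount) { bestCount = kv.second; bestComp = kv.first; }

  std::vector<int> vmap(nv, -1);
  std::vector<double> VX, VY, VZ;
  std::vector<int> FA, FB, FC;
  for (int t = 0; t < nf; ++t) {
    if (find(mesh.fa[t]) != bestComp) continue;
    int ids[3] = {mesh.fa[t], mesh.fb[t], mesh.fc[t]};
    int m[3];
    for (int k = 0; k < 3; ++k) {
      if (vmap[ids[k]] < 0) {
        vmap[ids[k]] = (int)VX.size();
        VX.push_back(mesh.vx[ids[k]]);
        VY.push_back(mesh.vy[ids[k]]);
        VZ.push_back(mesh.vz[ids[k]]);
      }
      m[k] = vmap[ids[k]];
    }
    FA.push_back(m[0]); FB.push_back(m[1]); FC.push_back(m[2]);
  }

  // Newton-project extracted vertices onto the zero level set (removes the
  // linear-interpolation discretisation error of the tetrahedral grid)
  {
    double eps = 0.25 * voxel;
    for (size_t i = 0; i < VX.size(); ++i) {
      Vec3 x = {VX[i], VY[i], VZ[i]};
      for (int it = 0; it < 3; ++it) {
        double f0 = field.eval(x);
        Vec3 g = {
            (field.eval({x.x + eps, x.y, x.z}) - field.eval({x.x - eps, x.y, x.z})) / (2 * eps),
            (field.eval({x.x, x.y + eps, x.z}) - field.eval({x.x, x.y - eps, x.z})) / (2 * eps),
            (field.eval({x.x, x.y, x.z + eps}) - field.eval({x.x, x.y, x.z - eps})) / (2 * eps)};
        double g2 = vnorm2(g);
        if (g2 < 1e-12) break;
        Vec3 step = vscale(g, -f0 / g2);
        double sn = std::sqrt(vnorm2(step));
        double cap = 0.45 * voxel;  // stay within the cell: keeps topology intact
        if (sn > cap) step = vscale(step, cap / sn);
        x = vadd(x, step);
        if (sn < 1e-4 * voxel) break;
      }
      VX[i] = x.x; VY[i] = x.y; VZ[i] = x.z;
    }
  }

  NumericMatrix Vout((int)VX.size(), 3);
  for (int i = 0; i < (int)VX.size(); ++i) { Vout(i, 0) = VX[i]; Vout(i, 1) = VY[i]; Vout(i, 2) = VZ[i]; }
  IntegerMatrix Fout((int)FA.size(), 3);
  for (int t = 0; t < (int)FA.size(); ++t) { Fout(t, 0) = FA[t] + 1; Fout(t, 1) = FB[t] + 1; Fout(t, 2) = FC[t] + 1; }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
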
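// Core 3D numerics: separable truncated Gaussian filtering, exact squared
// Euclidean distance transform, maximal-inscribed-sphere local thickness,
// marching-tetrahedra iso-surface area, and per-slice shell/interior
// classification. Arrays follow R column-major layout with the tomogram
// stack along the first (fastest-varying) dimension.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // half-sample symmetric reflection: (-1 -> 0), (n -> n-1)
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// [[Rcpp::export(name = ".gaussianFilterCpp")]]
NumericVector gaussian_filter_cpp(NumericVector vol, IntegerVector dims,
                                  double sigma, int support) {
  if (sigma < 0) stop("sigma must be non-negative");
  if (support < 0) stop("support must be non-negative");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(clone(vol));
  if (sigma == 0.0 || support == 0) return out;

  // truncated, renormalised sampled Gaussian
  std::vector<double> k(2 * support + 1);
  double ksum = 0.0;
  for (int t = -support; t <= support; ++t) {
    k[t + support] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    ksum += k[t + support];
  }
  for (double &w : k) w /= ksum;

  NumericVector tmp(ntot);
  double *src = out.begin(), *dst = tmp.begin();
  const int strides[3] = {1, n1, n1 * n2};
  const int sizes[3] = {n1, n2, n3};

  for (int axis = 0; axis < 3; ++axis) {
    const int n = sizes[axis], str = strides[axis];
    // iterate over all lines along `axis`
    const int oa1 = (axis == 0) ? 1 : 0;           // other axes
    const int oa2 = (axis == 2) ? 1 : 2;
    const int m1 = sizes[oa1], m2 = sizes[oa2];
    const int s1 = strides[oa1], s2 = strides[oa2];
    for (int b = 0; b < m2; ++b) {
      for (int a = 0; a < m1; ++a) {
        const R_xlen_t base = (R_xlen_t)a * s1 + (R_xlen_t)b * s2;
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int t = -support; t <= support; ++t)
            acc += k[t + support] * src[base + (R_xlen_t)reflect_idx(i + t, n) * str];
          dst[base + (R_xlen_t)i * str] = acc;
        }
      }
    }
    std::swap(src, dst);
  }
  if (src == out.begin()) return out; // odd number of swaps already resolved
  std::copy(src, src + ntot, out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared EDT (Felzenszwalb & Huttenlocher), distance of each
// foreground voxel to the nearest background voxel centre, in voxel units.

static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &v, std::vector<double> &z, int n) {
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[kk]] + (double)v[kk] * v[kk])) /
          (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = (double)q - v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export(name = ".edtSqCpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  const double INF = 1e60;
  NumericVector d(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) d[i] = mask[i] ? INF : 0.0;

  const int strides[3] = {1, n1, n1 * n2};
  const int sizes[3] = {n1, n2, n3};
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int axis = 0; axis < 3; ++axis) {
    const int n = sizes[axis], str = strides[axis];
    const int oa1 = (axis == 0) ? 1 : 0;
    const int oa2 = (axis == 2) ? 1 : 2;
    const int m1 = sizes[oa1], m2 = sizes[oa2];
    const int s1 = strides[oa1], s2 = strides[oa2];
    for (int b = 0; b < m2; ++b)
      for (int a = 0; a < m1; ++a) {
        const R_xlen_t base = (R_xlen_t)a * s1 + (R_xlen_t)b * s2;
        for (int i = 0; i < n; ++i) f[i] = d[base + (R_xlen_t)i * str];
        edt_1d(f, dd, v, z, n);
        for (int i = 0; i < n; ++i) d[base + (R_xlen_t)i * str] = dd[i];
      }
  }
  return d;
}

// ---------------------------------------------------------------------------
// Local thickness (Hildebrand-Ruegsegger direct method): thickness at a
// voxel is the diameter of the largest inscribed sphere containing it.
// Radii are taken from the EDT; redundant sphere centres (spheres fully
// contained in a neighbour's sphere) are pruned before painting.

// [[Rcpp::export(name = ".localThicknessCpp")]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector d2 = edt_sq_cpp(mask, dims);
  NumericVector th(ntot);

  std::vector<double> r(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) r[i] = mask[i] ? std::sqrt(d2[i]) : 0.0;

  const double eps = 1e-9;
  auto IDX = [&](int i, int j, int kk) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)n1 * j + (R_xlen_t)n1 * n2 * kk;
  };

  for (int kk = 0; kk < n3; ++kk)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t c = IDX(i, j, kk);
        if (!mask[c]) continue;
        double rc = r[c];
        // prune if a 26-neighbour's sphere contains this one
        bool pruned = false;
        for (int dz = -1; dz <= 1 && !pruned; ++dz)
          for (int dy = -1; dy <= 1 && !pruned; ++dy)
            for (int dx = -1; dx <= 1 && !pruned; ++dx) {
              if (!dx && !dy && !dz) continue;
              int ii = i + dx, jj = j + dy, kz = kk + dz;
              if (ii < 0 || jj < 0 || kz < 0 || ii >= n1 || jj >= n2 || kz >= n3)
                continue;
              R_xlen_t nb = IDX(ii, jj, kz);
              if (!mask[nb]) continue;
              double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              if (r[nb] >= rc + dist - eps) pruned = true;
            }
        if (pruned) continue;
        // paint sphere of radius rc with diameter value
        int rad = (int)std::floor(rc + eps);
        double rc2 = rc * rc + eps, diam = 2.0 * rc;
        for (int dz = -rad; dz <= rad; ++dz) {
          int kz = kk + dz;
          if (kz < 0 || kz >= n3) continue;
          for (int dy = -rad; dy <= rad; ++dy) {
            int jj = j + dy;
            if (jj < 0 || jj >= n2) continue;
            double dyz2 = (double)dz * dz + (double)dy * dy;
            if (dyz2 > rc2) continue;
            int dxmax = (int)std::floor(std::sqrt(rc2 - dyz2));
            for (int dx = -dxmax; dx <= dxmax; ++dx) {
              int ii = i + dx;
              if (ii < 0 || ii >= n1) continue;
              R_xlen_t x = IDX(ii, jj, kz);
              if (mask[x] && th[x] < diam) th[x] = diam;
            }
          }
        }
      }
  return th;
}

// ---------------------------------------------------------------------------
// Iso-surface area by marching tetrahedra on the Kuhn 6-tetrahedron
// decomposition of each grid cell, with linear interpolation of crossing
// points along tetrahedron edges. A cell contributes only if all eight of
// its corners lie inside the (optional) ROI, so surface sheets cut open at
// the ROI boundary are not closed off or counted.

struct Vec3 { double x, y, z; };
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double tri_area(const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  Vec3 u = vsub(b, a), v = vsub(c, a);
  double cx = u.y * v.z - u.z * v.y;
  double cy = u.z * v.x - u.x * v.z;
  double cz = u.x * v.y - u.y * v.x;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}
static inline Vec3 lerp(const Vec3 &p, const Vec3 &q, double fp, double fq,
                        double iso) {
  double t = (iso - fp) / (fq - fp);
  return {p.x + t * (q.x - p.x), p.y + t * (q.y - p.y), p.z + t * (q.z - p.z)};
}

// [[Rcpp::export(name = ".isoSurfaceAreaCpp")]]
double iso_surface_area_cpp(NumericVector field, IntegerVector dims,
                            double iso, Nullable<LogicalVector> roi_) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const bool has_roi = roi_.isNotNull();
  LogicalVector roi;
  if (has_roi) roi = roi_.get();

  // the 6 Kuhn tetrahedra: paths 0 -> 7 adding one axis at a time
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  int tet_corner[6][4]; // corner id = dx + 2*dy + 4*dz
  for (int p = 0; p < 6; ++p) {
    int bits[3] = {0, 0, 0};
    tet_corner[p][0] = 0;
    for (int s = 0; s < 3; ++s) {
      bits[perms[p][s]] = 1;
      tet_corner[p][s + 1] = bits[0] + 2 * bits[1] + 4 * bits[2];
    }
  }
  const Vec3 cpos[8] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};

  auto IDX = [&](int i, int j, int kk) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)n1 * j + (R_xlen_t)n1 * n2 * kk;
  };

  double area = 0.0;
  double f[8];
  for (int kk = 0; kk + 1 < n3; ++kk)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        bool any_in = false, any_out = false, ok = true;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = kk + ((c >> 2) & 1);
          R_xlen_t id = IDX(ci, cj, ck);
          if (has_roi && !roi[id]) { ok = false; break; }
          f[c] = field[id];
          if (f[c] >= iso) any_in = true; else any_out = true;
        }
        if (!ok || !any_in || !any_out) continue;
        for (int p = 0; p < 6; ++p) {
          const int *tc = tet_corner[p];
          double fv[4];
          bool ins[4];
          int nin = 0;
          for (int s = 0; s < 4; ++s) {
            fv[s] = f[tc[s]];
            ins[s] = fv[s] >= iso;
            if (ins[s]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          const Vec3 *pp[4] = {&cpos[tc[0]], &cpos[tc[1]], &cpos[tc[2]], &cpos[tc[3]]};
          if (nin == 1 || nin == 3) {
            bool want = (nin == 1);
            int a = 0;
            for (int s = 0; s < 4; ++s) if (ins[s] == want) a = s;
            Vec3 pts[3];
            int m = 0;
            for (int s = 0; s < 4; ++s)
              if (s != a) pts[m++] = lerp(*pp[a], *pp[s], fv[a], fv[s], iso);
            area += tri_area(pts[0], pts[1], pts[2]);
          } else { // 2 in, 2 out -> quad
            int a = -1, b = -1, c2 = -1, d = -1;
            for (int s = 0; s < 4; ++s) {
              if (ins[s]) { if (a < 0) a = s; else b = s; }
              else        { if (c2 < 0) c2 = s; else d = s; }
            }
            Vec3 pac = lerp(*pp[a], *pp[c2], fv[a], fv[c2], iso);
            Vec3 pad = lerp(*pp[a], *pp[d],  fv[a], fv[d],  iso);
            Vec3 pbd = lerp(*pp[b], *pp[d],  fv[b], fv[d],  iso);
            Vec3 pbc = lerp(*pp[b], *pp[c2], fv[b], fv[c2], iso);
            area += tri_area(pac, pad, pbd) + tri_area(pac, pbd, pbc);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Per-slice classification of a bone mask into exterior background (0),
// cortical shell (1, bone 8-connected to bone touching the exterior),
// enclosed interior background (2) and interior bone (3, e.g. trabeculae).
// Slices are indexed along the first array dimension; background flooding
// is 4-connected, bone components 8-connected.

// [[Rcpp::export(name = ".sliceRegionCodesCpp")]]
IntegerVector slice_region_codes_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector codes((R_xlen_t)n1 * n2 * n3);
  std::vector<int> state((size_t)n2 * n3);
  auto ID2 = [&](int j, int kk) { return (size_t)j + (size_t)n2 * kk; };
  auto IDX = [&](int i, int j, int kk) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)n1 * j + (R_xlen_t)n1 * n2 * kk;
  };
  const int dj4[4] = {1, -1, 0, 0}, dk4[4] = {0, 0, 1, -1};

  std::queue<std::pair<int,int>> q;
  for (int i = 0; i < n1; ++i) {
    // state: 0 unvisited bg, 1 bone, 2 exterior bg, 3 cortex bone
    for (int kk = 0; kk < n3; ++kk)
      for (int j = 0; j < n2; ++j)
        state[ID2(j, kk)] = mask[IDX(i, j, kk)] ? 1 : 0;
    // flood exterior background from slice border (4-connectivity)
    for (int kk = 0; kk < n3; ++kk)
      for (int j = 0; j < n2; ++j)
        if ((j == 0 || kk == 0 || j == n2 - 1 || kk == n3 - 1) &&
            state[ID2(j, kk)] == 0) {
          state[ID2(j, kk)] = 2;
          q.push({j, kk});
        }
    while (!q.empty()) {
      auto [j, kk] = q.front(); q.pop();
      for (int t = 0; t < 4; ++t) {
        int jj = j + dj4[t], kz = kk + dk4[t];
        if (jj < 0 || kz < 0 || jj >= n2 || kz >= n3) continue;
        if (state[ID2(jj, kz)] == 0) {
          state[ID2(jj, kz)] = 2;
          q.push({jj, kz});
        }
      }
    }
    // cortex: bone components (8-connected) seeded at voxels 4-adjacent to
    // exterior (or on the slice border)
    for (int kk = 0; kk < n3; ++kk)
      for (int j = 0; j < n2; ++j) {
        if (state[ID2(j, kk)] != 1) continue;
        bool seed = (j == 0 || kk == 0 || j == n2 - 1 || kk == n3 - 1);
        for (int t = 0; t < 4 && !seed; ++t) {
          int jj = j + dj4[t], kz = kk + dk4[t];
          if (jj >= 0 && kz >= 0 && jj < n2 && kz < n3 &&
              state[ID2(jj, kz)] == 2)
            seed = true;
        }
        if (seed) {
          state[ID2(j, kk)] = 3;
          q.push({j, kk});
        }
      }
    while (!q.empty()) {
      auto [j, kk] = q.front(); q.pop();
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          if (!dj && !dk) continue;
          int jj = j + dj, kz = kk + dk;
          if (jj < 0 || kz < 0 || jj >= n2 || kz >= n3) continue;
          if (state[ID2(jj, kz)] == 1) {
            state[ID2(jj, kz)] = 3;
            q.push({jj, kz});
          }
        }
    }
    for (int kk = 0; kk < n3; ++kk)
      for (int j = 0; j < n2; ++j) {
        int s = state[ID2(j, kk)];
        int code = (s == 2) ? 0 : (s == 3) ? 1 : (s == 0) ? 2 : 3;
        codes[IDX(i, j, kk)] = code;
      }
  }
  return codes;
}
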
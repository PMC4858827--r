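// Low-level geometry kernels: marching tetrahedra, 26-connected flood fill,
// separable Gaussian blur, binary dilation, parity voxelization and
// grid-accelerated closest point-on-surface queries.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable 3-D Gaussian blur, reflected boundaries. sigma in voxel units.
// ---------------------------------------------------------------------------
static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

static inline int reflect_idx(int i, int n) {
  // reflect-101 style boundary
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector vol, IntegerVector dims,
                              NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> b(a.size());
  auto idx = [&](int x, int y, int z) {
    return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * (size_t)z);
  };
  for (int axis = 0; axis < 3; ++axis) {
    double sg = sigma_vox[axis];
    if (sg <= 0) continue;
    std::vector<double> k = gauss_kernel(sg);
    int r = ((int)k.size() - 1) / 2;
    int n = dims[axis];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double acc = 0.0;
          for (int o = -r; o <= r; ++o) {
            int xx = x, yy = y, zz = z;
            if (axis == 0) xx = reflect_idx(x + o, nx);
            else if (axis == 1) yy = reflect_idx(y + o, ny);
            else zz = reflect_idx(z + o, nz);
            acc += k[o + r] * a[idx(xx, yy, zz)];
          }
          b[idx(x, y, z)] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component containing seed (1-based linear index).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_region_grow(LogicalVector mask, IntegerVector dims,
                              int seed_idx1) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> in(n), out(n, 0);
  for (size_t i = 0; i < n; ++i) in[i] = mask[i] ? 1 : 0;
  long seed = seed_idx1 - 1;
  if (seed < 0 || (size_t)seed >= n || !in[seed])
    stop("seed voxel is not inside the mask");
  std::queue<long> q;
  q.push(seed);
  out[seed] = 1;
  while (!q.empty()) {
    long c = q.front(); q.pop();
    int x = c % nx, y = (c / nx) % ny, z = c / ((long)nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          long c2 = xx + (long)nx * (yy + (long)ny * zz);
          if (in[c2] && !out[c2]) { out[c2] = 1; q.push(c2); }
        }
  }
  LogicalVector res(n);
  for (size_t i = 0; i < n; ++i) res[i] = out[i] != 0;
  res.attr("dim") = dims;
  return res;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate26(LogicalVector mask, IntegerVector dims, int iters) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> a(n), b(n);
  for (size_t i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  for (int it = 0; it < iters; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          long c = x + (long)nx * (y + (long)ny * z);
          char v = a[c];
          if (!v) {
            for (int dz = -1; dz <= 1 && !v; ++dz)
              for (int dy = -1; dy <= 1 && !v; ++dy)
                for (int dx = -1; dx <= 1 && !v; ++dx) {
                  int xx = x + dx, yy = y + dy, zz = z + dz;
                  if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                      zz < 0 || zz >= nz) continue;
                  if (a[xx + (long)nx * (yy + (long)ny * zz)]) v = 1;
                }
          }
          b[c] = v;
        }
    std::swap(a, b);
  }
  LogicalVector res(n);
  for (size_t i = 0; i < n; ++i) res[i] = a[i] != 0;
  res.attr("dim") = dims;
  return res;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a node-sampled scalar field. The cube is split into
// the 6-tetrahedron Kuhn decomposition (shared main diagonal), which is
// consistent across neighbouring cubes, so the extracted surface is
// watertight. Vertices are deduplicated per grid edge. Triangles are wound
// so normals point toward increasing field value (outward for signed
// distance functions).
// ---------------------------------------------------------------------------
struct Key64Hash {
  size_t operator()(const uint64_t& k) const { return std::hash<uint64_t>()(k); }
};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector f, IntegerVector dims,
                    NumericVector origin, NumericVector spacing,
                    double level) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto nid = [&](int x, int y, int z) -> long {
    return x + (long)nx * (y + (long)ny * z);
  };
  std::unordered_map<uint64_t, int, Key64Hash> edge_vert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F0, F1, F2;

  auto node_world = [&](long id, double* p) {
    int x = id % nx, y = (id / nx) % ny, z = id / ((long)nx * ny);
    p[0] = origin[0] + x * spacing[0];
    p[1] = origin[1] + y * spacing[1];
    p[2] = origin[2] + z * spacing[2];
  };

  auto edge_vertex = [&](long a, long b) -> int {
    if (a > b) std::swap(a, b);
    uint64_t key = (uint64_t)a * (uint64_t)(nx * (long)ny * nz) + (uint64_t)b;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double pa[3], pb[3];
    node_world(a, pa); node_world(b, pb);
    double fa = f[a], fb = f[b];
    double t = (level - fa) / (fb - fa);
    if (t < 1e-6) t = 1e-6;
    if (t > 1 - 1e-6) t = 1 - 1e-6;
    int id = (int)VX.size();
    VX.push_back(pa[0] + t * (pb[0] - pa[0]));
    VY.push_back(pa[1] + t * (pb[1] - pa[1]));
    VZ.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vert[key] = id;
    return id;
  };

  // add a triangle of edge-vertices, oriented away from the inside region
  auto add_tri = [&](int v0, int v1, int v2, const double* inref) {
    double ax = VX[v1] - VX[v0], ay = VY[v1] - VY[v0], az = VZ[v1] - VZ[v0];
    double bx = VX[v2] - VX[v0], by = VY[v2] - VY[v0], bz = VZ[v2] - VZ[v0];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz,
           nzv = ax * by - ay * bx;
    double cx = (VX[v0] + VX[v1] + VX[v2]) / 3.0 - inref[0];
    double cy = (VY[v0] + VY[v1] + VY[v2]) / 3.0 - inref[1];
    double cz = (VZ[v0] + VZ[v1] + VZ[v2]) / 3.0 - inref[2];
    if (nxv * cx + nyv * cy + nzv * cz < 0) std::swap(v1, v2);
    F0.push_back(v0); F1.push_back(v1); F2.push_back(v2);
  };

  // Kuhn decomposition: permutations of axis insertion order
  static const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  long tet[4];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        for (int pp = 0; pp < 6; ++pp) {
          int cx = x, cy = y, cz = z;
          tet[0] = nid(cx, cy, cz);
          for (int s = 0; s < 3; ++s) {
            int ax = perms[pp][s];
            if (ax == 0) cx++; else if (ax == 1) cy++; else cz++;
            tet[s + 1] = nid(cx, cy, cz);
          }
          bool inside[4];
          int nin = 0;
          for (int i = 0; i < 4; ++i) {
            inside[i] = f[tet[i]] < level;
            if (inside[i]) nin++;
          }
          if (nin == 0 || nin == 4) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int i = 0; i < 4; ++i)
            (inside[i] ? ins[ni++] : outs[no++]) = i;
          double inref[3] = {0, 0, 0};
          for (int i = 0; i < ni; ++i) {
            double p[3];
            node_world(tet[ins[i]], p);
            inref[0] += p[0] / ni; inref[1] += p[1] / ni; inref[2] += p[2] / ni;
          }
          if (nin == 1) {
            int a = ins[0];
            int e0 = edge_vertex(tet[a], tet[outs[0]]);
            int e1 = edge_vertex(tet[a], tet[outs[1]]);
            int e2 = edge_vertex(tet[a], tet[outs[2]]);
            add_tri(e0, e1, e2, inref);
          } else if (nin == 3) {
            int a = outs[0];
            int e0 = edge_vertex(tet[a], tet[ins[0]]);
            int e1 = edge_vertex(tet[a], tet[ins[1]]);
            int e2 = edge_vertex(tet[a], tet[ins[2]]);
            add_tri(e0, e1, e2, inref);
          } else { // 2-2: quad
            int i0 = ins[0], i1 = ins[1], o0 = outs[0], o1 = outs[1];
            int e00 = edge_vertex(tet[i0], tet[o0]);
            int e01 = edge_vertex(tet[i0], tet[o1]);
            int e10 = edge_vertex(tet[i1], tet[o0]);
            int e11 = edge_vertex(tet[i1], tet[o1]);
            add_tri(e00, e01, e11, inref);
            add_tri(e00, e11, e10, inref);
          }
        }
      }

  int nV = VX.size(), nF = F0.size();
  NumericMatrix V(nV, 3);
  for (int i = 0; i < nV; ++i) { V(i, 0) = VX[i]; V(i, 1) = VY[i]; V(i, 2) = VZ[i]; }
  IntegerMatrix Fm(nF, 3);
  for (int i = 0; i < nF; ++i) {
    Fm(i, 0) = F0[i] + 1; Fm(i, 1) = F1[i] + 1; Fm(i, 2) = F2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// Closest point on a triangle (Ericson, Real-Time Collision Detection)
// ---------------------------------------------------------------------------
static void closest_pt_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i] = a[i] + v*ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i] = a[i] + w*ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i] = b[i] + w*(c[i]-b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

// Grid-accelerated closest point query against a triangle soup.
// Returns distances, closest points and (1-based) face indices.
// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int nP = P.nrow(), nF = F.nrow();
  if (nF == 0) stop("empty mesh");
  int nV = V.nrow();
  // flat copies: much cheaper element access than Rcpp matrices
  std::vector<double> Vx(nV), Vy(nV), Vz(nV);
  for (int i = 0; i < nV; ++i) { Vx[i]=V(i,0); Vy[i]=V(i,1); Vz[i]=V(i,2); }
  std::vector<int> F0(nF), F1(nF), F2(nF);
  for (int t = 0; t < nF; ++t) { F0[t]=F(t,0)-1; F1[t]=F(t,1)-1; F2[t]=F(t,2)-1; }
  // bounding box
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < nV; ++i) {
    double c[3] = {Vx[i], Vy[i], Vz[i]};
    for (int k = 0; k < 3; ++k) {
      if (c[k] < lo[k]) lo[k] = c[k];
      if (c[k] > hi[k]) hi[k] = c[k];
    }
  }
  double ext[3];
  for (int k = 0; k < 3; ++k) ext[k] = std::max(hi[k]-lo[k], 1e-9);
  // target ~ 2 triangles per cell
  double vol = ext[0]*ext[1]*ext[2];
  double cs = std::cbrt(vol * 2.0 / nF);
  if (!(cs > 0) || !R_finite(cs)) cs = std::max({ext[0],ext[1],ext[2]}) / 8;
  int gd[3];
  for (int k = 0; k < 3; ++k) {
    gd[k] = std::max(1, std::min(256, (int)std::ceil(ext[k] / cs)));
  }
  double cw[3];
  for (int k = 0; k < 3; ++k) cw[k] = ext[k] / gd[k];
  auto cell_of = [&](double x, int k) {
    int c = (int)std::floor((x - lo[k]) / cw[k]);
    if (c < 0) c = 0;
    if (c >= gd[k]) c = gd[k]-1;
    return c;
  };
  long ncell = (long)gd[0]*gd[1]*gd[2];
  std::vector<std::vector<int>> cells(ncell);
  for (int t = 0; t < nF; ++t) {
    double tlo[3], thi[3];
    for (int k = 0; k < 3; ++k) { tlo[k] = R_PosInf; thi[k] = R_NegInf; }
    int vids[3] = {F0[t], F1[t], F2[t]};
    for (int j = 0; j < 3; ++j) {
      double c[3] = {Vx[vids[j]], Vy[vids[j]], Vz[vids[j]]};
      for (int k = 0; k < 3; ++k) {
        if (c[k] < tlo[k]) tlo[k] = c[k];
        if (c[k] > thi[k]) thi[k] = c[k];
      }
    }
    int c0[3], c1[3];
    for (int k = 0; k < 3; ++k) {
      c0[k] = cell_of(tlo[k], k); c1[k] = cell_of(thi[k], k);
    }
    for (int z = c0[2]; z <= c1[2]; ++z)
      for (int y = c0[1]; y <= c1[1]; ++y)
        for (int x = c0[0]; x <= c1[0]; ++x)
          cells[x + (long)gd[0]*(y + (long)gd[1]*z)].push_back(t);
  }
  double mincw = std::min({cw[0], cw[1], cw[2]});

  NumericVector dist(nP);
  NumericMatrix CP(nP, 3);
  IntegerVector FI(nP);
  int maxr = std::max({gd[0], gd[1], gd[2]});
  for (int ip = 0; ip < nP; ++ip) {
    double p[3] = {P(ip,0), P(ip,1), P(ip,2)};
    int pc[3];
    for (int k = 0; k < 3; ++k) pc[k] = cell_of(p[k], k);
    double best = R_PosInf, bestpt[3] = {0,0,0};
    int bestf = -1;
    for (int r = 0; r <= maxr; ++r) {
      if (bestf >= 0 && (double)(r - 1) * mincw > std::sqrt(best)) break;
      bool any = false;
      int x0 = pc[0]-r, x1 = pc[0]+r, y0 = pc[1]-r, y1 = pc[1]+r,
          z0 = pc[2]-r, z1 = pc[2]+r;
      for (int z = z0; z <= z1; ++z) {
        if (z < 0 || z >= gd[2]) continue;
        for (int y = y0; y <= y1; ++y) {
          if (y < 0 || y >= gd[1]) continue;
          for (int x = x0; x <= x1; ++x) {
            if (x < 0 || x >= gd[0]) continue;
            // ring only
            if (r > 0 && x != x0 && x != x1 && y != y0 && y != y1 &&
                z != z0 && z != z1) continue;
            any = true;
            const std::vector<int>& lst =
              cells[x + (long)gd[0]*(y + (long)gd[1]*z)];
            for (int t : lst) {
              double a[3] = {Vx[F0[t]], Vy[F0[t]], Vz[F0[t]]};
              double b[3] = {Vx[F1[t]], Vy[F1[t]], Vz[F1[t]]};
              double c[3] = {Vx[F2[t]], Vy[F2[t]], Vz[F2[t]]};
              double q[3];
              closest_pt_tri(p, a, b, c, q);
              double d2 = (p[0]-q[0])*(p[0]-q[0]) + (p[1]-q[1])*(p[1]-q[1]) +
                          (p[2]-q[2])*(p[2]-q[2]);
              if (d2 < best) {
                best = d2; bestf = t;
                bestpt[0]=q[0]; bestpt[1]=q[1]; bestpt[2]=q[2];
              }
            }
          }
        }
      }
      if (!any && bestf >= 0) break;
    }
    dist[ip] = std::sqrt(best);
    CP(ip,0) = bestpt[0]; CP(ip,1) = bestpt[1]; CP(ip,2) = bestpt[2];
    FI[ip] = bestf + 1;
  }
  return List::create(_["distance"] = dist, _["point"] = CP, _["face"] = FI);
}

// ---------------------------------------------------------------------------
// Parity voxelization: for voxel centers x[i], y[j], z[k], casts +x rays and
// counts triangle crossings; odd parity = inside. Assumes a watertight mesh.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_voxelize_parity(NumericMatrix V, IntegerMatrix F,
                                  NumericVector xs, NumericVector ys,
                                  NumericVector zs) {
  int nx = xs.size(), ny = ys.size(), nz = zs.size(), nF = F.nrow();
  // collect crossing x positions per (j,k) ray
  std::vector<std::vector<double>> cross((size_t)ny * nz);
  const double eps = 1e-9;
  double dy = ny > 1 ? ys[1]-ys[0] : 1.0, dz = nz > 1 ? zs[1]-zs[0] : 1.0;
  for (int t = 0; t < nF; ++t) {
    double a[3] = {V(F(t,0)-1,0), V(F(t,0)-1,1), V(F(t,0)-1,2)};
    double b[3] = {V(F(t,1)-1,0), V(F(t,1)-1,1), V(F(t,1)-1,2)};
    double c[3] = {V(F(t,2)-1,0), V(F(t,2)-1,1), V(F(t,2)-1,2)};
    double ylo = std::min({a[1],b[1],c[1]}), yhi = std::max({a[1],b[1],c[1]});
    double zlo = std::min({a[2],b[2],c[2]}), zhi = std::max({a[2],b[2],c[2]});
    int j0 = (int)std::ceil((ylo - ys[0]) / dy - eps);
    int j1 = (int)std::floor((yhi - ys[0]) / dy + eps);
    int k0 = (int)std::ceil((zlo - zs[0]) / dz - eps);
    int k1 = (int)std::floor((zhi - zs[0]) / dz + eps);
    if (j0 < 0) j0 = 0; if (j1 >= ny) j1 = ny-1;
    if (k0 < 0) k0 = 0; if (k1 >= nz) k1 = nz-1;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) {
        // tiny consistent jitter avoids edge-on-ray degeneracies
        double py = ys[j] + 1e-7 * dy, pz = zs[k] + 1.3e-7 * dz;
        // 2-D point-in-triangle in (y,z); signed areas
        double d1 = (b[1]-a[1])*(pz-a[2]) - (b[2]-a[2])*(py-a[1]);
        double d2 = (c[1]-b[1])*(pz-b[2]) - (c[2]-b[2])*(py-b[1]);
        double d3 = (a[1]-c[1])*(pz-c[2]) - (a[2]-c[2])*(py-c[1]);
        bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
        bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
        if (neg && pos) continue;
        double area2 = (b[1]-a[1])*(c[2]-a[2]) - (b[2]-a[2])*(c[1]-a[1]);
        if (std::fabs(area2) < 1e-14) continue;
        double w1 = d2 / area2, w2 = d3 / area2, w3 = d1 / area2;
        double xh = w1*a[0] + w2*b[0] + w3*c[0];
        cross[(size_t)j + (size_t)ny*k].push_back(xh);
      }
  }
  LogicalVector out((size_t)nx*ny*nz);
  IntegerVector dims = IntegerVector::create(nx, ny, nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      std::vector<double>& cr = cross[(size_t)j + (size_t)ny*k];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end());
      for (int i = 0; i < nx; ++i) {
        // parity of crossings beyond x
        size_t nbeyond = cr.end() -
          std::upper_bound(cr.begin(), cr.end(), xs[i]);
        if (nbeyond % 2 == 1)
          out[i + (size_t)nx*(j + (size_t)ny*k)] = true;
      }
    }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Mark voxels whose (dilated) neighbourhood is touched by any triangle's
// bounding box: the shell where exact surface distances are required.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_mark_tri_cells(NumericMatrix V, IntegerMatrix F,
                                 NumericVector xs, NumericVector ys,
                                 NumericVector zs, int dilate) {
  int nx = xs.size(), ny = ys.size(), nz = zs.size(), nF = F.nrow();
  double dx = nx > 1 ? xs[1]-xs[0] : 1.0;
  double dy = ny > 1 ? ys[1]-ys[0] : 1.0;
  double dz = nz > 1 ? zs[1]-zs[0] : 1.0;
  LogicalVector out((size_t)nx*ny*nz);
  auto clampi = [](int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
  };
  for (int t = 0; t < nF; ++t) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int j = 0; j < 3; ++j) {
      int vi = F(t, j) - 1;
      for (int k = 0; k < 3; ++k) {
        double x = V(vi, k);
        if (x < tlo[k]) tlo[k] = x;
        if (x > thi[k]) thi[k] = x;
      }
    }
    int i0 = clampi((int)std::floor((tlo[0]-xs[0])/dx) - dilate, 0, nx-1);
    int i1 = clampi((int)std::ceil((thi[0]-xs[0])/dx) + dilate, 0, nx-1);
    int j0 = clampi((int)std::floor((tlo[1]-ys[0])/dy) - dilate, 0, ny-1);
    int j1 = clampi((int)std::ceil((thi[1]-ys[0])/dy) + dilate, 0, ny-1);
    int k0 = clampi((int)std::floor((tlo[2]-zs[0])/dz) - dilate, 0, nz-1);
    int k1 = clampi((int)std::ceil((thi[2]-zs[0])/dz) + dilate, 0, nz-1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          out[i + (size_t)nx*(j + (size_t)ny*k)] = true;
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
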
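#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// ---- closest point on a triangle (Ericson, Real-Time Collision Detection) ----
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v*ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w*ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w*(c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

// For each point, distance to (and foot point on) the nearest triangle of
// the mesh (V, F). F is 0-based here. Triangles are binned into a uniform
// grid by bounding box; each query expands Chebyshev shells of cells
// around the point until the best distance provably cannot improve.
// [[Rcpp::export]]
List cpp_point_surface(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int n = P.nrow(), m = F.nrow();
  NumericVector dist(n);
  NumericMatrix nearest(n, 3);
  IntegerVector tri(n);
  // triangle bounding boxes + global bbox
  std::vector<double> blo(3 * m), bhi(3 * m);
  double glo[3] = { 1e300, 1e300, 1e300 }, ghi[3] = { -1e300, -1e300, -1e300 };
  for (int t = 0; t < m; ++t) {
    int ia = F(t,0), ib = F(t,1), ic = F(t,2);
    for (int d = 0; d < 3; ++d) {
      double va = V(ia,d), vb = V(ib,d), vcd = V(ic,d);
      blo[3*t+d] = std::min(va, std::min(vb, vcd));
      bhi[3*t+d] = std::max(va, std::max(vb, vcd));
      glo[d] = std::min(glo[d], blo[3*t+d]);
      ghi[d] = std::max(ghi[d], bhi[3*t+d]);
    }
  }
  // grid resolution: ~m cells, between 1 and 128 per axis
  double ext[3];
  for (int d = 0; d < 3; ++d) ext[d] = std::max(ghi[d] - glo[d], 1e-9);
  double target = std::cbrt((double)std::max(m, 1));
  int nc[3];
  double h = std::max(ext[0], std::max(ext[1], ext[2])) / std::max(target, 1.0);
  // cell edge at least the median-ish triangle size to limit bin counts
  double mean_diag = 0.0;
  for (int t = 0; t < m; ++t) {
    double dd = 0.0;
    for (int d = 0; d < 3; ++d) { double e = bhi[3*t+d] - blo[3*t+d]; dd += e * e; }
    mean_diag += std::sqrt(dd);
  }
  if (m > 0) mean_diag /= m;
  h = std::max(h, mean_diag);
  for (int d = 0; d < 3; ++d)
    nc[d] = std::min(128, std::max(1, (int)std::ceil(ext[d] / h)));
  auto cell_of = [&](double x, int d) {
    int c = (int)std::floor((x - glo[d]) / h);
    return std::min(nc[d] - 1, std::max(0, c));
  };
  long long ncell = (long long)nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int>> bins(ncell);
  for (int t = 0; t < m; ++t) {
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      c0[d] = cell_of(blo[3*t+d], d);
      c1[d] = cell_of(bhi[3*t+d], d);
    }
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          bins[i + (long long)nc[0] * (j + (long long)nc[1] * k)].push_back(t);
  }
  int max_shell = nc[0] + nc[1] + nc[2] + 2;
  std::vector<int> seen(m, -1);
  for (int i = 0; i < n; ++i) {
    double p[3] = { P(i,0), P(i,1), P(i,2) };
    double best = std::numeric_limits<double>::infinity();
    double bestpt[3] = { p[0], p[1], p[2] };
    int best_tri = 0;
    int pc[3];
    for (int d = 0; d < 3; ++d) pc[d] = cell_of(p[d], d);
    auto scan_tri = [&](int t) {
      if (seen[t] == i) return;
      seen[t] = i;
      double db = 0.0;
      for (int d = 0; d < 3; ++d) {
        double lo = blo[3*t+d], hi = bhi[3*t+d];
        double e = (p[d] < lo) ? lo - p[d] : (p[d] > hi ? p[d] - hi : 0.0);
        db += e * e;
      }
      if (db >= best) return;
      int ia = F(t,0), ib = F(t,1), ic = F(t,2);
      double a[3] = { V(ia,0), V(ia,1), V(ia,2) };
      double b[3] = { V(ib,0), V(ib,1), V(ib,2) };
      double c[3] = { V(ic,0), V(ic,1), V(ic,2) };
      double q[3];
      closest_on_tri(p, a, b, c, q);
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) { double e = q[d] - p[d]; d2 += e * e; }
      if (d2 < best) {
        best = d2;
        bestpt[0] = q[0]; bestpt[1] = q[1]; bestpt[2] = q[2];
        best_tri = t;
      }
    };
    for (int r = 0; r < max_shell; ++r) {
      // shells beyond r cannot contain anything closer than (r-1)*h
      if (r >= 1 && best <= (double)(r - 1) * h * (double)(r - 1) * h) break;
      int i0 = std::max(0, pc[0] - r), i1 = std::min(nc[0] - 1, pc[0] + r);
      int j0 = std::max(0, pc[1] - r), j1 = std::min(nc[1] - 1, pc[1] + r);
      int k0 = std::max(0, pc[2] - r), k1 = std::min(nc[2] - 1, pc[2] + r);
      bool any_cell = false;
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int ii = i0; ii <= i1; ++ii) {
            // only the surface of the Chebyshev shell
            if (r > 0 &&
                std::abs(ii - pc[0]) != r && std::abs(j - pc[1]) != r &&
                std::abs(k - pc[2]) != r) continue;
            any_cell = true;
            const std::vector<int> &b = bins[ii + (long long)nc[0] * (j + (long long)nc[1] * k)];
            for (size_t q = 0; q < b.size(); ++q) scan_tri(b[q]);
          }
      if (!any_cell && r > std::max(nc[0], std::max(nc[1], nc[2]))) break;
    }
    dist[i] = std::sqrt(best);
    nearest(i,0) = bestpt[0]; nearest(i,1) = bestpt[1]; nearest(i,2) = bestpt[2];
    tri[i] = best_tri + 1;  // 1-based for R
  }
  return List::create(_["dist"] = dist, _["nearest"] = nearest, _["tri"] = tri);
}

// For each row of P, Euclidean distance to the nearest row of Q.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix P, NumericMatrix Q) {
  const int n = P.nrow(), m = Q.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = P(i,0), py = P(i,1), pz = P(i,2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      double dx = Q(j,0) - px, dy = Q(j,1) - py, dz = Q(j,2) - pz;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Ray-cast voxelization: fill voxels whose centers lie inside the closed mesh.
// Rays are cast along +x through each (y,z) column of voxel centers.
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           IntegerVector dim, double spacing,
                           NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = F.nrow();
  LogicalVector out(nx * ny * nz);
  const double eps = 1e-7 * spacing;  // nudge rays off vertices/edges
  std::vector<std::vector<double>> cross(ny * nz);
  for (int t = 0; t < m; ++t) {
    int ia = F(t,0), ib = F(t,1), ic = F(t,2);
    double ay = V(ia,1), az = V(ia,2), by = V(ib,1), bz = V(ib,2), cy = V(ic,1), cz = V(ic,2);
    double ylo = std::min(ay, std::min(by, cy)), yhi = std::max(ay, std::max(by, cy));
    double zlo = std::min(az, std::min(bz, cz)), zhi = std::max(az, std::max(bz, cz));
    int j0 = std::max(0, (int)std::ceil((ylo - origin[1] - eps) / spacing));
    int j1 = std::min(ny - 1, (int)std::floor((yhi - origin[1] + eps) / spacing));
    int k0 = std::max(0, (int)std::ceil((zlo - origin[2] - eps) / spacing));
    int k1 = std::min(nz - 1, (int)std::floor((zhi - origin[2] + eps) / spacing));
    for (int k = k0; k <= k1; ++k) {
      double rz = origin[2] + k * spacing + eps;
      for (int j = j0; j <= j1; ++j) {
        double ry = origin[1] + j * spacing + eps;
        // 2D barycentric test in the (y,z) plane
        double d = (by - ay) * (cz - az) - (cy - ay) * (bz - az);
        if (std::fabs(d) < 1e-300) continue;
        double l1 = ((ry - ay) * (cz - az) - (cy - ay) * (rz - az)) / d;
        double l2 = ((by - ay) * (rz - az) - (ry - ay) * (bz - az)) / d;
        if (l1 < 0.0 || l2 < 0.0 || l1 + l2 > 1.0) continue;
        double x = V(ia,0) + l1 * (V(ib,0) - V(ia,0)) + l2 * (V(ic,0) - V(ia,0));
        cross[k * ny + j].push_back(x);
      }
    }
  }
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      std::vector<double> &xs = cross[k * ny + j];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      size_t npair = xs.size() / 2;
      for (size_t q = 0; q < npair; ++q) {
        double x0 = xs[2*q], x1 = xs[2*q + 1];
        int i0 = std::max(0, (int)std::ceil((x0 - origin[0]) / spacing));
        int i1 = std::min(nx - 1, (int)std::floor((x1 - origin[0]) / spacing));
        for (int i = i0; i <= i1; ++i)
          out[i + nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return out;
}

// ---- 1D squared distance transform (Felzenszwalb & Huttenlocher) ----
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q*(double)q) - (f[v[k]] + v[k]*(double)v[k])) / (2.0*q - 2.0*v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k+1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k+1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq*dq + f[v[k]];
  }
}

// Exact Euclidean distance (voxel units * spacing) from every voxel to the
// nearest TRUE voxel of `mask`.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, double spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = 1e20;
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) g[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[i + nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) g[i + nx * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[i + nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) g[i + nx * (j + (R_xlen_t)ny * k)] = d[k];
    }
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = spacing * std::sqrt(g[i]);
  return out;
}

// ---- marching tetrahedra ----
// Iso-surface of a scalar field sampled on a regular grid, at `level`.
// Each grid cube is split into 6 tetrahedra sharing the (0,0,0)-(1,1,1)
// diagonal; this decomposition is face-consistent between neighbouring cubes,
// and interpolated edge vertices are shared through a global edge table, so
// the resulting mesh is watertight. Triangles are wound so normals point
// toward decreasing field values (outward for an inside>level indicator).
// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dim, double level,
                    double spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto gidx = [&](int i, int j, int k) -> long long {
    return i + (long long)nx * (j + (long long)ny * k);
  };
  static const int tets[6][4] = {
    {0,1,2,6}, {0,2,3,6}, {0,3,7,6}, {0,7,4,6}, {0,4,5,6}, {0,5,1,6}
  };
  // cube corner offsets, matching v0..v7 convention
  static const int off[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };
  std::unordered_map<long long, int> edge_vert;
  std::vector<double> verts;   // flat xyz
  std::vector<int> faces;      // flat, 0-based
  long long NG = (long long)nx * ny * nz;

  auto edge_point = [&](long long ga, long long gb, double fa, double fb,
                        const double *pa, const double *pb) -> int {
    long long a = ga, b = gb;
    const double *p0 = pa, *p1 = pb;
    double f0 = fa, f1 = fb;
    if (a > b) { std::swap(a, b); std::swap(f0, f1); const double *t = p0; p0 = p1; p1 = t; }
    long long key = a * NG + b;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = (level - f0) / (f1 - f0);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int id = (int)(verts.size() / 3);
    for (int d = 0; d < 3; ++d) verts.push_back(p0[d] + t * (p1[d] - p0[d]));
    edge_vert[key] = id;
    return id;
  };

  auto emit_tri = [&](int a, int b, int c, const double *inside_cent) {
    double *va = &verts[3*a], *vb = &verts[3*b], *vc = &verts[3*c];
    double u[3], w[3], nrm[3], cen[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = vb[d] - va[d];
      w[d] = vc[d] - va[d];
      cen[d] = (va[d] + vb[d] + vc[d]) / 3.0;
    }
    nrm[0] = u[1]*w[2] - u[2]*w[1];
    nrm[1] = u[2]*w[0] - u[0]*w[2];
    nrm[2] = u[0]*w[1] - u[1]*w[0];
    double dot = 0.0;
    for (int d = 0; d < 3; ++d) dot += nrm[d] * (inside_cent[d] - cen[d]);
    if (dot > 0.0) { faces.push_back(a); faces.push_back(c); faces.push_back(b); }
    else           { faces.push_back(a); faces.push_back(b); faces.push_back(c); }
  };

  double cf[8];          // corner field values
  double cp[8][3];       // corner positions
  long long cg[8];       // corner grid ids
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + off[c][0], jj = j + off[c][1], kk = k + off[c][2];
          cg[c] = gidx(ii, jj, kk);
          cf[c] = field[cg[c]];
          cp[c][0] = origin[0] + ii * spacing;
          cp[c][1] = origin[1] + jj * spacing;
          cp[c][2] = origin[2] + kk * spacing;
          if (cf[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cf[tv[c]] > level) in_idx[ni++] = tv[c];
            else out_idx[no++] = tv[c];
          }
          if (ni == 0 || ni == 4) continue;
          double icent[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int d = 0; d < 3; ++d) icent[d] += cp[in_idx[c]][d] / ni;
          if (ni == 1) {
            int A = in_idx[0];
            int e0 = edge_point(cg[A], cg[out_idx[0]], cf[A], cf[out_idx[0]], cp[A], cp[out_idx[0]]);
            int e1 = edge_point(cg[A], cg[out_idx[1]], cf[A], cf[out_idx[1]], cp[A], cp[out_idx[1]]);
            int e2 = edge_point(cg[A], cg[out_idx[2]], cf[A], cf[out_idx[2]], cp[A], cp[out_idx[2]]);
            emit_tri(e0, e1, e2, icent);
          } else if (ni == 3) {
            int D = out_idx[0];
            int e0 = edge_point(cg[in_idx[0]], cg[D], cf[in_idx[0]], cf[D], cp[in_idx[0]], cp[D]);
            int e1 = edge_point(cg[in_idx[1]], cg[D], cf[in_idx[1]], cf[D], cp[in_idx[1]], cp[D]);
            int e2 = edge_point(cg[in_idx[2]], cg[D], cf[in_idx[2]], cf[D], cp[in_idx[2]], cp[D]);
            emit_tri(e0, e1, e2, icent);
          } else { // ni == 2: quad AC, AD, BD, BC
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            int eac = edge_point(cg[A], cg[C], cf[A], cf[C], cp[A], cp[C]);
            int ead = edge_point(cg[A], cg[D], cf[A], cf[D], cp[A], cp[D]);
            int ebd = edge_point(cg[B], cg[D], cf[B], cf[D], cp[B], cp[D]);
            int ebc = edge_point(cg[B], cg[C], cf[B], cf[C], cp[B], cp[C]);
            emit_tri(eac, ead, ebd, icent);
            emit_tri(eac, ebd, ebc, icent);
          }
        }
      }
  int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix Vm(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) Vm(i, d) = verts[3*i + d];
  for (int i = 0; i < nf; ++i)
    for (int d = 0; d < 3; ++d) Fm(i, d) = faces[3*i + d] + 1;  // 1-based for R
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// Largest 6-connected component of a logical mask; also reports the number
// of components.
// [[Rcpp::export]]
List cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<int> lab(ntot, 0);
  int ncomp = 0;
  R_xlen_t best_size = 0;
  int best_lab = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++ncomp;
    R_xlen_t size = 0;
    stack.push_back(s);
    lab[s] = ncomp;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      ++size;
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      const int di[6] = {-1,1,0,0,0,0}, dj[6] = {0,0,-1,1,0,0}, dk[6] = {0,0,0,0,-1,1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t nb = ii + nx * (jj + (R_xlen_t)ny * kk);
        if (mask[nb] && !lab[nb]) { lab[nb] = ncomp; stack.push_back(nb); }
      }
    }
    if (size > best_size) { best_size = size; best_lab = ncomp; }
  }
  LogicalVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = (lab[i] == best_lab);
  return List::create(_["mask"] = out, _["n_components"] = ncomp);
}
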
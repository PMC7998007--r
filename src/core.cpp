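#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Max-flow (Dinic) on a voxel graph with symmetric n-links and terminal links.
// Nodes are 0-based voxel ids; source = n, sink = n + 1.
// Undirected n-links are stored as an arc pair with equal capacity in both
// directions, each arc acting as the other's residual.
// ---------------------------------------------------------------------------

struct DinicGraph {
  int n;                       // total nodes incl. terminals
  std::vector<int> head;
  std::vector<int> to, nxt;
  std::vector<double> cap;
  std::vector<int> level, iter;

  explicit DinicGraph(int n_) : n(n_), head(n_, -1) {}

  void add_arc(int u, int v, double c_uv, double c_vu) {
    to.push_back(v); cap.push_back(c_uv); nxt.push_back(head[u]); head[u] = (int)to.size() - 1;
    to.push_back(u); cap.push_back(c_vu); nxt.push_back(head[v]); head[v] = (int)to.size() - 1;
  }

  bool bfs(int s, int t) {
    level.assign(n, -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && level[to[e]] < 0) {
          level[to[e]] = level[u] + 1;
          q.push(to[e]);
        }
      }
    }
    return level[t] >= 0;
  }

  double dfs(int u, int t, double f) {
    if (u == t) return f;
    for (int &e = iter[u]; e != -1; e = nxt[e]) {
      int v = to[e];
      if (cap[e] > 1e-12 && level[v] == level[u] + 1) {
        double d = dfs(v, t, std::min(f, cap[e]));
        if (d > 0) {
          cap[e] -= d;
          cap[e ^ 1] += d;
          return d;
        }
      }
    }
    return 0.0;
  }

  double maxflow(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      iter = head;
      double f;
      while ((f = dfs(s, t, std::numeric_limits<double>::infinity())) > 0)
        flow += f;
    }
    return flow;
  }
};

// from/to: 0-based voxel ids of symmetric n-links with capacity weight[]
// src_idx/src_cap, sink_idx/sink_cap: terminal links (sparse)
// Returns integer vector: 1 = source side (foreground), 0 = sink side,
// attribute "flow" = max-flow value.
// [[Rcpp::export]]
IntegerVector cpp_mincut(int n_voxels,
                         IntegerVector from, IntegerVector to_,
                         NumericVector weight,
                         IntegerVector src_idx, NumericVector src_cap,
                         IntegerVector sink_idx, NumericVector sink_cap) {
  int s = n_voxels, t = n_voxels + 1;
  DinicGraph g(n_voxels + 2);
  size_t m = from.size();
  g.to.reserve(2 * (m + src_idx.size() + sink_idx.size()));
  for (size_t e = 0; e < m; ++e)
    g.add_arc(from[e], to_[e], weight[e], weight[e]);
  for (int e = 0; e < src_idx.size(); ++e)
    g.add_arc(s, src_idx[e], src_cap[e], 0.0);
  for (int e = 0; e < sink_idx.size(); ++e)
    g.add_arc(sink_idx[e], t, sink_cap[e], 0.0);

  double flow = g.maxflow(s, t);

  // residual reachability from source
  IntegerVector lab(n_voxels, 0);
  std::vector<char> vis(g.n, 0);
  std::queue<int> q;
  vis[s] = 1; q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int e = g.head[u]; e != -1; e = g.nxt[e]) {
      int v = g.to[e];
      if (g.cap[e] > 1e-12 && !vis[v]) { vis[v] = 1; q.push(v); }
    }
  }
  for (int v = 0; v < n_voxels; ++v) lab[v] = vis[v] ? 1 : 0;
  lab.attr("flow") = flow;
  return lab;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb-Huttenlocher), spacing-
// aware: returns for every voxel the squared distance in mm^2 to the nearest
// feature (TRUE) voxel. All-false input returns +Inf everywhere.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  // the lower-envelope recursion needs finite inputs: track "no feature yet"
  // with a large finite sentinel and restore +Inf at the end
  const double BIG = 1e30;
  const double INF = BIG;
  std::vector<double> d(n);
  for (size_t i = 0; i < n; ++i) d[i] = feature[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = d[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, dd, v, z, nx, spacing[0] * spacing[0]);
      for (int i = 0; i < nx; ++i) d[base + i] = dd[i];
    }
  // y axis
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)k * nx * ny + i;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = d[base + (size_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, dd, v, z, ny, spacing[1] * spacing[1]);
      for (int j = 0; j < ny; ++j) d[base + (size_t)j * nx] = dd[j];
    }
  // z axis
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = d[base + (size_t)k * nx * ny]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, dd, v, z, nz, spacing[2] * spacing[2]);
      for (int k = 0; k < nz; ++k) d[base + (size_t)k * nx * ny] = dd[k];
    }

  NumericVector out(n);
  const double inf = std::numeric_limits<double>::infinity();
  for (size_t i = 0; i < n; ++i) out[i] = (d[i] >= BIG * 0.5) ? inf : d[i];
  return out;
}

// ---------------------------------------------------------------------------
// Median filter over the axis-aligned cross neighbourhood of arm length
// `radius`, replicate (clamp) padding at faces; axes of length 1 contribute
// no neighbours. Median of an even count is the mean of the two middle values.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_median_cross(NumericVector vol, IntegerVector dim, int radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  std::vector<double> vals;
  vals.reserve(6 * radius + 1);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = (size_t)k * nx * ny + (size_t)j * nx + i;
        vals.clear();
        vals.push_back(vol[idx]);
        for (int o = 1; o <= radius; ++o) {
          if (nx > 1) {
            int il = std::max(i - o, 0), ir = std::min(i + o, nx - 1);
            vals.push_back(vol[(size_t)k * nx * ny + (size_t)j * nx + il]);
            vals.push_back(vol[(size_t)k * nx * ny + (size_t)j * nx + ir]);
          }
          if (ny > 1) {
            int jl = std::max(j - o, 0), jr = std::min(j + o, ny - 1);
            vals.push_back(vol[(size_t)k * nx * ny + (size_t)jl * nx + i]);
            vals.push_back(vol[(size_t)k * nx * ny + (size_t)jr * nx + i]);
          }
          if (nz > 1) {
            int kl = std::max(k - o, 0), kr = std::min(k + o, nz - 1);
            vals.push_back(vol[(size_t)kl * nx * ny + (size_t)j * nx + i]);
            vals.push_back(vol[(size_t)kr * nx * ny + (size_t)j * nx + i]);
          }
        }
        size_t m = vals.size();
        std::nth_element(vals.begin(), vals.begin() + m / 2, vals.end());
        double med = vals[m / 2];
        if (m % 2 == 0) {
          double lo = *std::max_element(vals.begin(), vals.begin() + m / 2);
          med = 0.5 * (med + lo);
        }
        out[idx] = med;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface of a binary mask at level 0.5 by tetrahedral marching: each
// lattice cube is split into the six Kuhn tetrahedra around the main diagonal
// (a face-consistent tiling, so the mesh is watertight); surface vertices lie
// at midpoints of lattice edges and are welded by exact midpoint key.
// Triangles are oriented with outward normals (away from the inside corner).
// The mask is zero-padded internally so surfaces at the grid boundary close.
// Output vertices are 0-based voxel-centre coordinates.
// ---------------------------------------------------------------------------

struct MeshAcc {
  std::unordered_map<uint64_t, int> key2id;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  int vertex(double x, double y, double z) {
    // coordinates are multiples of 0.5 >= -1; shift and double to get exact keys
    uint64_t kx = (uint64_t)llround((x + 2.0) * 2.0);
    uint64_t ky = (uint64_t)llround((y + 2.0) * 2.0);
    uint64_t kz = (uint64_t)llround((z + 2.0) * 2.0);
    uint64_t key = (kx << 42) | (ky << 21) | kz;
    auto it = key2id.find(key);
    if (it != key2id.end()) return it->second;
    int id = (int)vx.size();
    key2id.emplace(key, id);
    vx.push_back(x); vy.push_back(y); vz.push_back(z);
    return id;
  }

  void add(int a, int b, int c) { tri.push_back(a); tri.push_back(b); tri.push_back(c); }
};

// [[Rcpp::export]]
List cpp_marching_tets(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  std::vector<char> m((size_t)px * py * pz, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        m[(size_t)(k + 1) * px * py + (size_t)(j + 1) * px + (i + 1)] =
          mask[(size_t)k * nx * ny + (size_t)j * nx + i] ? 1 : 0;

  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};

  MeshAcc acc;
  double cx[8], cy[8], cz[8];
  int cv[8];

  for (int k = 0; k < pz - 1; ++k)
    for (int j = 0; j < py - 1; ++j)
      for (int i = 0; i < px - 1; ++i) {
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner[c][0], jj = j + corner[c][1], kk = k + corner[c][2];
          cv[c] = m[(size_t)kk * px * py + (size_t)jj * px + ii];
          cx[c] = ii - 1.0; cy[c] = jj - 1.0; cz[c] = kk - 1.0;  // un-pad
          nin += cv[c];
        }
        if (nin == 0 || nin == 8) continue;

        for (int t = 0; t < 6; ++t) {
          int tid[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int ins[4], nins = 0;
          for (int c = 0; c < 4; ++c) { ins[c] = cv[tid[c]]; nins += ins[c]; }
          if (nins == 0 || nins == 4) continue;

          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) (ins[c] ? in_idx[ni++] : out_idx[no++]) = tid[c];

          auto mid = [&](int a, int b, double p[3]) {
            p[0] = 0.5 * (cx[a] + cx[b]);
            p[1] = 0.5 * (cy[a] + cy[b]);
            p[2] = 0.5 * (cz[a] + cz[b]);
          };
          auto orient_add = [&](double p0[3], double p1[3], double p2[3],
                                double inx, double iny, double inz) {
            // outward: normal opposes the direction toward the inside point
            double ux = p1[0]-p0[0], uy = p1[1]-p0[1], uz = p1[2]-p0[2];
            double wx = p2[0]-p0[0], wy = p2[1]-p0[1], wz = p2[2]-p0[2];
            double nxn = uy*wz - uz*wy, nyn = uz*wx - ux*wz, nzn = ux*wy - uy*wx;
            double dot = nxn*(inx-p0[0]) + nyn*(iny-p0[1]) + nzn*(inz-p0[2]);
            int a = acc.vertex(p0[0], p0[1], p0[2]);
            int b = acc.vertex(p1[0], p1[1], p1[2]);
            int c = acc.vertex(p2[0], p2[1], p2[2]);
            if (dot < 0) acc.add(a, b, c); else acc.add(a, c, b);
          };

          double p0[3], p1[3], p2[3], p3[3];
          if (nins == 1) {
            int a = in_idx[0];
            mid(a, out_idx[0], p0); mid(a, out_idx[1], p1); mid(a, out_idx[2], p2);
            orient_add(p0, p1, p2, cx[a], cy[a], cz[a]);
          } else if (nins == 3) {
            int o = out_idx[0];
            mid(in_idx[0], o, p0); mid(in_idx[1], o, p1); mid(in_idx[2], o, p2);
            // inside reference: any inside corner
            orient_add(p0, p1, p2, cx[in_idx[0]], cy[in_idx[0]], cz[in_idx[0]]);
          } else {  // 2 in, 2 out -> quad split into two triangles
            int a = in_idx[0], b = in_idx[1], c = out_idx[0], d = out_idx[1];
            mid(a, c, p0); mid(a, d, p1); mid(b, d, p2); mid(b, c, p3);
            orient_add(p0, p1, p2, cx[a], cy[a], cz[a]);
            orient_add(p0, p2, p3, cx[a], cy[a], cz[a]);
          }
        }
      }

  int nv = (int)acc.vx.size(), nt = (int)acc.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v,0)=acc.vx[v]; V(v,1)=acc.vy[v]; V(v,2)=acc.vz[v]; }
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t) {
    T(t,0) = acc.tri[3*t] + 1; T(t,1) = acc.tri[3*t+1] + 1; T(t,2) = acc.tri[3*t+2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}

// ---------------------------------------------------------------------------
// Seeded region growing: breadth-first flood fill accepting voxels whose
// intensity is within `tol` of the running mean of the accepted region; the
// mean is updated once per frontier generation (order-independent).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              IntegerVector seeds0, double tol,
                              IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> in(n, 0);
  std::vector<int> frontier, next;
  double sum = 0.0; size_t cnt = 0;
  for (int s = 0; s < seeds0.size(); ++s) {
    int id = seeds0[s];
    if (!in[id]) { in[id] = 1; frontier.push_back(id); sum += vol[id]; ++cnt; }
  }
  while (!frontier.empty()) {
    double mean = sum / cnt;
    next.clear();
    for (int id : frontier) {
      int i = id % nx, j = (id / nx) % ny, k = id / (nx * ny);
      for (int o = 0; o < offsets.nrow(); ++o) {
        int ii = i + offsets(o,0), jj = j + offsets(o,1), kk = k + offsets(o,2);
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t nid = (size_t)kk * nx * ny + (size_t)jj * nx + ii;
        if (in[nid]) continue;
        if (std::fabs(vol[nid] - mean) <= tol) {
          in[nid] = 1;
          next.push_back((int)nid);
          sum += vol[nid]; ++cnt;
        }
      }
    }
    frontier.swap(next);
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = in[i] != 0;
  return out;
}
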
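// Isosurface extraction and mesh utilities.
//
// Marching cubes for binary grids at level 0.5: the per-configuration
// triangulation is derived constructively at first use (marching squares on
// each cube face with the foreground-diagonal-connected tie rule, chords
// chained into closed loops, fan triangulation), so neighbouring cells agree
// on shared faces and the mesh is watertight. Triangle orientation is fixed
// per triangle from the trilinear gradient of the corner values (normals
// point from foreground to background). Vertices sit on cube-edge midpoints.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

const int EDGE_CORNERS[12][2] = {
  {0,1},{1,2},{2,3},{3,0},{4,5},{5,6},{6,7},{7,4},{0,4},{1,5},{2,6},{3,7}
};
// corner offsets (x,y,z)
const int CORNER_OFF[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
// faces: corner cycle and matching edge cycle (edge i joins corner i and i+1)
const int FACE_CORNERS[6][4] = {
  {0,1,2,3},{4,5,6,7},{0,1,5,4},{3,2,6,7},{0,3,7,4},{1,2,6,5}
};
const int FACE_EDGES[6][4] = {
  {0,1,2,3},{4,5,6,7},{0,9,4,8},{2,10,6,11},{3,11,7,8},{1,10,5,9}
};
// global identity of each cell edge: (dx, dy, dz, axis) of the edge's base voxel
const int EDGE_BASE[12][4] = {
  {0,0,0,0},{1,0,0,1},{0,1,0,0},{0,0,0,1},
  {0,0,1,0},{1,0,1,1},{0,1,1,0},{0,0,1,1},
  {0,0,0,2},{1,0,0,2},{1,1,0,2},{0,1,0,2}
};

// case table: for each of 256 configs, list of triangles as edge-index triples
static std::vector<std::array<int,3>> CASE_TRIS[256];
static bool table_ready = false;

static void face_chords(int config, int f, std::vector<std::pair<int,int>>& chords) {
  bool in[4];
  for (int i = 0; i < 4; ++i) in[i] = (config >> FACE_CORNERS[f][i]) & 1;
  const int* e = FACE_EDGES[f];
  int cnt = in[0] + in[1] + in[2] + in[3];
  if (cnt == 0 || cnt == 4) return;
  if (cnt == 1 || cnt == 3) {
    // single inside (or single outside) corner x: chord joins the two edges
    // adjacent to x
    int x = -1;
    for (int i = 0; i < 4; ++i) if (in[i] == (cnt == 1)) x = i;
    chords.push_back({ e[x], e[(x + 3) % 4] });
  } else {
    // two inside corners
    if (in[0] == in[2]) { // diagonal: chords cut off each outside corner
      int o1 = in[0] ? 1 : 0, o2 = o1 + 2;
      chords.push_back({ e[o1], e[(o1 + 3) % 4] });
      chords.push_back({ e[o2], e[(o2 + 3) % 4] });
    } else {
      // adjacent pair: chord joins the two cut edges
      int cut[2], k = 0;
      for (int i = 0; i < 4; ++i)
        if (in[i] != in[(i + 1) % 4]) cut[k++] = e[i];
      chords.push_back({ cut[0], cut[1] });
    }
  }
}

static void build_case_table() {
  for (int config = 0; config < 256; ++config) {
    CASE_TRIS[config].clear();
    if (config == 0 || config == 255) continue;
    std::vector<std::pair<int,int>> chords;
    for (int f = 0; f < 6; ++f) face_chords(config, f, chords);
    // adjacency: every cut edge appears in exactly two chords
    std::vector<std::vector<int>> adj(12);
    for (auto& c : chords) { adj[c.first].push_back(c.second); adj[c.second].push_back(c.first); }
    bool used[12] = {false};
    for (int start = 0; start < 12; ++start) {
      if (adj[start].empty() || used[start]) continue;
      std::vector<int> loop;
      int prev = -1, cur = start;
      do {
        loop.push_back(cur);
        used[cur] = true;
        int nxt = (adj[cur][0] != prev) ? adj[cur][0] : adj[cur][1];
        prev = cur;
        cur = nxt;
      } while (cur != start);
      for (size_t i = 1; i + 1 < loop.size(); ++i)
        CASE_TRIS[config].push_back({ loop[0], loop[i], loop[i + 1] });
    }
  }
  table_ready = true;
}

static inline void edge_midpoint(int e, double* p) {
  const int* a = CORNER_OFF[EDGE_CORNERS[e][0]];
  const int* b = CORNER_OFF[EDGE_CORNERS[e][1]];
  p[0] = 0.5 * (a[0] + b[0]);
  p[1] = 0.5 * (a[1] + b[1]);
  p[2] = 0.5 * (a[2] + b[2]);
}

// gradient of the trilinear interpolant of the 8 corner values at local (x,y,z)
static void tri_gradient(const double* c, double x, double y, double z, double* g) {
  // corner order c0..c7 as CORNER_OFF
  double c000=c[0], c100=c[1], c110=c[2], c010=c[3], c001=c[4], c101=c[5], c111=c[6], c011=c[7];
  g[0] = (1-y)*(1-z)*(c100-c000) + y*(1-z)*(c110-c010) + (1-y)*z*(c101-c001) + y*z*(c111-c011);
  g[1] = (1-x)*(1-z)*(c010-c000) + x*(1-z)*(c110-c100) + (1-x)*z*(c011-c001) + x*z*(c111-c101);
  g[2] = (1-x)*(1-y)*(c001-c000) + x*(1-y)*(c101-c100) + (1-x)*y*(c011-c010) + x*y*(c111-c110);
}

} // namespace

// [[Rcpp::export]]
List cpp_marching_cubes(LogicalVector grid, IntegerVector dim) {
  if (!table_ready) build_case_table();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto gid = [&](int x, int y, int z) {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  };
  std::unordered_map<long long, int> vert_id;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  double P[3][3], g[3], cv[8];
  for (int z = 0; z < nz - 1; ++z) for (int y = 0; y < ny - 1; ++y) for (int x = 0; x < nx - 1; ++x) {
    int config = 0;
    for (int c = 0; c < 8; ++c) {
      bool v = grid[gid(x + CORNER_OFF[c][0], y + CORNER_OFF[c][1], z + CORNER_OFF[c][2])];
      cv[c] = v ? 1.0 : 0.0;
      if (v) config |= (1 << c);
    }
    if (config == 0 || config == 255) continue;
    for (auto& tri : CASE_TRIS[config]) {
      int ids[3];
      double cent[3] = {0, 0, 0};
      for (int k = 0; k < 3; ++k) {
        int e = tri[k];
        const int* eb = EDGE_BASE[e];
        long long key = 3LL * ((( (long long)(z + eb[2]) * ny + (y + eb[1]) ) * nx) + (x + eb[0])) + eb[3];
        auto it = vert_id.find(key);
        int id;
        if (it == vert_id.end()) {
          double p[3];
          edge_midpoint(e, p);
          id = (int)vx.size();
          vx.push_back(x + p[0]); vy.push_back(y + p[1]); vz.push_back(z + p[2]);
          vert_id.emplace(key, id);
        } else id = it->second;
        ids[k] = id;
        double pl[3];
        edge_midpoint(e, pl);
        for (int d = 0; d < 3; ++d) { P[k][d] = pl[d]; cent[d] += pl[d] / 3.0; }
      }
      // orient: normal must point toward decreasing field (outside)
      double u[3] = { P[1][0]-P[0][0], P[1][1]-P[0][1], P[1][2]-P[0][2] };
      double w[3] = { P[2][0]-P[0][0], P[2][1]-P[0][1], P[2][2]-P[0][2] };
      double nvec[3] = { u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0] };
      tri_gradient(cv, cent[0], cent[1], cent[2], g);
      bool flip = (nvec[0]*g[0] + nvec[1]*g[1] + nvec[2]*g[2]) > 0;
      f0.push_back(ids[0] + 1);
      f1.push_back(flip ? ids[2] + 1 : ids[1] + 1);
      f2.push_back(flip ? ids[1] + 1 : ids[2] + 1);
    }
  }
  NumericMatrix V(vx.size(), 3);
  for (size_t i = 0; i < vx.size(); ++i) { V(i,0)=vx[i]; V(i,1)=vy[i]; V(i,2)=vz[i]; }
  IntegerMatrix F(f0.size(), 3);
  for (size_t i = 0; i < f0.size(); ++i) { F(i,0)=f0[i]; F(i,1)=f1[i]; F(i,2)=f2[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Taubin lambda/mu smoothing with uniform weights.
// [[Rcpp::export]]
NumericMatrix cpp_taubin(NumericMatrix verts, IntegerMatrix faces,
                         double lambda, double mu, int iterations) {
  int n = verts.nrow(), m = faces.nrow();
  // adjacency (undirected, dedup via sorted neighbour insert)
  std::vector<std::vector<int>> adj(n);
  auto add = [&](int a, int b) {
    auto& v = adj[a];
    for (int x : v) if (x == b) return;
    v.push_back(b);
  };
  for (int i = 0; i < m; ++i) {
    int a = faces(i,0)-1, b = faces(i,1)-1, c = faces(i,2)-1;
    add(a,b); add(b,a); add(b,c); add(c,b); add(a,c); add(c,a);
  }
  std::vector<double> X(n), Y(n), Z(n), X2(n), Y2(n), Z2(n);
  for (int i = 0; i < n; ++i) { X[i]=verts(i,0); Y[i]=verts(i,1); Z[i]=verts(i,2); }
  auto step = [&](double fac, std::vector<double>& x, std::vector<double>& y, std::vector<double>& z,
                  std::vector<double>& ox, std::vector<double>& oy, std::vector<double>& oz) {
    for (int i = 0; i < n; ++i) {
      if (adj[i].empty()) { ox[i]=x[i]; oy[i]=y[i]; oz[i]=z[i]; continue; }
      double mx=0,my=0,mz=0;
      for (int j : adj[i]) { mx+=x[j]; my+=y[j]; mz+=z[j]; }
      double k = 1.0/adj[i].size();
      ox[i] = x[i] + fac*(mx*k - x[i]);
      oy[i] = y[i] + fac*(my*k - y[i]);
      oz[i] = z[i] + fac*(mz*k - z[i]);
    }
  };
  for (int it = 0; it < iterations; ++it) {
    step(lambda, X, Y, Z, X2, Y2, Z2);
    step(mu, X2, Y2, Z2, X, Y, Z);
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0)=X[i]; out(i,1)=Y[i]; out(i,2)=Z[i]; }
  return out;
}

// total surface area and signed enclosed volume (divergence theorem)
// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericMatrix verts, IntegerMatrix faces) {
  double area = 0, vol = 0;
  for (int i = 0; i < faces.nrow(); ++i) {
    int a = faces(i,0)-1, b = faces(i,1)-1, c = faces(i,2)-1;
    double p0[3] = { verts(a,0), verts(a,1), verts(a,2) };
    double p1[3] = { verts(b,0), verts(b,1), verts(b,2) };
    double p2[3] = { verts(c,0), verts(c,1), verts(c,2) };
    double u[3] = { p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2] };
    double w[3] = { p2[0]-p0[0], p2[1]-p0[1], p2[2]-p0[2] };
    double cr[3] = { u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0] };
    area += 0.5 * std::sqrt(cr[0]*cr[0] + cr[1]*cr[1] + cr[2]*cr[2]);
    vol += (p0[0]*(p1[1]*p2[2]-p1[2]*p2[1])
          - p0[1]*(p1[0]*p2[2]-p1[2]*p2[0])
          + p0[2]*(p1[0]*p2[1]-p1[1]*p2[0])) / 6.0;
  }
  return NumericVector::create(area, vol);
}

// vertices + triangle centroids; surface sample set for box counting
// (triangles are smaller than the finest counting box, so this covers every
// box the surface touches)
// [[Rcpp::export]]
NumericMatrix cpp_mesh_surface_points(NumericMatrix verts, IntegerMatrix faces) {
  int n = verts.nrow(), m = faces.nrow();
  NumericMatrix out(n + m, 3);
  for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) out(i, d) = verts(i, d);
  for (int i = 0; i < m; ++i) {
    int a = faces(i,0)-1, b = faces(i,1)-1, c = faces(i,2)-1;
    for (int d = 0; d < 3; ++d)
      out(n + i, d) = (verts(a,d) + verts(b,d) + verts(c,d)) / 3.0;
  }
  return out;
}
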
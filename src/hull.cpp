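// 3D convex hull (quickhull with per-face outside sets); returns the hull's
// triangulated surface area and enclosed volume.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
using namespace Rcpp;

namespace {

struct Vec3 { double x, y, z; };
static inline Vec3 sub(const Vec3& a, const Vec3& b) { return { a.x-b.x, a.y-b.y, a.z-b.z }; }
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return { a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x };
}
static inline double dot(const Vec3& a, const Vec3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;
  Vec3 n;           // unit outward normal
  double d;         // plane offset: dot(n, p) = d on the plane
  bool alive;
  std::vector<int> outside;
};

static void face_plane(Face& f, const std::vector<Vec3>& P) {
  Vec3 n = cross(sub(P[f.b], P[f.a]), sub(P[f.c], P[f.a]));
  double ln = norm(n);
  if (ln > 0) { n.x /= ln; n.y /= ln; n.z /= ln; }
  f.n = n;
  f.d = dot(n, P[f.a]);
}

} // namespace

// Support points of a cloud along a deterministic Fibonacci-lattice direction
// set; every returned point is an extreme point (true hull vertex).
// [[Rcpp::export]]
NumericMatrix cpp_support_points(NumericMatrix pts, int n_dir) {
  int n = pts.nrow();
  std::vector<double> dx(n_dir), dy(n_dir), dz(n_dir);
  const double ga = M_PI * (1.0 + std::sqrt(5.0));
  for (int j = 0; j < n_dir; ++j) {
    double i = j + 0.5;
    double phi = std::acos(1.0 - 2.0 * i / n_dir);
    double th = ga * i;
    dx[j] = std::sin(phi) * std::cos(th);
    dy[j] = std::sin(phi) * std::sin(th);
    dz[j] = std::cos(phi);
  }
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = pts(i,0); py[i] = pts(i,1); pz[i] = pts(i,2); }
  std::vector<int> best(n_dir, 0);
  for (int j = 0; j < n_dir; ++j) {
    const double ax = dx[j], ay = dy[j], az = dz[j];
    double bv = -1e300; int bi = 0;
    for (int i = 0; i < n; ++i) {
      double s = px[i]*ax + py[i]*ay + pz[i]*az;
      if (s > bv) { bv = s; bi = i; }
    }
    best[j] = bi;
  }
  std::vector<char> keep(n, 0);
  for (int j = 0; j < n_dir; ++j) keep[best[j]] = 1;
  int k = 0;
  for (int i = 0; i < n; ++i) k += keep[i];
  NumericMatrix out(k, 3);
  for (int i = 0, p = 0; i < n; ++i) if (keep[i]) {
    out(p,0) = pts(i,0); out(p,1) = pts(i,1); out(p,2) = pts(i,2);
    ++p;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_convex_hull(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<Vec3> P(n);
  double scale = 0;
  for (int i = 0; i < n; ++i) {
    P[i] = { pts(i,0), pts(i,1), pts(i,2) };
    scale = std::max(scale, std::abs(P[i].x) + std::abs(P[i].y) + std::abs(P[i].z));
  }
  const double eps = 1e-10 * std::max(scale, 1.0);

  // initial simplex: extreme pair, farthest from line, farthest from plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (P[i].x < P[i0].x) i0 = i;
    if (P[i].x > P[i1].x) i1 = i;
  }
  if (i0 == i1) { for (int i = 1; i < n; ++i) if (P[i].y < P[i0].y || P[i].z < P[i0].z) { i1 = i; break; } }
  int i2 = -1; double best = eps;
  Vec3 dir = sub(P[i1], P[i0]);
  for (int i = 0; i < n; ++i) {
    double dl = norm(cross(dir, sub(P[i], P[i0])));
    if (dl > best) { best = dl; i2 = i; }
  }
  if (i2 < 0) stop("degenerate (collinear) point set");
  int i3 = -1; best = eps;
  Vec3 nrm = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
  double ln = norm(nrm);
  nrm.x /= ln; nrm.y /= ln; nrm.z /= ln;
  double dpl = dot(nrm, P[i0]);
  for (int i = 0; i < n; ++i) {
    double dd = std::abs(dot(nrm, P[i]) - dpl);
    if (dd > best) { best = dd; i3 = i; }
  }
  if (i3 < 0) stop("degenerate (coplanar) point set");

  std::vector<Face> faces;
  Vec3 centroid = { (P[i0].x+P[i1].x+P[i2].x+P[i3].x)/4.0,
                    (P[i0].y+P[i1].y+P[i2].y+P[i3].y)/4.0,
                    (P[i0].z+P[i1].z+P[i2].z+P[i3].z)/4.0 };
  auto add_face = [&](int a, int b, int c) {
    Face f; f.a = a; f.b = b; f.c = c; f.alive = true;
    face_plane(f, P);
    if (dot(f.n, centroid) - f.d > 0) { std::swap(f.b, f.c); face_plane(f, P); }
    faces.push_back(f);
    return (int)faces.size() - 1;
  };
  add_face(i0, i1, i2); add_face(i0, i1, i3); add_face(i0, i2, i3); add_face(i1, i2, i3);

  // assign points to outside sets
  for (int i = 0; i < n; ++i) {
    for (auto& f : faces) {
      if (dot(f.n, P[i]) - f.d > eps) { f.outside.push_back(i); break; }
    }
  }

  std::vector<int> pending;
  for (int fi = 0; fi < (int)faces.size(); ++fi)
    if (!faces[fi].outside.empty()) pending.push_back(fi);

  while (!pending.empty()) {
    int fi = pending.back(); pending.pop_back();
    if (fi >= (int)faces.size() || !faces[fi].alive || faces[fi].outside.empty()) continue;
    Face& f = faces[fi];
    // farthest point
    int far = f.outside[0];
    double fd = dot(f.n, P[far]) - f.d;
    for (int i : f.outside) {
      double dd = dot(f.n, P[i]) - f.d;
      if (dd > fd) { fd = dd; far = i; }
    }
    // visible faces (for a point outside a convex polytope the visible set is
    // exactly the faces whose plane it is above)
    std::vector<int> visible, orphan;
    for (int k = 0; k < (int)faces.size(); ++k) {
      if (!faces[k].alive) continue;
      if (dot(faces[k].n, P[far]) - faces[k].d > eps) visible.push_back(k);
    }
    // horizon: edges used exactly once among visible faces (directed edges,
    // count undirected)
    std::map<std::pair<int,int>, std::pair<int,int>> edge_count; // key sorted, val (count, a, keeps orientation of first)
    std::map<std::pair<int,int>, std::pair<int,int>> first_dir;
    for (int k : visible) {
      int e[3][2] = { { faces[k].a, faces[k].b }, { faces[k].b, faces[k].c }, { faces[k].c, faces[k].a } };
      for (auto& ed : e) {
        auto key = std::minmax(ed[0], ed[1]);
        auto it = edge_count.find(key);
        if (it == edge_count.end()) {
          edge_count[key] = {1, 0};
          first_dir[key] = { ed[0], ed[1] };
        } else it->second.first += 1;
      }
    }
    for (int k : visible) {
      for (int i : faces[k].outside) if (i != far) orphan.push_back(i);
      faces[k].alive = false;
      faces[k].outside.clear();
    }
    std::vector<int> fresh;
    for (auto& kv : edge_count) {
      if (kv.second.first != 1) continue;
      auto dirn = first_dir[kv.first];
      // new face keeps the winding of the dying face's horizon edge
      int nf = add_face(dirn.first, dirn.second, far);
      fresh.push_back(nf);
    }
    for (int i : orphan) {
      for (int k : fresh) {
        Face& g = faces[k];
        if (dot(g.n, P[i]) - g.d > eps) { g.outside.push_back(i); break; }
      }
    }
    for (int k : fresh) if (!faces[k].outside.empty()) pending.push_back(k);
  }

  double area = 0, vol = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    Vec3 u = sub(P[f.b], P[f.a]), w = sub(P[f.c], P[f.a]);
    Vec3 cr = cross(u, w);
    area += 0.5 * norm(cr);
    vol += (P[f.a].x*(P[f.b].y*P[f.c].z - P[f.b].z*P[f.c].y)
          - P[f.a].y*(P[f.b].x*P[f.c].z - P[f.b].z*P[f.c].x)
          + P[f.a].z*(P[f.b].x*P[f.c].y - P[f.b].y*P[f.c].x)) / 6.0;
  }
  return NumericVector::create(area, std::abs(vol));
}
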
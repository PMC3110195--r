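#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_set>
using namespace Rcpp;

struct V3 { double x, y, z; };
static inline V3 vsub(const V3 &a, const V3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 vcross(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double vnorm(const V3 &a) { return std::sqrt(vdot(a, a)); }

struct Face {
  int a, b, c;
  V3 n;        // outward (unnormalised) normal
  double off;  // plane offset dot(n, P[a])
  bool alive;
};

// Surface area and volume of the convex hull of a 3-D point set.
// Incremental construction; returns ok = false for degenerate input
// (fewer than 4 points, collinear or coplanar sets).
// [[Rcpp::export]]
List hull_metrics_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return List::create(_["ok"] = false, _["reason"] = "fewer than 4 points");
  std::vector<V3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};

  V3 cen = {0, 0, 0};
  for (int i = 0; i < n; ++i) { cen.x += P[i].x; cen.y += P[i].y; cen.z += P[i].z; }
  cen.x /= n; cen.y /= n; cen.z /= n;
  double scale = 0;
  for (int i = 0; i < n; ++i) scale = std::max(scale, vnorm(vsub(P[i], cen)));
  const double eps = 1e-9 * std::max(scale, 1.0);

  // initial simplex: two extreme points, farthest from the line, farthest from the plane
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n; ++i) if (P[i].x < P[i0].x) i0 = i;
  double best = -1;
  for (int i = 0; i < n; ++i) {
    double d = vnorm(vsub(P[i], P[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (best < eps) return List::create(_["ok"] = false, _["reason"] = "all points coincide");
  V3 d01 = vsub(P[i1], P[i0]);
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = vnorm(vcross(d01, vsub(P[i], P[i0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (best < eps * vnorm(d01))
    return List::create(_["ok"] = false, _["reason"] = "points are collinear");
  V3 nrm = vcross(d01, vsub(P[i2], P[i0]));
  double nl = vnorm(nrm);
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(vdot(nrm, vsub(P[i], P[i0]))) / nl;
    if (d > best) { best = d; i3 = i; }
  }
  if (best < eps)
    return List::create(_["ok"] = false, _["reason"] = "points are coplanar");

  std::vector<Face> faces;
  faces.reserve(8 * n);
  auto add_face = [&](int a, int b, int c) {
    V3 nn = vcross(vsub(P[b], P[a]), vsub(P[c], P[a]));
    faces.push_back({a, b, c, nn, vdot(nn, P[a]), true});
  };
  // orient each tetrahedron face so the opposite vertex lies below it
  int tet[4] = {i0, i1, i2, i3};
  int opp[4][4] = {{0, 1, 2, 3}, {0, 3, 1, 2}, {0, 2, 3, 1}, {1, 3, 2, 0}};
  for (int f = 0; f < 4; ++f) {
    int a = tet[opp[f][0]], b = tet[opp[f][1]], c = tet[opp[f][2]], d = tet[opp[f][3]];
    V3 nn = vcross(vsub(P[b], P[a]), vsub(P[c], P[a]));
    if (vdot(nn, vsub(P[d], P[a])) > 0) std::swap(b, c);
    add_face(a, b, c);
  }

  std::vector<int> visible;
  std::unordered_set<long long> vis_edges;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double d = vdot(faces[f].n, P[p]) - faces[f].off;
      if (d > eps * vnorm(faces[f].n)) visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    vis_edges.clear();
    auto key = [&](int u, int v) { return (long long)u * (long long)n + v; };
    for (int f : visible) {
      vis_edges.insert(key(faces[f].a, faces[f].b));
      vis_edges.insert(key(faces[f].b, faces[f].c));
      vis_edges.insert(key(faces[f].c, faces[f].a));
    }
    for (int f : visible) faces[f].alive = false;
    for (int f : visible) {
      int e[3][2] = {{faces[f].a, faces[f].b}, {faces[f].b, faces[f].c}, {faces[f].c, faces[f].a}};
      for (int k = 0; k < 3; ++k) {
        int u = e[k][0], v = e[k][1];
        if (vis_edges.find(key(v, u)) == vis_edges.end()) add_face(u, v, p);
      }
    }
  }

  double area = 0, vol = 0;
  int nf = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    ++nf;
    V3 a = vsub(P[faces[f].a], cen), b = vsub(P[faces[f].b], cen), c = vsub(P[faces[f].c], cen);
    V3 cr = vcross(vsub(b, a), vsub(c, a));
    area += 0.5 * vnorm(cr);
    vol += vdot(a, vcross(b, c)) / 6.0;
  }
  return List::create(_["ok"] = true, _["area"] = area, _["volume"] = vol,
                      _["n_faces"] = nf);
}

// Summed switched Lennard-Jones + Debye-screened Coulomb over atom
// pairs. pair_mode: 0 = inter-chain pairs plus intra-chain pairs not
// excluded (excl is a 1-based two-column index matrix of excluded
// intra-chain pairs), 1 = only pairs between chain group 1 and group 2
// (group vector: 1, 2 or 0 = ignore).
// [[Rcpp::export]]
List nonbonded_sum_cpp(NumericMatrix xyz, NumericVector sigma,
                       NumericVector eps, NumericVector q,
                       IntegerVector chain, IntegerMatrix excl,
                       IntegerVector group, int pair_mode,
                       double debye_length, double r_on, double r_off,
                       double r_floor) {
  const int n = xyz.nrow();
  const double on2 = r_on * r_on, off2 = r_off * r_off;
  const double denom = (off2 - on2) * (off2 - on2) * (off2 - on2);
  const double kE = 332.0636;
  const bool screened = R_finite(debye_length);
  std::vector<std::vector<int> > ex(n);
  for (int k = 0; k < excl.nrow(); ++k) {
    int a = excl(k, 0) - 1, b = excl(k, 1) - 1;
    ex[a].push_back(b);
  }
  for (int i = 0; i < n; ++i) std::sort(ex[i].begin(), ex[i].end());
  double vdw = 0, elec = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (pair_mode == 1) {
        int gi = group[i], gj = group[j];
        if (!((gi == 1 && gj == 2) || (gi == 2 && gj == 1))) continue;
      } else if (chain[i] == chain[j]) {
        if (std::binary_search(ex[i].begin(), ex[i].end(), j)) continue;
      }
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= off2) continue;
      double r = std::sqrt(r2);
      double sw = 1.0;
      if (r > r_on) sw = (off2 - r2) * (off2 - r2) * (off2 + 2 * r2 - 3 * on2) / denom;
      double re = r < r_floor ? r_floor : r;
      double s = (sigma[i] + sigma[j]) / 2.0 / re;
      double s6 = s * s * s; s6 = s6 * s6;
      vdw += 4.0 * std::sqrt(eps[i] * eps[j]) * (s6 * s6 - s6) * sw;
      double qq = q[i] * q[j];
      if (qq != 0) {
        double e = kE * qq / re;
        if (screened) e *= std::exp(-r / debye_length);
        elec += e * sw;
      }
    }
  }
  return List::create(_["vdw"] = vdw, _["elec"] = elec);
}

// Shrake-Rupley solvent accessible surface area, one value per atom.
// Sample points on each solvent-expanded sphere via a golden-section
// spiral; a point is buried if it falls inside any neighbour's expanded
// sphere.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii, double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector out(n);
  if (n == 0) return out;
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    px[k] = rk * std::cos(th);
    py[k] = rk * std::sin(th);
    pz[k] = zk;
  }
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1), dz = xyz(j, 2) - xyz(i, 2);
      if (dx * dx + dy * dy + dz * dz < (R[i] + R[j]) * (R[i] + R[j])) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double sx = xyz(i, 0) + R[i] * px[k];
      double sy = xyz(i, 1) + R[i] * py[k];
      double sz = xyz(i, 2) + R[i] * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = sx - xyz(j, 0), dy = sy - xyz(j, 1), dz = sz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) { buried = true; break; }
      }
      if (!buried) ++exposed;
    }
    out[i] = 4.0 * M_PI * R[i] * R[i] * ((double)exposed / n_points);
  }
  return out;
}
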
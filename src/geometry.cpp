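// Geometric kernels: tetrahedral point location (uniform-grid index),
// incremental 3-D convex hull (for the gyrification-index envelope of closed
// surfaces), and brute-force nearest-neighbour queries.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

// Locate points in a tet mesh: for each point return the 1-based index of a
// containing tet and its barycentric coordinates. A point is accepted in the
// tet maximizing its minimum barycentric coordinate; coordinates below -eps
// mean "outside" (tet = NA). Small negatives (boundary points) are clamped
// to the face and renormalized.
// [[Rcpp::export]]
List cpp_locate_points(NumericMatrix nodes, IntegerMatrix tets,
                       NumericMatrix points, double eps) {
  const int N = nodes.nrow(), M = tets.nrow(), P = points.nrow();
  if (M == 0) stop("no tetrahedra");

  std::vector<double> X(3 * (size_t)N);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) X[3 * i + a] = nodes(i, a);

  // precompute inverse edge matrices (column-major)
  std::vector<double> Binv(9 * (size_t)M);
  std::vector<int> TV(4 * (size_t)M);
  for (int m = 0; m < M; ++m) {
    for (int k = 0; k < 4; ++k) TV[4 * m + k] = tets(m, k);
    const double* p0 = &X[3 * TV[4 * m]];
    double B[9];
    for (int c = 0; c < 3; ++c) {
      const double* pc = &X[3 * TV[4 * m + c + 1]];
      for (int r = 0; r < 3; ++r) B[3 * c + r] = pc[r] - p0[r];
    }
    double d = B[0] * (B[4] * B[8] - B[7] * B[5])
             - B[3] * (B[1] * B[8] - B[7] * B[2])
             + B[6] * (B[1] * B[5] - B[4] * B[2]);
    if (d == 0.0) stop("degenerate tetrahedron %d", m + 1);
    double id = 1.0 / d;
    double* o = &Binv[9 * m];
    o[0] =  (B[4] * B[8] - B[7] * B[5]) * id;
    o[1] = -(B[1] * B[8] - B[7] * B[2]) * id;
    o[2] =  (B[1] * B[5] - B[4] * B[2]) * id;
    o[3] = -(B[3] * B[8] - B[6] * B[5]) * id;
    o[4] =  (B[0] * B[8] - B[6] * B[2]) * id;
    o[5] = -(B[0] * B[5] - B[3] * B[2]) * id;
    o[6] =  (B[3] * B[7] - B[6] * B[4]) * id;
    o[7] = -(B[0] * B[7] - B[6] * B[1]) * id;
    o[8] =  (B[0] * B[4] - B[3] * B[1]) * id;
  }

  // uniform grid over the mesh bounding box; each tet registered in every
  // cell its bounding box overlaps, so a containing tet is always found in
  // the query point's own cell
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = R_PosInf; hi[a] = R_NegInf; }
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) {
      if (X[3 * i + a] < lo[a]) lo[a] = X[3 * i + a];
      if (X[3 * i + a] > hi[a]) hi[a] = X[3 * i + a];
    }
  double vol = 1.0;
  for (int a = 0; a < 3; ++a) vol *= std::max(hi[a] - lo[a], 1e-12);
  double cell = std::cbrt(vol / std::max(M, 1)) * 1.5;
  int dim[3];
  for (int a = 0; a < 3; ++a)
    dim[a] = std::max(1, (int)std::floor((hi[a] - lo[a]) / cell) + 1);
  size_t ncell = (size_t)dim[0] * dim[1] * dim[2];

  auto cell_of = [&](double px, double py, double pz, int* c) {
    double p[3] = { px, py, pz };
    for (int a = 0; a < 3; ++a) {
      int k = (int)std::floor((p[a] - lo[a]) / cell);
      if (k < 0) k = 0;
      if (k >= dim[a]) k = dim[a] - 1;
      c[a] = k;
    }
  };

  std::vector<int> counts(ncell + 1, 0);
  std::vector<int> tlo(3 * (size_t)M), thi(3 * (size_t)M);
  for (int m = 0; m < M; ++m) {
    double bl[3] = { R_PosInf, R_PosInf, R_PosInf };
    double bh[3] = { R_NegInf, R_NegInf, R_NegInf };
    for (int k = 0; k < 4; ++k) {
      const double* p = &X[3 * TV[4 * m + k]];
      for (int a = 0; a < 3; ++a) {
        if (p[a] < bl[a]) bl[a] = p[a];
        if (p[a] > bh[a]) bh[a] = p[a];
      }
    }
    int cl[3], ch[3];
    cell_of(bl[0], bl[1], bl[2], cl);
    cell_of(bh[0], bh[1], bh[2], ch);
    for (int a = 0; a < 3; ++a) { tlo[3 * m + a] = cl[a]; thi[3 * m + a] = ch[a]; }
    for (int ix = cl[0]; ix <= ch[0]; ++ix)
      for (int iy = cl[1]; iy <= ch[1]; ++iy)
        for (int iz = cl[2]; iz <= ch[2]; ++iz)
          ++counts[(size_t)ix + dim[0] * ((size_t)iy + (size_t)dim[1] * iz) + 1];
  }
  for (size_t c = 0; c < ncell; ++c) counts[c + 1] += counts[c];
  std::vector<int> items(counts[ncell]);
  std::vector<int> cursor(counts.begin(), counts.end() - 1);
  for (int m = 0; m < M; ++m)
    for (int ix = tlo[3 * m]; ix <= thi[3 * m]; ++ix)
      for (int iy = tlo[3 * m + 1]; iy <= thi[3 * m + 1]; ++iy)
        for (int iz = tlo[3 * m + 2]; iz <= thi[3 * m + 2]; ++iz)
          items[cursor[(size_t)ix + dim[0] * ((size_t)iy + (size_t)dim[1] * iz)]++] = m;

  IntegerVector tet_out(P);
  NumericMatrix bary(P, 4);
  for (int q = 0; q < P; ++q) {
    double p[3] = { points(q, 0), points(q, 1), points(q, 2) };
    int c[3];
    cell_of(p[0], p[1], p[2], c);
    size_t ci = (size_t)c[0] + dim[0] * ((size_t)c[1] + (size_t)dim[1] * c[2]);
    int best = -1;
    double bestmin = R_NegInf, bb[4] = { 0, 0, 0, 0 };
    for (int j = counts[ci]; j < counts[ci + 1]; ++j) {
      int m = items[j];
      const double* p0 = &X[3 * TV[4 * m]];
      const double* Bi = &Binv[9 * m];
      double d[3] = { p[0] - p0[0], p[1] - p0[1], p[2] - p0[2] };
      double l1 = Bi[0] * d[0] + Bi[3] * d[1] + Bi[6] * d[2];
      double l2 = Bi[1] * d[0] + Bi[4] * d[1] + Bi[7] * d[2];
      double l3 = Bi[2] * d[0] + Bi[5] * d[1] + Bi[8] * d[2];
      double l0 = 1.0 - l1 - l2 - l3;
      double mn = std::min(std::min(l0, l1), std::min(l2, l3));
      if (mn > bestmin) {
        bestmin = mn;
        best = m;
        bb[0] = l0; bb[1] = l1; bb[2] = l2; bb[3] = l3;
      }
      if (mn >= 0.0) break;  // strictly inside: done
    }
    if (best >= 0 && bestmin >= -eps) {
      if (bestmin < 0.0) {  // snap to the nearest face
        double s = 0.0;
        for (int k = 0; k < 4; ++k) {
          if (bb[k] < 0.0) bb[k] = 0.0;
          s += bb[k];
        }
        for (int k = 0; k < 4; ++k) bb[k] /= s;
      }
      tet_out[q] = best + 1;
      for (int k = 0; k < 4; ++k) bary(q, k) = bb[k];
    } else {
      tet_out[q] = NA_INTEGER;
      for (int k = 0; k < 4; ++k) bary(q, k) = NA_REAL;
    }
  }
  return List::create(_["tet"] = tet_out, _["bary"] = bary);
}

// Incremental convex hull of a 3-D point set; returns total hull surface
// area and the hull triangles (1-based indices).
// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix pts) {
  const int N = pts.nrow();
  if (N < 4) stop("convex hull needs at least 4 points");
  std::vector<double> P(3 * (size_t)N);
  double lo[3] = { R_PosInf, R_PosInf, R_PosInf };
  double hi[3] = { R_NegInf, R_NegInf, R_NegInf };
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) {
      P[3 * i + a] = pts(i, a);
      if (P[3 * i + a] < lo[a]) lo[a] = P[3 * i + a];
      if (P[3 * i + a] > hi[a]) hi[a] = P[3 * i + a];
    }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  const double eps = 1e-10 * std::max(diag, 1.0);

  auto sub3 = [&](int i, int j, double* o) {
    for (int a = 0; a < 3; ++a) o[a] = P[3 * i + a] - P[3 * j + a];
  };
  auto cross = [](const double* a, const double* b, double* o) {
    o[0] = a[1] * b[2] - a[2] * b[1];
    o[1] = a[2] * b[0] - a[0] * b[2];
    o[2] = a[0] * b[1] - a[1] * b[0];
  };
  auto dot = [](const double* a, const double* b) {
    return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
  };

  // initial simplex: extremes in x, farthest from segment, farthest from plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < N; ++i) {
    if (P[3 * i] < P[3 * i0]) i0 = i;
    if (P[3 * i] > P[3 * i1]) i1 = i;
  }
  if (i0 == i1) stop("degenerate point set (all x equal extremes)");
  int i2 = -1;
  double bestd = eps;
  double e01[3];
  sub3(i1, i0, e01);
  for (int i = 0; i < N; ++i) {
    double v[3], c[3];
    sub3(i, i0, v);
    cross(e01, v, c);
    double d = std::sqrt(dot(c, c));
    if (d > bestd) { bestd = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point set (collinear)");
  double e02[3], n0[3];
  sub3(i2, i0, e02);
  cross(e01, e02, n0);
  int i3 = -1;
  bestd = eps;
  for (int i = 0; i < N; ++i) {
    double v[3];
    sub3(i, i0, v);
    double d = std::fabs(dot(n0, v)) / std::sqrt(dot(n0, n0));
    if (d > bestd) { bestd = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set (coplanar)");

  double ctr[3];
  for (int a = 0; a < 3; ++a)
    ctr[a] = (P[3 * i0 + a] + P[3 * i1 + a] + P[3 * i2 + a] + P[3 * i3 + a]) / 4.0;

  struct Face { int a, b, c; double n[3], d; bool alive; };
  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    Face f;
    f.a = a; f.b = b; f.c = c; f.alive = true;
    double u[3], v[3];
    sub3(b, a, u);
    sub3(c, a, v);
    cross(u, v, f.n);
    double toc[3] = { ctr[0] - P[3 * a], ctr[1] - P[3 * a + 1], ctr[2] - P[3 * a + 2] };
    if (dot(f.n, toc) > 0) {  // flip to point away from the interior
      std::swap(f.b, f.c);
      for (int k = 0; k < 3; ++k) f.n[k] = -f.n[k];
    }
    f.d = dot(f.n, &P[3 * f.a]);
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  for (int p = 0; p < N; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double nn = std::sqrt(dot(faces[f].n, faces[f].n));
      if (dot(faces[f].n, &P[3 * p]) - faces[f].d > eps * std::max(nn, 1.0))
        vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    std::unordered_set<long long> edges;
    auto key = [&](int u, int v) { return (long long)u * N + v; };
    for (int f : vis) {
      int e[3][2] = { { faces[f].a, faces[f].b },
                      { faces[f].b, faces[f].c },
                      { faces[f].c, faces[f].a } };
      for (int k = 0; k < 3; ++k) {
        long long rev = key(e[k][1], e[k][0]);
        if (edges.count(rev)) edges.erase(rev);
        else edges.insert(key(e[k][0], e[k][1]));
      }
      faces[f].alive = false;
    }
    for (long long ek : edges) {
      int u = (int)(ek / N), v = (int)(ek % N);
      add_face(u, v, p);
    }
  }

  double area = 0.0;
  std::vector<int> ha, hb, hc;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    area += 0.5 * std::sqrt(dot(f.n, f.n));
    ha.push_back(f.a + 1);
    hb.push_back(f.b + 1);
    hc.push_back(f.c + 1);
  }
  IntegerMatrix tri(ha.size(), 3);
  for (size_t k = 0; k < ha.size(); ++k) {
    tri(k, 0) = ha[k]; tri(k, 1) = hb[k]; tri(k, 2) = hc[k];
  }
  return List::create(_["area"] = area, _["faces"] = tri);
}

// Nearest reference point for each query point (brute force, exact).
// [[Rcpp::export]]
IntegerVector cpp_nearest(NumericMatrix query, NumericMatrix ref) {
  const int Q = query.nrow(), R = ref.nrow();
  if (R == 0) stop("empty reference point set");
  IntegerVector out(Q);
  std::vector<double> RX(3 * (size_t)R);
  for (int j = 0; j < R; ++j)
    for (int a = 0; a < 3; ++a) RX[3 * j + a] = ref(j, a);
  for (int i = 0; i < Q; ++i) {
    double p[3] = { query(i, 0), query(i, 1), query(i, 2) };
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < R; ++j) {
      double dx = RX[3 * j] - p[0], dy = RX[3 * j + 1] - p[1],
             dz = RX[3 * j + 2] - p[2];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}
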
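#include "hemesh.h"
using namespace Rcpp;

// Build the halfedge structure, rejecting meshes that are non-manifold,
// inconsistently oriented, or contain degenerate faces.
void build_hemesh(const NumericMatrix& V, const IntegerMatrix& Fm, HEMesh& M) {
  M.nv = V.nrow();
  M.nf = Fm.nrow();
  M.X.resize(M.nv); M.Y.resize(M.nv); M.Z.resize(M.nv);
  for (int i = 0; i < M.nv; ++i) {
    M.X[i] = V(i, 0); M.Y[i] = V(i, 1); M.Z[i] = V(i, 2);
  }
  M.F.resize(3 * M.nf);
  for (int f = 0; f < M.nf; ++f)
    for (int c = 0; c < 3; ++c) {
      int v = Fm(f, c) - 1;  // R is 1-based
      if (v < 0 || v >= M.nv) stop("face %d references vertex out of range", f + 1);
      M.F[3 * f + c] = v;
    }
  for (int f = 0; f < M.nf; ++f) {
    int a = M.F[3 * f], b = M.F[3 * f + 1], c = M.F[3 * f + 2];
    if (a == b || b == c || a == c) stop("face %d is degenerate (repeated vertex)", f + 1);
  }
  int nh = 3 * M.nf;
  M.twin.assign(nh, -1);
  M.elen.resize(nh);
  std::unordered_map<long long, int> dir;
  dir.reserve(2 * nh);
  for (int h = 0; h < nh; ++h) {
    int a = M.from(h), b = M.to(h);
    double dx = M.X[b] - M.X[a], dy = M.Y[b] - M.Y[a], dz = M.Z[b] - M.Z[a];
    M.elen[h] = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (M.elen[h] <= 0) stop("zero-length edge in face %d", h / 3 + 1);
    long long key = (long long)a * M.nv + b;
    if (dir.count(key))
      stop("mesh is non-manifold or inconsistently oriented at edge %d-%d",
           a + 1, b + 1);
    dir[key] = h;
  }
  for (int h = 0; h < nh; ++h) {
    long long rev = (long long)M.to(h) * M.nv + M.from(h);
    auto it = dir.find(rev);
    M.twin[h] = (it == dir.end()) ? -1 : it->second;
  }
  M.vout.assign(M.nv, {});
  for (int h = 0; h < nh; ++h) M.vout[M.from(h)].push_back(h);
  M.vbnd.assign(M.nv, 0);
  M.angsum.assign(M.nv, 0.0);
  for (int h = 0; h < nh; ++h) {
    if (M.twin[h] < 0) { M.vbnd[M.from(h)] = 1; M.vbnd[M.to(h)] = 1; }
    // angle at from(h) between edges h and -prv(h)
    double a = M.elen[h], b = M.elen[M.prv(h)], c = M.elen[M.nxt(h)];
    double ca = (a * a + b * b - c * c) / (2 * a * b);
    ca = std::max(-1.0, std::min(1.0, ca));
    M.angsum[M.from(h)] += std::acos(ca);
  }
}

// [[Rcpp::export]]
List cpp_mesh_validate(NumericMatrix V, IntegerMatrix F) {
  HEMesh M;
  build_hemesh(V, F, M);
  LogicalVector bnd(M.nv);
  NumericVector ang(M.nv);
  IntegerVector deg(M.nv);
  for (int i = 0; i < M.nv; ++i) {
    bnd[i] = M.vbnd[i] != 0;
    ang[i] = M.angsum[i];
    deg[i] = (int)M.vout[i].size();
  }
  return List::create(_["boundary"] = bnd, _["angle_sum"] = ang,
                      _["degree"] = deg);
}

// Per-vertex differential geometry: area-weighted normals, Meyer mixed
// (Voronoi-safe) areas, cotangent mean-curvature and angle-defect Gaussian
// curvature. Boundary vertices carry NA curvature.
// [[Rcpp::export]]
List cpp_vertex_geometry(NumericMatrix V, IntegerMatrix F) {
  HEMesh M;
  build_hemesh(V, F, M);
  int nv = M.nv, nf = M.nf;
  std::vector<double> nx(nv, 0), ny(nv, 0), nz(nv, 0);
  std::vector<double> amix(nv, 0);
  std::vector<double> lx(nv, 0), ly(nv, 0), lz(nv, 0);  // cotan Laplacian of position

  for (int f = 0; f < nf; ++f) {
    int i = M.F[3 * f], j = M.F[3 * f + 1], k = M.F[3 * f + 2];
    double e0x = M.X[j] - M.X[i], e0y = M.Y[j] - M.Y[i], e0z = M.Z[j] - M.Z[i];
    double e1x = M.X[k] - M.X[i], e1y = M.Y[k] - M.Y[i], e1z = M.Z[k] - M.Z[i];
    double cxx = e0y * e1z - e0z * e1y;
    double cyy = e0z * e1x - e0x * e1z;
    double czz = e0x * e1y - e0y * e1x;
    double a2 = std::sqrt(cxx * cxx + cyy * cyy + czz * czz);  // 2*area
    double area = 0.5 * a2;
    if (area <= 0) stop("zero-area face %d", f + 1);
    int vid[3] = {i, j, k};
    for (int c = 0; c < 3; ++c) {
      nx[vid[c]] += cxx * 0.5; ny[vid[c]] += cyy * 0.5; nz[vid[c]] += czz * 0.5;
    }
    // corner angles and cotangents
    double ang[3], cot[3];
    for (int c = 0; c < 3; ++c) {
      int h = 3 * f + c;
      double a = M.elen[h], b = M.elen[M.prv(h)], cc = M.elen[M.nxt(h)];
      double ca = (a * a + b * b - cc * cc) / (2 * a * b);
      ca = std::max(-1.0, std::min(1.0, ca));
      ang[c] = std::acos(ca);
      cot[c] = ca / std::sqrt(std::max(1e-300, 1.0 - ca * ca));
    }
    bool obtuse = ang[0] > M_PI_2 || ang[1] > M_PI_2 || ang[2] > M_PI_2;
    for (int c = 0; c < 3; ++c) {
      if (!obtuse) {
        // Voronoi area at corner c: (1/8)(|e_prev|^2 cot(next) + |e_here|^2 cot(prev))
        int h = 3 * f + c;
        double lh = M.elen[h], lp = M.elen[M.prv(h)];
        amix[vid[c]] += (lp * lp * cot[(c + 1) % 3] + lh * lh * cot[(c + 2) % 3]) / 8.0;
      } else {
        amix[vid[c]] += (ang[c] > M_PI_2) ? area / 2.0 : area / 4.0;
      }
    }
    // cotangent Laplacian: edge (from,to) of halfedge h gets cot(angle at apex)
    for (int c = 0; c < 3; ++c) {
      int h = 3 * f + c;
      int a = M.from(h), b = M.to(h);
      double w = cot[(c + 2) % 3];  // angle at apex vertex of h
      double dx = M.X[a] - M.X[b], dy = M.Y[a] - M.Y[b], dz = M.Z[a] - M.Z[b];
      lx[a] += w * dx; ly[a] += w * dy; lz[a] += w * dz;
      lx[b] -= w * dx; ly[b] -= w * dy; lz[b] -= w * dz;
    }
  }

  NumericMatrix normals(nv, 3);
  NumericVector H(nv), K(nv), A(nv);
  LogicalVector bnd(nv);
  for (int v = 0; v < nv; ++v) {
    if (M.vout[v].empty()) stop("isolated vertex %d has no incident face", v + 1);
    double nn = std::sqrt(nx[v] * nx[v] + ny[v] * ny[v] + nz[v] * nz[v]);
    if (nn <= 0) stop("degenerate normal at vertex %d", v + 1);
    normals(v, 0) = nx[v] / nn; normals(v, 1) = ny[v] / nn; normals(v, 2) = nz[v] / nn;
    A[v] = amix[v];
    bnd[v] = M.vbnd[v] != 0;
    if (M.vbnd[v] || amix[v] <= 1e-300) {
      H[v] = NA_REAL; K[v] = NA_REAL;
      continue;
    }
    // mean-curvature normal K_H = Laplacian/(2 A_mixed); H = |K_H|/2 signed by normal
    double kx = lx[v] / (2 * amix[v]), ky = ly[v] / (2 * amix[v]), kz = lz[v] / (2 * amix[v]);
    H[v] = 0.5 * (kx * normals(v, 0) + ky * normals(v, 1) + kz * normals(v, 2));
    K[v] = (2 * M_PI - M.angsum[v]) / amix[v];
  }
  return List::create(_["normals"] = normals, _["H"] = H, _["K"] = K,
                      _["area_mixed"] = A, _["boundary"] = bnd);
}

// Total surface area and absolute projected (xy-plane) area.
// [[Rcpp::export]]
NumericVector cpp_mesh_areas(NumericMatrix V, IntegerMatrix F) {
  double asurf = 0, aproj = 0;
  for (int f = 0; f < F.nrow(); ++f) {
    int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
    double e0x = V(j, 0) - V(i, 0), e0y = V(j, 1) - V(i, 1), e0z = V(j, 2) - V(i, 2);
    double e1x = V(k, 0) - V(i, 0), e1y = V(k, 1) - V(i, 1), e1z = V(k, 2) - V(i, 2);
    double cx = e0y * e1z - e0z * e1y;
    double cy = e0z * e1x - e0x * e1z;
    double cz = e0x * e1y - e0y * e1x;
    asurf += 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
    aproj += 0.5 * std::fabs(cz);
  }
  return NumericVector::create(_["A_surf"] = asurf, _["A_proj"] = aproj);
}
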
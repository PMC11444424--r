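#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

// Uniform lateral (xy) bucket grid over the mesh vertices. Queries expand in
// Chebyshev rings until the ring lower bound exceeds the best hit, so a full
// trajectory snaps in near-linear time. Ties break to the lowest index.
struct Grid2 {
  double x0, y0, cs;
  int ngx, ngy;
  bool per;
  double Lx, Ly;
  std::vector<std::vector<int>> cells;

  void build(const NumericMatrix& V, double Lx_, double Ly_) {
    int nv = V.nrow();
    per = Lx_ > 0 && Ly_ > 0;
    Lx = Lx_; Ly = Ly_;
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < nv; ++i) {
      xmin = std::min(xmin, V(i, 0)); xmax = std::max(xmax, V(i, 0));
      ymin = std::min(ymin, V(i, 1)); ymax = std::max(ymax, V(i, 1));
    }
    double ex, ey;
    if (per) { x0 = 0; y0 = 0; ex = Lx; ey = Ly; }
    else { x0 = xmin; y0 = ymin; ex = std::max(1e-9, xmax - xmin); ey = std::max(1e-9, ymax - ymin); }
    cs = std::max(1e-9, std::sqrt(ex * ey / std::max(1, nv)));
    ngx = std::max(1, (int)std::floor(ex / cs));
    ngy = std::max(1, (int)std::floor(ey / cs));
    cells.assign((size_t)ngx * ngy, {});
    for (int i = 0; i < nv; ++i) {
      int cx = cellx(V(i, 0)), cy = celly(V(i, 1));
      cells[(size_t)cy * ngx + cx].push_back(i);
    }
  }
  int cellx(double x) const {
    if (per) x -= Lx * std::floor(x / Lx);
    int c = (int)std::floor((x - x0) / cs);
    return std::min(ngx - 1, std::max(0, c));
  }
  int celly(double y) const {
    if (per) y -= Ly * std::floor(y / Ly);
    int c = (int)std::floor((y - y0) / cs);
    return std::min(ngy - 1, std::max(0, c));
  }

  void query(const NumericMatrix& V, double qx, double qy, double qz,
             int& best, double& bestd2) const {
    best = -1;
    bestd2 = std::numeric_limits<double>::infinity();
    int c0x = cellx(qx), c0y = celly(qy);
    int rmax = std::max(ngx, ngy);
    for (int r = 0; r <= rmax; ++r) {
      if (r > 0) {
        double lb = (r - 1) * cs;
        if (bestd2 <= lb * lb) break;
      }
      bool wrap_all = per && (2 * r + 1 >= ngx || 2 * r + 1 >= ngy);
      if (wrap_all) {
        for (size_t c = 0; c < cells.size(); ++c) scan(V, cells[c], qx, qy, qz, best, bestd2);
        break;
      }
      for (int dy = -r; dy <= r; ++dy) {
        for (int dx = -r; dx <= r; ++dx) {
          if (std::max(std::abs(dx), std::abs(dy)) != r) continue;
          int cx = c0x + dx, cy = c0y + dy;
          if (per) {
            cx = ((cx % ngx) + ngx) % ngx;
            cy = ((cy % ngy) + ngy) % ngy;
          } else if (cx < 0 || cx >= ngx || cy < 0 || cy >= ngy) {
            continue;
          }
          scan(V, cells[(size_t)cy * ngx + cx], qx, qy, qz, best, bestd2);
        }
      }
    }
  }

  void scan(const NumericMatrix& V, const std::vector<int>& ids, double qx,
            double qy, double qz, int& best, double& bestd2) const {
    for (int i : ids) {
      double dx = qx - V(i, 0), dy = qy - V(i, 1), dz = qz - V(i, 2);
      if (per) {
        dx -= Lx * std::nearbyint(dx / Lx);
        dy -= Ly * std::nearbyint(dy / Ly);
      }
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < bestd2 || (d2 == bestd2 && i < best)) {
        bestd2 = d2;
        best = i;
      }
    }
  }
};

}  // namespace

// Nearest mesh vertex for each query point; Lx/Ly <= 0 disables the lateral
// minimum-image convention.
// [[Rcpp::export]]
List cpp_nearest_vertex(NumericMatrix V, NumericMatrix Q, double Lx, double Ly) {
  Grid2 g;
  g.build(V, Lx, Ly);
  R_xlen_t n = Q.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int best; double d2;
    g.query(V, Q(i, 0), Q(i, 1), Q(i, 2), best, d2);
    idx[i] = best + 1;
    dist[i] = std::sqrt(d2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Gaussian-kernel height-field estimate on a regular grid: each node height
// is the kernel-weighted mean of point z-values within 3*sigma laterally,
// with periodic wrapping in x and y when Lx/Ly > 0. support counts the
// contributing points per node.
// [[Rcpp::export]]
List cpp_kernel_heightfield(NumericVector px, NumericVector py, NumericVector pz,
                            double x0, double y0, double sx, double sy,
                            int nx, int ny, double sigma, double Lx, double Ly) {
  bool per = Lx > 0 && Ly > 0;
  int np = px.size();
  double cut = 3.0 * sigma, cut2 = cut * cut;
  // bin points on a coarse grid of cell size >= cut so only 3x3 cells matter
  double ex = per ? Lx : 0, ey = per ? Ly : 0;
  double pxmin = R_PosInf, pxmax = R_NegInf, pymin = R_PosInf, pymax = R_NegInf;
  for (int i = 0; i < np; ++i) {
    pxmin = std::min(pxmin, px[i]); pxmax = std::max(pxmax, px[i]);
    pymin = std::min(pymin, py[i]); pymax = std::max(pymax, py[i]);
  }
  double bx0 = per ? 0 : std::min(pxmin, x0) - cut;
  double by0 = per ? 0 : std::min(pymin, y0) - cut;
  if (!per) {
    ex = std::max(pxmax, x0 + (nx - 1) * sx) + cut - bx0;
    ey = std::max(pymax, y0 + (ny - 1) * sy) + cut - by0;
  }
  int bgx = std::max(1, (int)std::floor(ex / cut));
  int bgy = std::max(1, (int)std::floor(ey / cut));
  double csx = ex / bgx, csy = ey / bgy;
  std::vector<std::vector<int>> bins((size_t)bgx * bgy);
  auto binx = [&](double x) {
    if (per) x -= Lx * std::floor(x / Lx);
    return std::min(bgx - 1, std::max(0, (int)std::floor((x - bx0) / csx)));
  };
  auto biny = [&](double y) {
    if (per) y -= Ly * std::floor(y / Ly);
    return std::min(bgy - 1, std::max(0, (int)std::floor((y - by0) / csy)));
  };
  for (int i = 0; i < np; ++i) bins[(size_t)biny(py[i]) * bgx + binx(px[i])].push_back(i);

  NumericVector z((R_xlen_t)nx * ny);
  IntegerVector support((R_xlen_t)nx * ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double gx = x0 + i * sx, gy = y0 + j * sy;
      double wsum = 0, wz = 0;
      int cnt = 0;
      int cx = binx(gx), cy = biny(gy);
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          int ix = cx + dx, iy = cy + dy;
          if (per) {
            ix = ((ix % bgx) + bgx) % bgx;
            iy = ((iy % bgy) + bgy) % bgy;
          } else if (ix < 0 || ix >= bgx || iy < 0 || iy >= bgy) {
            continue;
          }
          for (int p : bins[(size_t)iy * bgx + ix]) {
            double ddx = px[p] - gx, ddy = py[p] - gy;
            if (per) {
              ddx -= Lx * std::nearbyint(ddx / Lx);
              ddy -= Ly * std::nearbyint(ddy / Ly);
            }
            double r2 = ddx * ddx + ddy * ddy;
            if (r2 > cut2) continue;
            double w = std::exp(-r2 / (2 * sigma * sigma));
            wsum += w;
            wz += w * pz[p];
            ++cnt;
          }
        }
      }
      R_xlen_t k = (R_xlen_t)j * nx + i;
      support[k] = cnt;
      z[k] = cnt > 0 ? wz / wsum : NA_REAL;
    }
  }
  return List::create(_["z"] = z, _["support"] = support);
}

// Accumulate squared geodesic displacements onto both endpoints of each
// record, per lag. A self-record (v_lo == v_hi) contributes twice to its
// vertex, consistent with the both-endpoint rule.
// [[Rcpp::export]]
List cpp_accumulate_gmsd(IntegerVector vlo, IntegerVector vhi,
                         IntegerVector lag_index, NumericVector dist, int nv,
                         int nlag) {
  R_xlen_t n = vlo.size();
  NumericMatrix sums(nv, nlag);
  NumericMatrix counts(nv, nlag);
  for (R_xlen_t i = 0; i < n; ++i) {
    int li = lag_index[i] - 1;
    if (li < 0 || li >= nlag) stop("lag index out of range at record %ld", (long)(i + 1));
    int a = vlo[i] - 1, b = vhi[i] - 1;
    if (a < 0 || a >= nv || b < 0 || b >= nv)
      stop("vertex index out of range at record %ld", (long)(i + 1));
    double d2 = dist[i] * dist[i];
    sums(a, li) += d2;
    counts(a, li) += 1;
    sums(b, li) += d2;
    counts(b, li) += 1;
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}
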
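#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact k-nearest-neighbour and fixed-radius search on 2D/3D points via a
// uniform grid with expanding-ring pruning. Distances use the anisotropic
// metric sqrt(dx^2 + dy^2 + (zscale*dz)^2); the grid is built on (x, y)
// only, which is a valid lower bound for pruning. Ties at identical
// distance are broken by smaller point index, so callers passing points in
// id-sorted order get id-based tie-breaking.

struct Grid {
  double x0, y0, h;
  int nx, ny;
  std::vector<std::vector<int>> cells;
  Grid(const NumericVector& x, const NumericVector& y, double cell) {
    x0 = *std::min_element(x.begin(), x.end());
    y0 = *std::min_element(y.begin(), y.end());
    double x1 = *std::max_element(x.begin(), x.end());
    double y1 = *std::max_element(y.begin(), y.end());
    h = std::max(cell, 1e-9);
    nx = std::max(1, (int)std::floor((x1 - x0) / h) + 1);
    ny = std::max(1, (int)std::floor((y1 - y0) / h) + 1);
    cells.resize((size_t)nx * ny);
    for (int i = 0; i < x.size(); ++i) cells[idx(x[i], y[i])].push_back(i);
  }
  int cx(double x) const { return std::min(nx - 1, std::max(0, (int)((x - x0) / h))); }
  int cy(double y) const { return std::min(ny - 1, std::max(0, (int)((y - y0) / h))); }
  size_t idx(double x, double y) const { return (size_t)cx(x) + (size_t)nx * cy(y); }
};

struct Neighbour { double d; int j; };

static inline bool nb_less(const Neighbour& a, const Neighbour& b) {
  if (a.d != b.d) return a.d < b.d;
  return a.j < b.j;
}

// k nearest targets for each query point; self-match excluded when
// self_offset >= 0 marks query i as identical to target i.
static void knn_core(const NumericVector& qx, const NumericVector& qy,
                     const NumericVector& qz, const NumericVector& tx,
                     const NumericVector& ty, const NumericVector& tz,
                     double zscale, int k, double max_dist, bool exclude_self,
                     std::vector<int>& out_i, std::vector<int>& out_j,
                     std::vector<double>& out_d) {
  int nt = tx.size(), nq = qx.size();
  if (nt == 0 || nq == 0 || k <= 0) return;
  double cell = R_FINITE(max_dist) && max_dist > 0 ? max_dist : -1.0;
  if (cell < 0) {
    double dx = *std::max_element(tx.begin(), tx.end()) - *std::min_element(tx.begin(), tx.end());
    double dy = *std::max_element(ty.begin(), ty.end()) - *std::min_element(ty.begin(), ty.end());
    cell = std::max(std::sqrt(std::max(dx, 1e-6) * std::max(dy, 1e-6) / nt), 1e-6);
  }
  Grid g(tx, ty, cell);
  std::vector<Neighbour> best;
  for (int i = 0; i < nq; ++i) {
    best.clear();
    int ci = g.cx(qx[i]), cj = g.cy(qy[i]);
    int max_ring = std::max(std::max(ci, g.nx - 1 - ci), std::max(cj, g.ny - 1 - cj));
    for (int r = 0; r <= max_ring; ++r) {
      // prune: min possible distance to ring r is (r-1)*h
      double bound = R_FINITE(max_dist) ? max_dist : R_PosInf;
      if ((int)best.size() >= k && best.back().d < bound) bound = best.back().d;
      if (r >= 1 && (double)(r - 1) * g.h > bound) break;
      for (int a = ci - r; a <= ci + r; ++a) {
        if (a < 0 || a >= g.nx) continue;
        for (int b = cj - r; b <= cj + r; ++b) {
          if (b < 0 || b >= g.ny) continue;
          if (std::max(std::abs(a - ci), std::abs(b - cj)) != r) continue;
          const std::vector<int>& pts = g.cells[(size_t)a + (size_t)g.nx * b];
          for (size_t m = 0; m < pts.size(); ++m) {
            int j = pts[m];
            if (exclude_self && j == i) continue;
            double dx = qx[i] - tx[j], dy = qy[i] - ty[j];
            double dz = (qz.size() && tz.size()) ? zscale * (qz[i] - tz[j]) : 0.0;
            double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (R_FINITE(max_dist) && d > max_dist) continue;
            Neighbour nb; nb.d = d; nb.j = j;
            if ((int)best.size() < k) {
              best.push_back(nb);
              std::sort(best.begin(), best.end(), nb_less);
            } else if (nb_less(nb, best.back())) {
              best.back() = nb;
              std::sort(best.begin(), best.end(), nb_less);
            }
          }
        }
      }
    }
    for (size_t m = 0; m < best.size(); ++m) {
      out_i.push_back(i + 1);
      out_j.push_back(best[m].j + 1);
      out_d.push_back(best[m].d);
    }
  }
}

// [[Rcpp::export]]
List cpp_grid_knn(NumericVector x, NumericVector y, NumericVector z,
                  double zscale, int k, double max_dist) {
  std::vector<int> oi, oj; std::vector<double> od;
  knn_core(x, y, z, x, y, z, zscale, k, max_dist, true, oi, oj, od);
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj), _["dist"] = wrap(od));
}

// [[Rcpp::export]]
List cpp_knn_query(NumericVector qx, NumericVector qy, NumericVector tx,
                   NumericVector ty, int k, double max_dist) {
  std::vector<int> oi, oj; std::vector<double> od;
  NumericVector none(0);
  knn_core(qx, qy, none, tx, ty, none, 1.0, k, max_dist, false, oi, oj, od);
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj), _["dist"] = wrap(od));
}

// All unordered pairs (i < j) within distance r.
// [[Rcpp::export]]
List cpp_radius_pairs(NumericVector x, NumericVector y, double r) {
  std::vector<int> oi, oj; std::vector<double> od;
  int n = x.size();
  if (n >= 2 && r > 0) {
    Grid g(x, y, r);
    for (int i = 0; i < n; ++i) {
      int ci = g.cx(x[i]), cj = g.cy(y[i]);
      for (int a = std::max(0, ci - 1); a <= std::min(g.nx - 1, ci + 1); ++a) {
        for (int b = std::max(0, cj - 1); b <= std::min(g.ny - 1, cj + 1); ++b) {
          const std::vector<int>& pts = g.cells[(size_t)a + (size_t)g.nx * b];
          for (size_t m = 0; m < pts.size(); ++m) {
            int j = pts[m];
            if (j <= i) continue;
            double dx = x[i] - x[j], dy = y[i] - y[j];
            double d = std::sqrt(dx * dx + dy * dy);
            if (d <= r) { oi.push_back(i + 1); oj.push_back(j + 1); od.push_back(d); }
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj), _["dist"] = wrap(od));
}
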
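#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Mechanical shoving relaxation: overlapping disk pairs are displaced apart
// symmetrically along their centre line by half the overlap each, sweeping
// until the largest overlap drops below `tol` um or `max_sweeps` sweeps.
// Pairs are processed in ascending (i, j) index order (cells are passed
// sorted by id) so the relaxation is reproducible. x wraps periodically over
// `width`; cells are reflected above the substratum (y >= radius).
//
// Candidate pairs are collected through a uniform bin grid with a small
// distance margin and reused across sweeps; the list is rebuilt whenever any
// cell has accumulated enough displacement to possibly create a new contact.

static inline double wrap_x(double x, double width) {
  x -= width * std::floor(x / width);
  if (x >= width) x = 0.0;
  return x;
}

// deterministic pseudo-random unit direction for coincident centres
static inline void tie_break_dir(int i, int j, double& ux, double& uy) {
  double v = std::sin(12.9898 * (i + 1) + 78.233 * (j + 1)) * 43758.5453;
  double a = (v - std::floor(v)) * 6.283185307179586;
  ux = std::cos(a); uy = std::sin(a);
}

// [[Rcpp::export]]
List shove_cpp(NumericVector x_in, NumericVector y_in, NumericVector r_in,
               double width, double tol, int max_sweeps) {
  const int n = x_in.size();
  std::vector<double> x(x_in.begin(), x_in.end());
  std::vector<double> y(y_in.begin(), y_in.end());
  std::vector<double> r(r_in.begin(), r_in.end());

  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  if (n < 2 || rmax == 0) {
    return List::create(_["x"] = x_in, _["y"] = y_in, _["sweeps"] = 0,
                        _["max_overlap"] = 0.0, _["converged"] = true);
  }
  const double margin = 0.1;                 // candidate distance slack (um)
  const double cell = 2.0 * rmax + margin + 1e-9;
  const int nx = std::max(1, (int)std::floor(width / cell));
  const double bw = width / nx;
  const bool wrap_ok = nx >= 3;              // neighbour bins distinct

  std::vector<std::pair<int,int> > pairs;
  std::vector<double> disp(n, 0.0);          // displacement since last build

  auto build_pairs = [&]() {
    pairs.clear();
    std::fill(disp.begin(), disp.end(), 0.0);
    if (!wrap_ok) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = x[j] - x[i]; dx -= width * std::round(dx / width);
          double dy = y[j] - y[i];
          double cut = r[i] + r[j] + margin;
          if (dx * dx + dy * dy < cut * cut) pairs.push_back({i, j});
        }
      return;
    }
    double ymax = 0;
    for (int i = 0; i < n; ++i) ymax = std::max(ymax, y[i]);
    const int ny = (int)std::floor(ymax / cell) + 1;
    std::vector<std::vector<int> > bins((size_t)nx * ny);
    std::vector<int> bxv(n), byv(n);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(wrap_x(x[i], width) / bw); if (cx >= nx) cx = nx - 1;
      int cy = (int)std::floor(y[i] / cell);
      if (cy >= ny) cy = ny - 1;
      if (cy < 0) cy = 0;
      bxv[i] = cx; byv[i] = cy;
      bins[(size_t)cy * nx + cx].push_back(i);
    }
    for (int i = 0; i < n; ++i) {
      for (int dy_ = -1; dy_ <= 1; ++dy_) {
        int cy = byv[i] + dy_;
        if (cy < 0 || cy >= ny) continue;
        for (int dx_ = -1; dx_ <= 1; ++dx_) {
          int cx = bxv[i] + dx_;
          if (cx < 0) cx += nx; else if (cx >= nx) cx -= nx;
          const std::vector<int>& b = bins[(size_t)cy * nx + cx];
          for (size_t k = 0; k < b.size(); ++k) {
            int j = b[k];
            if (j <= i) continue;
            double ddx = x[j] - x[i]; ddx -= width * std::round(ddx / width);
            double ddy = y[j] - y[i];
            double cut = r[i] + r[j] + margin;
            if (ddx * ddx + ddy * ddy < cut * cut) pairs.push_back({i, j});
          }
        }
      }
    }
    std::sort(pairs.begin(), pairs.end());
  };

  build_pairs();
  int sweeps = 0;
  double max_ov = 0.0;
  bool converged = false;
  double max_disp = 0.0;
  // a pair needs re-checking only if one of its cells moved last sweep
  // (the first sweep checks everything: radii changed since the last call)
  std::vector<char> moved_prev(n, 1), moved_now(n, 0);

  for (sweeps = 1; sweeps <= max_sweeps; ++sweeps) {
    if (max_disp > margin * 0.45) {
      build_pairs(); max_disp = 0.0;
      std::fill(moved_prev.begin(), moved_prev.end(), 1);
    }
    max_ov = 0.0;
    std::fill(moved_now.begin(), moved_now.end(), 0);
    for (size_t k = 0; k < pairs.size(); ++k) {
      int i = pairs[k].first, j = pairs[k].second;
      if (!moved_prev[i] && !moved_prev[j] && !moved_now[i] && !moved_now[j])
        continue;
      double dx = x[j] - x[i];
      dx -= width * std::round(dx / width);   // minimal image
      double dy = y[j] - y[i];
      double rr = r[i] + r[j];
      double d2 = dx * dx + dy * dy;
      if (d2 >= rr * rr) continue;
      double d = std::sqrt(d2);
      double ov = rr - d;
      if (ov > max_ov) max_ov = ov;
      double ux, uy;
      if (d < 1e-9) tie_break_dir(i, j, ux, uy);
      else { ux = dx / d; uy = dy / d; }
      x[i] = wrap_x(x[i] - 0.5 * ov * ux, width);
      x[j] = wrap_x(x[j] + 0.5 * ov * ux, width);
      y[i] -= 0.5 * ov * uy;
      y[j] += 0.5 * ov * uy;
      if (y[i] < r[i]) y[i] = 2.0 * r[i] - y[i];
      if (y[j] < r[j]) y[j] = 2.0 * r[j] - y[j];
      disp[i] += 0.5 * ov; disp[j] += 0.5 * ov;
      if (disp[i] > max_disp) max_disp = disp[i];
      if (disp[j] > max_disp) max_disp = disp[j];
      moved_now[i] = 1; moved_now[j] = 1;
    }
    moved_prev.swap(moved_now);
    if (max_ov < tol) { converged = true; break; }
  }
  if (sweeps > max_sweeps) sweeps = max_sweeps;

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["sweeps"] = sweeps,
                      _["max_overlap"] = max_ov,
                      _["converged"] = converged);
}

// exact neighbour statistics for the segregation index: for every cell, the
// number of neighbours within `radius` (periodic x) and how many share its
// type; O(n) with uniform bins, exact.
// [[Rcpp::export]]
List neighbour_counts_cpp(NumericVector x, NumericVector y,
                          IntegerVector type, double radius, double width) {
  const int n = x.size();
  IntegerVector n_d(n), n_same(n);
  const double cell = radius + 1e-9;
  int nx = std::max(1, (int)std::floor(width / cell));
  const double bw = width / nx;
  bool wrap_ok = nx >= 3;
  if (!wrap_ok) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dx = std::fabs(x[i] - x[j]); dx = std::min(dx, width - dx);
        double dy = y[i] - y[j];
        if (dx * dx + dy * dy <= radius * radius) {
          n_d[i]++; if (type[i] == type[j]) n_same[i]++;
        }
      }
    return List::create(_["n_d"] = n_d, _["n_same"] = n_same);
  }
  double ymax = 0;
  for (int i = 0; i < n; ++i) ymax = std::max(ymax, y[i]);
  const int ny = (int)std::floor(ymax / cell) + 1;
  std::vector<std::vector<int> > bins((size_t)nx * ny);
  std::vector<int> bxv(n), byv(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i] - width * std::floor(x[i] / width);
    int cx = (int)std::floor(xi / bw); if (cx >= nx) cx = nx - 1;
    int cy = (int)std::floor(y[i] / cell);
    if (cy >= ny) cy = ny - 1;
    if (cy < 0) cy = 0;
    bxv[i] = cx; byv[i] = cy;
    bins[(size_t)cy * nx + cx].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    for (int dy_ = -1; dy_ <= 1; ++dy_) {
      int cy = byv[i] + dy_;
      if (cy < 0 || cy >= ny) continue;
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        int cx = bxv[i] + dx_;
        if (cx < 0) cx += nx; else if (cx >= nx) cx -= nx;
        const std::vector<int>& b = bins[(size_t)cy * nx + cx];
        for (size_t k = 0; k < b.size(); ++k) {
          int j = b[k];
          if (j == i) continue;
          double dx = std::fabs(x[i] - x[j]); dx = std::min(dx, width - dx);
          double dy2 = y[i] - y[j];
          if (dx * dx + dy2 * dy2 <= radius * radius) {
            n_d[i]++; if (type[i] == type[j]) n_same[i]++;
          }
        }
      }
    }
  }
  return List::create(_["n_d"] = n_d, _["n_same"] = n_same);
}
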
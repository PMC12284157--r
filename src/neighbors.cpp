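#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Fixed-radius neighbor search on a uniform grid of cell size r.
// When use_z is true the neighborhood is a cylinder: xy distance <= r AND
// |dz| <= rz (the axial window is wider because the axial localization
// spread is larger than the lateral one).
namespace {

struct GridIndex {
  double r, rz;
  bool use_z;
  const double *x, *y, *z;
  int n;
  std::unordered_map<int64_t, std::vector<int>> cells;
  double x0, y0;

  static int64_t key(int cx, int cy) {
    return (static_cast<int64_t>(cx) << 32) ^ (static_cast<uint32_t>(cy));
  }

  GridIndex(const NumericVector& xs, const NumericVector& ys,
            const NumericVector& zs, double r_, double rz_, bool use_z_)
      : r(r_), rz(rz_), use_z(use_z_),
        x(xs.begin()), y(ys.begin()), z(use_z_ ? zs.begin() : nullptr),
        n(xs.size()) {
    x0 = 0.0; y0 = 0.0;
    if (n > 0) { x0 = x[0]; y0 = y[0]; }
    cells.reserve(static_cast<size_t>(n));
    for (int i = 0; i < n; ++i) {
      int cx = static_cast<int>(std::floor((x[i] - x0) / r));
      int cy = static_cast<int>(std::floor((y[i] - y0) / r));
      cells[key(cx, cy)].push_back(i);
    }
  }

  template <typename F>
  void for_neighbors(int i, F&& f) const {
    double r2 = r * r;
    int cx = static_cast<int>(std::floor((x[i] - x0) / r));
    int cy = static_cast<int>(std::floor((y[i] - y0) / r));
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = cells.find(key(cx + dx, cy + dy));
        if (it == cells.end()) continue;
        for (int j : it->second) {
          if (j == i) continue;
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 > r2) continue;
          if (use_z && std::fabs(z[i] - z[j]) > rz) continue;
          f(j);
        }
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_radius_counts(NumericVector x, NumericVector y,
                                NumericVector z, double r, double rz,
                                bool use_z) {
  GridIndex g(x, y, z, r, rz, use_z);
  IntegerVector out(x.size());
  for (int i = 0; i < g.n; ++i) {
    int c = 0;
    g.for_neighbors(i, [&](int) { ++c; });
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_radius_neighbors(NumericVector x, NumericVector y, NumericVector z,
                          double r, double rz, bool use_z) {
  GridIndex g(x, y, z, r, rz, use_z);
  List out(x.size());
  std::vector<int> buf;
  for (int i = 0; i < g.n; ++i) {
    buf.clear();
    g.for_neighbors(i, [&](int j) { buf.push_back(j + 1); }); // 1-based
    out[i] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}
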
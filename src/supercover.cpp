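#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Cells are half-open squares [c*cs, (c+1)*cs) x [r*cs, (r+1)*cs) relative to
// the grid origin. A polyline visits a cell iff some point of it has that
// floor index. We enumerate, per segment, the parameter values where the
// segment crosses a grid line, and take the floor of each inter-crossing
// midpoint; endpoint cells are added exactly. This reproduces, in exact
// arithmetic, the cell set a dense point-walker along the path converges to.

static inline long long packCell(long long col, long long row) {
  return ((col + 33554432LL) << 26) | (row + 33554432LL);
}

static void segmentCells(double gx0, double gy0, double gx1, double gy1,
                         std::unordered_set<long long> &cells,
                         std::vector<double> &ts) {
  cells.insert(packCell((long long)std::floor(gx0), (long long)std::floor(gy0)));
  cells.insert(packCell((long long)std::floor(gx1), (long long)std::floor(gy1)));
  double dx = gx1 - gx0, dy = gy1 - gy0;
  if (dx == 0.0 && dy == 0.0) return;
  ts.clear();
  ts.push_back(0.0); ts.push_back(1.0);
  if (dx != 0.0) {
    long long klo = (long long)std::floor(std::min(gx0, gx1)) + 1;
    long long khi = (long long)std::floor(std::max(gx0, gx1));
    for (long long k = klo; k <= khi; ++k) {
      double t = ((double)k - gx0) / dx;
      if (t > 0.0 && t < 1.0) ts.push_back(t);
    }
  }
  if (dy != 0.0) {
    long long klo = (long long)std::floor(std::min(gy0, gy1)) + 1;
    long long khi = (long long)std::floor(std::max(gy0, gy1));
    for (long long k = klo; k <= khi; ++k) {
      double t = ((double)k - gy0) / dy;
      if (t > 0.0 && t < 1.0) ts.push_back(t);
    }
  }
  std::sort(ts.begin(), ts.end());
  for (size_t i = 0; i + 1 < ts.size(); ++i) {
    double tm = 0.5 * (ts[i] + ts[i + 1]);
    if (ts[i + 1] - ts[i] <= 0.0) continue;
    double px = gx0 + tm * dx, py = gy0 + tm * dy;
    cells.insert(packCell((long long)std::floor(px), (long long)std::floor(py)));
  }
}

// [[Rcpp::export(name = ".supercoverKeys")]]
NumericVector supercoverKeys(NumericVector x, NumericVector y,
                             LogicalVector bridge, double originX,
                             double originY, double cellSize) {
  int n = x.size();
  if (n == 0) return NumericVector(0);
  if (bridge.size() != std::max(n - 1, 0))
    stop("bridge must have length(x) - 1 elements");
  std::unordered_set<long long> cells;
  std::vector<double> ts;
  ts.reserve(64);
  double inv = 1.0 / cellSize;
  double gxPrev = (x[0] - originX) * inv, gyPrev = (y[0] - originY) * inv;
  cells.insert(packCell((long long)std::floor(gxPrev), (long long)std::floor(gyPrev)));
  for (int i = 1; i < n; ++i) {
    double gx = (x[i] - originX) * inv, gy = (y[i] - originY) * inv;
    if (bridge[i - 1]) {
      segmentCells(gxPrev, gyPrev, gx, gy, cells, ts);
    } else {
      cells.insert(packCell((long long)std::floor(gx), (long long)std::floor(gy)));
    }
    gxPrev = gx; gyPrev = gy;
  }
  std::vector<long long> out(cells.begin(), cells.end());
  std::sort(out.begin(), out.end());
  NumericVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) {
    long long v = out[i];
    long long row = (v & 67108863LL) - 33554432LL;
    long long col = (v >> 26) - 33554432LL;
    res[i] = ((double)col + 33554432.0) * 67108864.0 + ((double)row + 33554432.0);
  }
  return res;
}
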
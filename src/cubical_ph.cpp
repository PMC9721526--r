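#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Persistent homology of the super-level-set filtration of a 2D/3D scalar
// field, viewed as a cubical complex of closed pixel/voxel cubes.
//
// Cells live on the "doubled" grid: a cell has integer coordinates
// g_i in [0, 2*n_i]; coordinate parity encodes the cell dimension (odd
// coordinates span an interval, even ones are degenerate).  Top cells
// (pixels/voxels) sit at all-odd coordinates.  A face carries the maximum
// value over its cofacing top cells, so it enters the filtration exactly
// when its first top cell does; the pixel attaining that maximum (smallest
// linear index on ties) is recorded as the cell's source pixel and becomes
// the critical cell of any bar born or dying there.
//
// Filtration order: value descending, then cell dimension ascending, then
// grid index ascending.  Faces always have value >= their cofaces' value,
// so this order is a valid filtration and fully deterministic.

namespace {

struct CellInfo {
  double value;
  int src;   // 0-based pixel linear index (column-major)
  int dim;   // cell dimension
};

// symmetric difference of two sorted int vectors
static void symdiff(std::vector<int>& a, const std::vector<int>& b,
                    std::vector<int>& tmp) {
  tmp.clear();
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) tmp.push_back(a[i++]);
    else if (b[j] < a[i]) tmp.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) tmp.push_back(a[i++]);
  while (j < b.size()) tmp.push_back(b[j++]);
  a.swap(tmp);
}

} // namespace

// [[Rcpp::export(name = ".cubical_persistence_cpp")]]
List cubical_persistence_cpp(NumericVector field, IntegerVector shape) {
  const int d = shape.size();
  if (d < 2 || d > 3) stop("field dimension must be 2 or 3");
  int n[3] = {1, 1, 1};
  for (int i = 0; i < d; ++i) {
    n[i] = shape[i];
    if (n[i] < 1) stop("all field dimensions must be >= 1");
  }
  int G[3] = {1, 1, 1};
  for (int i = 0; i < d; ++i) G[i] = 2 * n[i] + 1;
  const long long Cll = (long long)G[0] * G[1] * G[2];
  if (Cll > INT_MAX) stop("field too large");
  const int C = (int)Cll;

  for (R_xlen_t i = 0; i < field.size(); ++i)
    if (!R_finite(field[i])) stop("field values must be finite");

  // per-cell value, source pixel, dimension
  std::vector<CellInfo> cells((size_t)C);
  {
    int g[3];
    for (int id = 0; id < C; ++id) {
      int r = id;
      g[0] = r % G[0]; r /= G[0];
      g[1] = r % G[1]; r /= G[1];
      g[2] = (d == 3) ? r % G[2] : 0;
      int dim = 0;
      // candidate pixel coordinate ranges per axis
      int lo[3], hi[3];
      for (int ax = 0; ax < d; ++ax) {
        if (g[ax] % 2 == 1) { // interval [ (g-1)/2, (g-1)/2 + 1 ]
          ++dim;
          lo[ax] = hi[ax] = (g[ax] - 1) / 2;
        } else {             // vertex coordinate g/2: pixels g/2-1 and g/2
          lo[ax] = std::max(0, g[ax] / 2 - 1);
          hi[ax] = std::min(n[ax] - 1, g[ax] / 2);
        }
      }
      for (int ax = d; ax < 3; ++ax) { lo[ax] = hi[ax] = 0; }
      double best = -1.0;
      int bestpix = -1;
      for (int pz = lo[2]; pz <= hi[2]; ++pz)
        for (int py = lo[1]; py <= hi[1]; ++py)
          for (int px = lo[0]; px <= hi[0]; ++px) {
            int pix = px + n[0] * (py + n[1] * pz);
            double v = field[pix];
            if (v > best || (v == best && pix < bestpix)) {
              best = v; bestpix = pix;
            }
          }
      cells[id].value = best;
      cells[id].src = bestpix;
      cells[id].dim = dim;
    }
  }

  // filtration order
  std::vector<int> order((size_t)C);
  for (int i = 0; i < C; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (cells[a].value != cells[b].value) return cells[a].value > cells[b].value;
    if (cells[a].dim != cells[b].dim) return cells[a].dim < cells[b].dim;
    return a < b;
  });
  std::vector<int> pos((size_t)C);
  for (int i = 0; i < C; ++i) pos[order[i]] = i;

  // boundary-matrix reduction
  std::vector<std::vector<int>> cols((size_t)C);
  std::vector<int> owner((size_t)C, -1);
  std::vector<char> paired((size_t)C, 0);
  std::vector<int> birth_pos, death_pos;
  std::vector<int> col, tmp;
  const int strideG[3] = {1, G[0], G[0] * G[1]};

  for (int j = 0; j < C; ++j) {
    const int id = order[j];
    col.clear();
    // faces: for each odd coordinate, the two cells at g_ax -/+ 1
    int r = id, g[3] = {0, 0, 0};
    g[0] = r % G[0]; r /= G[0];
    g[1] = r % G[1]; r /= G[1];
    g[2] = (d == 3) ? r % G[2] : 0;
    for (int ax = 0; ax < d; ++ax) {
      if (g[ax] % 2 == 1) {
        col.push_back(pos[id - strideG[ax]]);
        col.push_back(pos[id + strideG[ax]]);
      }
    }
    std::sort(col.begin(), col.end());
    // reduce
    while (!col.empty()) {
      int piv = col.back();
      int own = owner[piv];
      if (own == -1) {
        owner[piv] = j;
        paired[piv] = 1; paired[j] = 1;
        birth_pos.push_back(piv);
        death_pos.push_back(j);
        cols[j] = col;
        break;
      }
      symdiff(col, cols[own], tmp);
    }
  }

  // collect bars
  std::vector<int> bdim; std::vector<double> bb, bd;
  std::vector<int> bcell, dcell; std::vector<int> ess;
  for (size_t k = 0; k < birth_pos.size(); ++k) {
    int ci = order[birth_pos[k]], cj = order[death_pos[k]];
    double b = cells[ci].value, dth = cells[cj].value;
    if (b == dth) continue; // zero-length
    bdim.push_back(cells[ci].dim);
    bb.push_back(b);
    bd.push_back(dth);
    bcell.push_back(cells[ci].src + 1); // 1-based for R
    dcell.push_back(cells[cj].src + 1);
    ess.push_back(0);
  }
  for (int j = 0; j < C; ++j) {
    if (!paired[j]) {
      int ci = order[j];
      double b = cells[ci].value;
      if (b == 0.0) continue; // zero-length after truncation at 0
      bdim.push_back(cells[ci].dim);
      bb.push_back(b);
      bd.push_back(0.0);
      bcell.push_back(cells[ci].src + 1);
      dcell.push_back(NA_INTEGER);
      ess.push_back(1);
    }
  }

  return List::create(
    _["dim"] = wrap(bdim),
    _["birth"] = wrap(bb),
    _["death"] = wrap(bd),
    _["birth_cell"] = wrap(bcell),
    _["death_cell"] = wrap(dcell),
    _["essential"] = wrap(ess));
}
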
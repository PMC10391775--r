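// Multi-source label-setting Dijkstra over a raster grid with 16-neighbour
// connectivity (4 orthogonal, 4 diagonal, 8 knight moves). Step cost is
// L * (tau_a + tau_b)/2 with L = cellSize * {1, sqrt(2), sqrt(5)}. Knight
// moves are admissible only if both interior cells crossed by the straight
// centre-to-centre segment are passable (prevents tunnelling through
// one-cell-wide barriers). Impassable cells (tau = NA) have no incident
// moves. Each cell is finalised exactly once; equal-distance ties resolve
// the nearest-source label toward the smaller source index, so outputs are
// deterministic when sources are pre-sorted by id.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct QItem {
  double dist;
  int label;
  int cell;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.label > b.label;
  }
};

// moves: dr, dc, and the two interior cells for knight moves (or sentinel 9)
static const int NMOVES = 16;
static const int MV[NMOVES][6] = {
  // dr  dc  i1r i1c i2r i2c   (9 = none)
  { -1,  0,  9, 9, 9, 9 }, { 1, 0, 9, 9, 9, 9 },
  {  0, -1,  9, 9, 9, 9 }, { 0, 1, 9, 9, 9, 9 },
  { -1, -1,  9, 9, 9, 9 }, { -1, 1, 9, 9, 9, 9 },
  {  1, -1,  9, 9, 9, 9 }, { 1, 1, 9, 9, 9, 9 },
  // knight moves: interiors are (0, sgn_c) and (sgn_r, sgn_c) for |dc|=2,
  // (sgn_r, 0) and (sgn_r, sgn_c) for |dr|=2
  { -1, -2,  0, -1, -1, -1 }, { -1, 2, 0, 1, -1, 1 },
  {  1, -2,  0, -1,  1, -1 }, { 1, 2, 0, 1, 1, 1 },
  { -2, -1, -1,  0, -1, -1 }, { -2, 1, -1, 0, -1, 1 },
  {  2, -1,  1,  0,  1, -1 }, { 2, 1, 1, 0, 1, 1 }
};

// [[Rcpp::export(name = ".gridCostDijkstra")]]
List gridCostDijkstra(NumericMatrix tau, double cellSize,
                      IntegerVector srcRow, IntegerVector srcCol) {
  const int nr = tau.nrow(), nc = tau.ncol();
  const int n = nr * nc;
  const double SQ2 = std::sqrt(2.0), SQ5 = std::sqrt(5.0);
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> label(n, NA_INTEGER);
  std::vector<char> done(n, 0);

  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  for (int s = 0; s < srcRow.size(); ++s) {
    int r = srcRow[s] - 1, c = srcCol[s] - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source cell outside grid");
    if (NumericMatrix::is_na(tau(r, c)))
      stop("source cell is impassable");
    int id = r + c * nr;
    // multiple sources in one cell: keep the smallest label
    if (dist[id] > 0.0 || (dist[id] == 0.0 && s < label[id])) {
      dist[id] = 0.0;
      label[id] = s;
      pq.push({0.0, s, id});
    }
  }
  if (pq.empty()) stop("no reachable sources");

  while (!pq.empty()) {
    QItem top = pq.top(); pq.pop();
    int u = top.cell;
    if (done[u]) continue;
    if (top.dist > dist[u] ||
        (top.dist == dist[u] && top.label > label[u])) continue;
    done[u] = 1;
    int ur = u % nr, uc = u / nr;
    double tu = tau(ur, uc);
    for (int m = 0; m < NMOVES; ++m) {
      int vr = ur + MV[m][0], vc = uc + MV[m][1];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      double tv = tau(vr, vc);
      if (NumericMatrix::is_na(tv)) continue;
      int v = vr + vc * nr;
      if (done[v]) continue;
      double len;
      if (m < 4) len = cellSize;
      else if (m < 8) len = cellSize * SQ2;
      else {
        // both crossed interior cells must be passable
        int i1r = ur + MV[m][2], i1c = uc + MV[m][3];
        int i2r = ur + MV[m][4], i2c = uc + MV[m][5];
        if (i1r < 0 || i1r >= nr || i1c < 0 || i1c >= nc) continue;
        if (i2r < 0 || i2r >= nr || i2c < 0 || i2c >= nc) continue;
        if (NumericMatrix::is_na(tau(i1r, i1c)) ||
            NumericMatrix::is_na(tau(i2r, i2c))) continue;
        len = cellSize * SQ5;
      }
      double nd = dist[u] + len * 0.5 * (tu + tv);
      if (nd < dist[v] || (nd == dist[v] && label[u] < label[v])) {
        dist[v] = nd;
        label[v] = label[u];
        pq.push({nd, label[u], v});
      }
    }
  }

  NumericMatrix seconds(nr, nc);
  IntegerMatrix nearest(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int id = r + c * nr;
      if (std::isinf(dist[id])) {
        seconds(r, c) = NA_REAL;
        nearest(r, c) = NA_INTEGER;
      } else {
        seconds(r, c) = dist[id];
        nearest(r, c) = label[id] + 1;  // 1-based into source order
      }
    }
  return List::create(_["seconds"] = seconds, _["nearest"] = nearest);
}
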
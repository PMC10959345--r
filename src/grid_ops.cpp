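#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Connected-component labeling of a binary mask by breadth-first flood
// fill. Labels are assigned in scan order (column-major, matching R);
// the R wrapper re-orders them by area. connectivity is 4 or 8.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 0, 0, 1};
  const int dc4[] = {0, -1, 1, 0};
  const int* dr = connectivity == 4 ? dr4 : dr8;
  const int* dc = connectivity == 4 ? dc4 : dc8;
  const int nd = connectivity == 4 ? 4 : 8;

  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != 1 || labels(r, c) != 0) continue;
      labels(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> cur = q.front(); q.pop();
        for (int k = 0; k < nd; ++k) {
          int rr = cur.first + dr[k], cc = cur.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) == 1 && labels(rr, cc) == 0) {
            labels(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return labels;
}

// Least-cost path between two labeled patches on an 8-connected grid.
// Multi-source Dijkstra: every cell of patch `a` starts at distance 0, the
// search stops when the cheapest frontier cell belongs to patch `b`. The
// cost of a move is cell_km * move_len * (r_u + r_v) / 2 with move_len 1
// for rook moves and sqrt(2) for diagonal moves; NA resistance is
// impassable. Returns cwd = Inf when b is unreachable, otherwise the
// accumulated cost and the path (1-based row/col, from a to b).
// [[Rcpp::export(name = ".cpp_lcp")]]
List cpp_lcp(const NumericMatrix& resistance, const IntegerMatrix& labels,
             int a, int b, double cell_km) {
  const int nr = resistance.nrow(), nc = resistance.ncol();
  const int n = nr * nc;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n, INF);
  std::vector<int> prev(n, -1);
  std::vector<char> done(n, 0);
  // column-major flat index to match R
  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (labels(r, c) == a && !NumericMatrix::is_na(resistance(r, c))) {
        int id = c * nr + r;
        dist[id] = 0.0;
        pq.push(std::make_pair(0.0, id));
      }

  const int dr[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double SQRT2 = std::sqrt(2.0);
  int goal = -1;

  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    int r = u % nr, c = u / nr;
    if (labels(r, c) == b) { goal = u; break; }
    double ru = resistance(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (NumericMatrix::is_na(resistance(rr, cc))) continue;
      int v = cc * nr + rr;
      if (done[v]) continue;
      double len = (dr[k] != 0 && dc[k] != 0) ? SQRT2 : 1.0;
      double w = cell_km * len * (ru + resistance(rr, cc)) / 2.0;
      if (top.first + w < dist[v]) {
        dist[v] = top.first + w;
        prev[v] = u;
        pq.push(std::make_pair(dist[v], v));
      }
    }
  }

  if (goal < 0) {
    return List::create(_["cwd"] = R_PosInf,
                        _["path_row"] = IntegerVector(0),
                        _["path_col"] = IntegerVector(0));
  }
  std::vector<int> path;
  for (int u = goal; u != -1; u = prev[u]) path.push_back(u);
  const int m = (int)path.size();
  IntegerVector prow(m), pcol(m);
  for (int i = 0; i < m; ++i) {
    int u = path[m - 1 - i];
    prow[i] = u % nr + 1;
    pcol[i] = u / nr + 1;
  }
  return List::create(_["cwd"] = dist[goal],
                      _["path_row"] = prow, _["path_col"] = pcol);
}

// Minimum Euclidean distance (km, between cell centers) over two cell sets
// given as 1-based row/col vectors.
// [[Rcpp::export(name = ".cpp_min_pair_dist")]]
double cpp_min_pair_dist(const IntegerVector& ra, const IntegerVector& ca,
                         const IntegerVector& rb, const IntegerVector& cb,
                         double cell_km) {
  double best = std::numeric_limits<double>::infinity();
  for (int i = 0; i < ra.size(); ++i)
    for (int j = 0; j < rb.size(); ++j) {
      double dr = (double)(ra[i] - rb[j]);
      double dc = (double)(ca[i] - cb[j]);
      double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best) * cell_km;
}
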
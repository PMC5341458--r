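#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over the 8-connected pixel graph of a well.
//
// intens is the H x W matrix of normalised intensities (rows = y, cols = x).
// Edge weight between neighbouring pixels p, q:
//   clamp  mode: w = max(0, 1 - alpha * I(p) * I(q))
//   scaled mode: w = alpha * (1 - I(p) * I(q))
// with alpha = 1 for orthogonal neighbours and sqrt(2) for diagonals.
// Node index y * W + x orders ties by (y, x), so the pop order (and hence
// the run) is fully deterministic.

// [[Rcpp::export]]
NumericMatrix dijkstra_grid_cpp(NumericMatrix intens,
                                IntegerVector seed_x,
                                IntegerVector seed_y,
                                bool scaled_weights) {
  const int H = intens.nrow(), W = intens.ncol();
  const int n = H * W;
  const double SQRT2 = std::sqrt(2.0);
  std::vector<double> dist(n, R_PosInf);
  std::vector<bool> done(n, false);

  typedef std::pair<double, int> Node; // (distance, y * W + x)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int i = 0; i < seed_x.size(); ++i) {
    int x = seed_x[i], y = seed_y[i];
    if (x < 0 || x >= W || y < 0 || y >= H)
      stop("seed point (%d, %d) outside the well", x, y);
    int id = y * W + x;
    if (dist[id] > 0.0) {
      dist[id] = 0.0;
      pq.push(Node(0.0, id));
    }
  }
  if (pq.empty()) stop("multi_source_dijkstra needs at least one seed point");

  const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = true;
    int uy = u / W, ux = u % W;
    double iu = intens(uy, ux);
    for (int k = 0; k < 8; ++k) {
      int vx = ux + dx[k], vy = uy + dy[k];
      if (vx < 0 || vx >= W || vy < 0 || vy >= H) continue;
      int v = vy * W + vx;
      if (done[v]) continue;
      bool diag = (dx[k] != 0 && dy[k] != 0);
      double alpha = diag ? SQRT2 : 1.0;
      double w;
      if (scaled_weights) {
        w = alpha * (1.0 - iu * intens(vy, vx));
      } else {
        w = 1.0 - alpha * iu * intens(vy, vx);
        if (w < 0.0) w = 0.0;
      }
      double nd = dist[u] + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(Node(nd, v));
      }
    }
  }

  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      out(y, x) = dist[y * W + x];
  return out;
}
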
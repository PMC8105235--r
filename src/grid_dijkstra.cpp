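#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <vector>
#include <utility>
using namespace Rcpp;

// Multi-source Dijkstra on the 26-connected voxel grid.
//
// dim     : grid size (nx, ny, nz); linear index x-fastest, 0-based
// spacing : voxel spacing in mm per axis
// domain  : which voxels paths may traverse
// sources : 0-based linear indices of zero-distance seed voxels
//
// Edge weight between neighbouring voxels is the Euclidean distance between
// their centers in mm.  Returns the geodesic distance per voxel (Inf outside
// the domain or unreachable).
// [[Rcpp::export]]
NumericVector grid_geodesic_dist(IntegerVector dim, NumericVector spacing,
                                 LogicalVector domain, IntegerVector sources) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (domain.size() != n) stop("domain length does not match grid size");

  // Precompute the 26 neighbour offsets and their metric lengths.
  std::vector<int> odx, ody, odz;
  std::vector<double> ow;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
        double w = std::sqrt(dx * dx * spacing[0] * spacing[0] +
                             dy * dy * spacing[1] * spacing[1] +
                             dz * dz * spacing[2] * spacing[2]);
        ow.push_back(w);
      }

  NumericVector dist(n, R_PosInf);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (R_xlen_t k = 0; k < sources.size(); ++k) {
    R_xlen_t s = sources[k];
    if (s < 0 || s >= n) stop("source index out of range");
    if (!domain[s]) continue;
    if (dist[s] > 0) { dist[s] = 0.0; pq.push(Node(0.0, s)); }
  }

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = top.first; R_xlen_t v = top.second;
    if (d > dist[v]) continue;
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    for (size_t e = 0; e < ow.size(); ++e) {
      int xx = x + odx[e], yy = y + ody[e], zz = z + odz[e];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t u = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
      if (!domain[u]) continue;
      double nd = d + ow[e];
      if (nd < dist[u]) { dist[u] = nd; pq.push(Node(nd, u)); }
    }
  }
  return dist;
}

// For each row of `from` (points in mm), the 1-based index of the nearest
// row of `to` and the distance.  Brute force; used for centerline-to-mask
// snapping and straight-line fallbacks.
// [[Rcpp::export]]
List nearest_point(NumericMatrix from, NumericMatrix to) {
  const int nf = from.nrow(), nt = to.nrow();
  IntegerVector idx(nf);
  NumericVector d(nf);
  for (int i = 0; i < nf; ++i) {
    double best = R_PosInf; int bi = -1;
    double fx = from(i, 0), fy = from(i, 1), fz = from(i, 2);
    for (int j = 0; j < nt; ++j) {
      double dx = fx - to(j, 0), dy = fy - to(j, 1), dz = fz - to(j, 2);
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) { best = dd; bi = j; }
    }
    idx[i] = bi + 1;
    d[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = d);
}
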
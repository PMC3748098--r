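#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Seeded propagation: assign every pixel of `mask` (plus all seed pixels) to
// the seed reachable at minimal accumulated cost, where one 8-connected step
// p -> q costs |I(p) - I(q)| + lambda * ||p - q|| (step length 1 or sqrt(2)).
// Ties are broken lexicographically by (accumulated cost, accumulated
// Euclidean path length, seed label).  Seed pixels keep their own label: they
// start at cost 0 so no competing path (cost >= 0, longer) can displace them.

struct Node {
  double cost;
  double dist;
  int label;
  int idx;
};

struct NodeCmp {
  bool operator()(const Node &a, const Node &b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.dist != b.dist) return a.dist > b.dist;
    if (a.label != b.label) return a.label > b.label;
    return a.idx > b.idx;
  }
};

// [[Rcpp::export]]
IntegerMatrix propagate_cpp(NumericMatrix intensity, IntegerMatrix seeds,
                            LogicalMatrix mask, double lambda) {
  const int nr = intensity.nrow(), nc = intensity.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("intensity, seeds and mask must share dimensions");
  if (lambda < 0) stop("lambda must be >= 0");

  const int n = nr * nc;
  std::vector<double> cost(n, R_PosInf), dist(n, R_PosInf);
  std::vector<int> label(n, 0);
  std::vector<bool> domain(n, false), done(n, false);

  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = i + j * nr;
      if (mask(i, j) || seeds(i, j) > 0) domain[k] = true;
      if (seeds(i, j) > 0) {
        cost[k] = 0.0;
        dist[k] = 0.0;
        label[k] = seeds(i, j);
        pq.push({0.0, 0.0, seeds(i, j), k});
      }
    }
  }

  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double sqrt2 = std::sqrt(2.0);

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int k = nd.idx;
    if (done[k]) continue;
    // stale entry (a better tuple was pushed later)
    if (nd.cost != cost[k] || nd.dist != dist[k] || nd.label != label[k])
      continue;
    done[k] = true;
    int i = k % nr, j = k / nr;
    for (int d = 0; d < 8; ++d) {
      int ii = i + di[d], jj = j + dj[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int kk = ii + jj * nr;
      if (!domain[kk] || done[kk]) continue;
      double step = (d < 4) ? 1.0 : sqrt2;
      double ncost = nd.cost + std::fabs(intensity(i, j) - intensity(ii, jj)) +
                     lambda * step;
      double ndist = nd.dist + step;
      bool better = false;
      if (ncost < cost[kk]) better = true;
      else if (ncost == cost[kk]) {
        if (ndist < dist[kk]) better = true;
        else if (ndist == dist[kk] && nd.label < label[kk]) better = true;
      }
      if (better) {
        cost[kk] = ncost;
        dist[kk] = ndist;
        label[kk] = nd.label;
        pq.push({ncost, ndist, nd.label, kk});
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = label[i + j * nr];
  return out;
}

// 8-connected component labeling of a binary mask; labels assigned in
// column-major scan order of each component's first-encountered pixel.

// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int k = stack.back();
        stack.pop_back();
        int ci = k % nr, cj = k / nr;
        for (int d = 0; d < 8; ++d) {
          int ii = ci + di[d], jj = cj + dj[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  return lab;
}
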
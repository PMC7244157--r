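#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Synchronous 8-connected ring growing of labels inside a mask: one pixel
// layer per iteration; when two labels reach a pixel in the same iteration
// the lower label wins.  Used to draw dividing lines between declumped
// objects.
// [[Rcpp::export]]
IntegerMatrix cpp_ring_grow(IntegerMatrix labels, LogicalMatrix mask) {
  int h = labels.nrow(), w = labels.ncol();
  IntegerMatrix lab = clone(labels);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> frontier;
  frontier.reserve(1024);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      if (lab(r, c) > 0) frontier.push_back(r + c * h);
  std::vector<int> cand(static_cast<size_t>(h) * w, 0);
  while (!frontier.empty()) {
    std::vector<int> touched;
    touched.reserve(frontier.size());
    for (size_t i = 0; i < frontier.size(); ++i) {
      int idx = frontier[i];
      int r = idx % h, c = idx / h;
      int L = lab(r, c);
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
        if (!mask(rr, cc) || lab(rr, cc) != 0) continue;
        int j = rr + cc * h;
        if (cand[j] == 0 || L < cand[j]) {
          if (cand[j] == 0) touched.push_back(j);
          cand[j] = L;
        }
      }
    }
    frontier.clear();
    for (size_t i = 0; i < touched.size(); ++i) {
      int j = touched[i];
      lab(j % h, j / h) = cand[j];
      cand[j] = 0;
      frontier.push_back(j);
    }
  }
  return lab;
}

struct PqNode {
  double cost;
  int label;
  int idx;  // row-major pixel index, deterministic final tie-break
};
struct PqCompare {
  bool operator()(const PqNode& a, const PqNode& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.label != b.label) return a.label > b.label;
    return a.idx > b.idx;
  }
};

// Seeded propagation: assigns each region pixel to the seed minimizing the
// accumulated path cost, each 8-connected step p->q costing
// sqrt((I(p)-I(q))^2 + lambda * d(p,q)^2) with d the Euclidean step length.
// Ties in accumulated cost are resolved toward the lower seed label.  Seed
// pixels are frozen: they always keep their own label.  Dijkstra with
// lazy re-insertion; states are re-expanded on any lexicographic
// (cost, label) improvement, so the result equals the Bellman-Ford
// fixpoint exactly, including tie-breaks.
// [[Rcpp::export]]
List cpp_propagate(IntegerMatrix seeds, NumericMatrix intensity,
                   LogicalMatrix region, double lambda) {
  int h = seeds.nrow(), w = seeds.ncol();
  size_t n = static_cast<size_t>(h) * w;
  std::vector<double> cost(n, R_PosInf);
  std::vector<int> label(n, 0);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double dlen[8] = {M_SQRT2, 1.0, M_SQRT2, 1.0, 1.0, M_SQRT2, 1.0, M_SQRT2};
  std::priority_queue<PqNode, std::vector<PqNode>, PqCompare> pq;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (seeds(r, c) > 0) {
        size_t j = static_cast<size_t>(r) + static_cast<size_t>(c) * h;
        cost[j] = 0.0;
        label[j] = seeds(r, c);
        pq.push({0.0, seeds(r, c), r * w + c});
      }
    }
  }
  while (!pq.empty()) {
    PqNode nd = pq.top();
    pq.pop();
    int r = nd.idx / w, c = nd.idx % w;
    size_t j = static_cast<size_t>(r) + static_cast<size_t>(c) * h;
    if (nd.cost != cost[j] || nd.label != label[j]) continue;  // stale
    double ip = intensity(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
      if (!region(rr, cc)) continue;
      if (seeds(rr, cc) > 0) continue;  // frozen seed pixels
      size_t q = static_cast<size_t>(rr) + static_cast<size_t>(cc) * h;
      double di = ip - intensity(rr, cc);
      double step = std::sqrt(di * di + lambda * dlen[k] * dlen[k]);
      double nc = nd.cost + step;
      if (nc < cost[q] || (nc == cost[q] && nd.label < label[q])) {
        cost[q] = nc;
        label[q] = nd.label;
        pq.push({nc, nd.label, rr * w + cc});
      }
    }
  }
  IntegerMatrix lab(h, w);
  NumericMatrix cst(h, w);
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      size_t j = static_cast<size_t>(r) + static_cast<size_t>(c) * h;
      lab(r, c) = label[j];
      cst(r, c) = cost[j];
    }
  }
  return List::create(_["labels"] = lab, _["cost"] = cst);
}
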
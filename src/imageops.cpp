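// Label-map operations: 8-connectivity component labeling and the
// marker-controlled compact watershed flood (priority flood over a scalar
// surface, typically the negated Euclidean distance transform).
#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + H * qj);
            }
          }
      }
    }
  return lab;
}

struct FloodEntry {
  double cost;
  long seq;
  int idx;
  int label;
};
struct FloodCmp {
  bool operator()(const FloodEntry& a, const FloodEntry& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.idx != b.idx) return a.idx > b.idx;
    return a.seq > b.seq;
  }
};

// Flood `surface` (ascending) from `markers` restricted to mask>0.
// Candidate cost at pixel p pushed by region l:
//   surface(p) + compactness * ||p - centroid(seed pixels of l)||.
// 8-connected growth; first assignment wins; deterministic pop order
// (cost, then linear index, then push sequence).
// [[Rcpp::export(name = ".ws_flood")]]
IntegerMatrix ws_flood(NumericMatrix surface, IntegerMatrix markers,
                       IntegerMatrix mask, double compactness) {
  const int H = surface.nrow(), W = surface.ncol();
  IntegerMatrix lab(H, W);
  int maxlab = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (markers(i, j) > maxlab) maxlab = markers(i, j);
  // seed centroids
  std::vector<double> ci(maxlab + 1, 0.0), cj(maxlab + 1, 0.0);
  std::vector<int> cn(maxlab + 1, 0);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int m = markers(i, j);
      if (m > 0) { ci[m] += i; cj[m] += j; cn[m] += 1; }
    }
  for (int m = 1; m <= maxlab; ++m)
    if (cn[m] > 0) { ci[m] /= cn[m]; cj[m] /= cn[m]; }
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> pq;
  long seq = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (markers(i, j) > 0 && mask(i, j) > 0) {
        lab(i, j) = markers(i, j);
      }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) > 0) {
        const int l = lab(i, j);
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int qi = i + di, qj = j + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) > 0 && lab(qi, qj) == 0) {
              const double dd = std::sqrt((qi - ci[l]) * (qi - ci[l]) +
                                          (qj - cj[l]) * (qj - cj[l]));
              pq.push({surface(qi, qj) + compactness * dd, seq++, qi + H * qj, l});
            }
          }
      }
  while (!pq.empty()) {
    const FloodEntry e = pq.top();
    pq.pop();
    const int pi = e.idx % H, pj = e.idx / H;
    if (lab(pi, pj) != 0) continue;
    lab(pi, pj) = e.label;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int qi = pi + di, qj = pj + dj;
        if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
        if (mask(qi, qj) > 0 && lab(qi, qj) == 0) {
          const double dd = std::sqrt((qi - ci[e.label]) * (qi - ci[e.label]) +
                                      (qj - cj[e.label]) * (qj - cj[e.label]));
          pq.push({surface(qi, qj) + compactness * dd, seq++, qi + H * qj,
                   e.label});
        }
      }
  }
  return lab;
}
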
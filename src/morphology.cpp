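// Connected-component labelling and marker-controlled watershed flooding.
// Both operate on column-major R matrices.
#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// [[Rcpp::export]]
List cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  int nnb = (connectivity == 4) ? 4 : 8;
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int ii = ci + DR8[k], jj = cj + DC8[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  return List::create(_["labels"] = lab, _["n"] = next);
}

struct FloodEntry {
  double pri;
  int ord;
  int idx;
  int lab;
};
struct FloodCmp {
  bool operator()(const FloodEntry &a, const FloodEntry &b) const {
    if (a.pri != b.pri) return a.pri > b.pri;
    return a.ord > b.ord; // FIFO among equal priorities (Meyer's flooding)
  }
};

// Priority-flood watershed: seeds > 0 are marker labels, 0 is unassigned.
// Every pixel ends up with the label of the marker whose flood reaches it
// first when flooding in increasing order of the priority image.
// [[Rcpp::export]]
IntegerMatrix cpp_flood_watershed(NumericMatrix priority, IntegerMatrix seeds) {
  int nr = priority.nrow(), nc = priority.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("priority and seeds must have identical dimensions");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> q;
  int ord = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0) lab(i, j) = seeds(i, j);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) == 0) continue;
      for (int k = 0; k < 8; ++k) {
        int ii = i + DR8[k], jj = j + DC8[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (lab(ii, jj) == 0)
          q.push({priority(ii, jj), ord++, ii + jj * nr, lab(i, j)});
      }
    }
  }
  while (!q.empty()) {
    FloodEntry e = q.top(); q.pop();
    int i = e.idx % nr, j = e.idx / nr;
    if (lab(i, j) != 0) continue;
    lab(i, j) = e.lab;
    for (int k = 0; k < 8; ++k) {
      int ii = i + DR8[k], jj = j + DC8[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (lab(ii, jj) == 0)
        q.push({priority(ii, jj), ord++, ii + jj * nr, e.lab});
    }
  }
  return lab;
}
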
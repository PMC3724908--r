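#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected region containing the seed(s) within an eligibility mask.
// Breadth-first, queue order fixed by (row, col) scan of the neighbourhood,
// so the result is a set and traversal order can never matter.
//
// eligible: logical matrix (TRUE = pixel may join the region)
// seed_r, seed_c: 0-based row/col indices of one or more seeds
// eight: 8-connected growth if true, else 4-connected
// [[Rcpp::export(name = ".flood_fill_cpp")]]
LogicalMatrix flood_fill_cpp(LogicalMatrix eligible,
                             IntegerVector seed_r, IntegerVector seed_c,
                             bool eight) {
  const int nr = eligible.nrow(), nc = eligible.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<int> queue;
  queue.reserve(256);
  for (int i = 0; i < seed_r.size(); ++i) {
    int r = seed_r[i], c = seed_c[i];
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("seed out of bounds");
    if (eligible(r, c) && !out(r, c)) {
      out(r, c) = true;
      queue.push_back(r + nr * c);
    }
  }
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = eight ? dr8 : dr4;
  const int *dc = eight ? dc8 : dc4;
  const int nn = eight ? 8 : 4;
  size_t head = 0;
  while (head < queue.size()) {
    int idx = queue[head++];
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < nn; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (eligible(rr, cc) && !out(rr, cc)) {
        out(rr, cc) = true;
        queue.push_back(rr + nr * cc);
      }
    }
  }
  return out;
}
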
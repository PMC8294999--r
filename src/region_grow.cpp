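#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Seeded region growing from one seed. A pixel joins when
// |P(pixel) - reference| <= tau, where reference is the running region mean
// (classic) or the frozen seed value. Breadth-first, row-major queue order.
// [[Rcpp::export]]
IntegerMatrix region_grow_cpp(const NumericMatrix& img, int seed_row,
                              int seed_col, double tau, int connectivity,
                              bool frozen) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix mask(H, W);
  std::vector<char> visited(H * W, 0);

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;

  std::queue<std::pair<int, int> > q;
  q.push(std::make_pair(seed_row, seed_col));
  visited[seed_row * W + seed_col] = 1;
  mask(seed_row, seed_col) = 1;
  double sum = img(seed_row, seed_col);
  long count = 1;
  const double seed_val = img(seed_row, seed_col);

  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < nn; ++k) {
      int r = p.first + dr[k], c = p.second + dc[k];
      if (r < 0 || r >= H || c < 0 || c >= W) continue;
      if (visited[r * W + c]) continue;
      visited[r * W + c] = 1;
      double ref = frozen ? seed_val : (sum / count);
      // 1e-12 absolute slack: running-mean accumulation error must not
      // reject exact matches at tau = 0
      if (std::fabs(img(r, c) - ref) <= tau + 1e-12) {
        mask(r, c) = 1;
        sum += img(r, c);
        ++count;
        q.push(std::make_pair(r, c));
      }
    }
  }
  return mask;
}
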
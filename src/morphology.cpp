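// Binary-image morphology for root trait extraction: 8-connected component
// labelling and Zhang-Suen thinning (topology-preserving skeletonization).

#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix mm_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push({i, j});
      while (!q.empty()) {
        auto [r, c] = q.front();
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int rr = r + di, cc = c + dj;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push({rr, cc});
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

static inline int px(const std::vector<int>& m, int H, int W, int i, int j) {
  if (i < 0 || i >= H || j < 0 || j >= W) return 0;
  return m[static_cast<size_t>(j) * H + i];
}

// Zhang-Suen thinning. Neighbours p2..p9 clockwise from north.
// [[Rcpp::export]]
IntegerMatrix mm_thin(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> m(static_cast<size_t>(H) * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      m[static_cast<size_t>(j) * H + i] = mask(i, j) != 0 ? 1 : 0;

  std::vector<size_t> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (!m[static_cast<size_t>(j) * H + i]) continue;
          const int p2 = px(m, H, W, i - 1, j),     p3 = px(m, H, W, i - 1, j + 1);
          const int p4 = px(m, H, W, i,     j + 1), p5 = px(m, H, W, i + 1, j + 1);
          const int p6 = px(m, H, W, i + 1, j),     p7 = px(m, H, W, i + 1, j - 1);
          const int p8 = px(m, H, W, i,     j - 1), p9 = px(m, H, W, i - 1, j - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int t = 0; t < 8; ++t)
            if (seq[t] == 0 && seq[t + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(static_cast<size_t>(j) * H + i);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t t : kill) m[t] = 0;
      }
    }
  }
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = m[static_cast<size_t>(j) * H + i];
  return out;
}

// Rutovitz crossing number: transitions 0 -> 1 in the cyclic neighbour
// sequence p2..p9,p2. Distinguishes true bifurcations (>= 3 branches leave
// the pixel) from path pixels that merely touch several neighbours
// diagonally; 0 for background.
// [[Rcpp::export]]
IntegerMatrix mm_crossing_number(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return mask(i, j) != 0 ? 1 : 0;
  };
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0) continue;
      const int seq[9] = {at(i - 1, j), at(i - 1, j + 1), at(i, j + 1),
                          at(i + 1, j + 1), at(i + 1, j), at(i + 1, j - 1),
                          at(i, j - 1), at(i - 1, j - 1), at(i - 1, j)};
      int A = 0;
      for (int t = 0; t < 8; ++t)
        if (seq[t] == 0 && seq[t + 1] == 1) ++A;
      out(i, j) = A;
    }
  }
  return out;
}

// Number of foreground 8-neighbours of every foreground pixel (0 elsewhere).
// [[Rcpp::export]]
IntegerMatrix mm_neighbor_count(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0) continue;
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int rr = i + di, cc = j + dj;
          if (rr >= 0 && rr < H && cc >= 0 && cc < W && mask(rr, cc) != 0) ++n;
        }
      out(i, j) = n;
    }
  }
  return out;
}

// Sum of skeleton step lengths: for every foreground pixel, half the sum of
// distances (1 axial, sqrt(2) diagonal) to its foreground 8-neighbours, so
// every adjacency is counted exactly once in total.
// [[Rcpp::export]]
double mm_adjacency_length(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double SQ2 = std::sqrt(2.0);
  double total = 0.0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0) continue;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int rr = i + di, cc = j + dj;
          if (rr >= 0 && rr < H && cc >= 0 && cc < W && mask(rr, cc) != 0)
            total += (di != 0 && dj != 0) ? SQ2 : 1.0;
        }
    }
  }
  return total / 2.0;
}
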
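#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zhang-Suen topological thinning with a post-pass that removes
// redundant pixels from any remaining 2x2 blocks while preserving
// 8-connectivity (crossing-number test), so the result is a
// 1-pixel-wide, 8-connected skeleton.

static inline int at(const std::vector<int>& m, int nr, int nc, int r, int c) {
  if (r < 0 || c < 0 || r >= nr || c >= nc) return 0;
  return m[r + (size_t)nr * c];
}

// neighbours P2..P9 clockwise starting north (row-1)
static void nbrs(const std::vector<int>& m, int nr, int nc, int r, int c,
                 int p[8]) {
  p[0] = at(m, nr, nc, r - 1, c);     // N
  p[1] = at(m, nr, nc, r - 1, c + 1); // NE
  p[2] = at(m, nr, nc, r, c + 1);     // E
  p[3] = at(m, nr, nc, r + 1, c + 1); // SE
  p[4] = at(m, nr, nc, r + 1, c);     // S
  p[5] = at(m, nr, nc, r + 1, c - 1); // SW
  p[6] = at(m, nr, nc, r, c - 1);     // W
  p[7] = at(m, nr, nc, r - 1, c - 1); // NW
}

static inline int bsum(const int p[8]) {
  return p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
}

// number of 0->1 transitions in circular order P2..P9,P2
static inline int acount(const int p[8]) {
  int a = 0;
  for (int i = 0; i < 8; ++i)
    if (p[i] == 0 && p[(i + 1) % 8] == 1) ++a;
  return a;
}

// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> m(img.begin(), img.end());
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  int p[8];
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          if (!m[r + (size_t)nr * c]) continue;
          nbrs(m, nr, nc, r, c, p);
          int B = bsum(p);
          if (B < 2 || B > 6) continue;
          if (acount(p) != 1) continue;
          // p[0]=N(P2), p[2]=E(P4), p[4]=S(P6), p[6]=W(P8)
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i)
        m[del[i].first + (size_t)nr * del[i].second] = 0;
    }
  }
  // 2x2 block cleanup: remove simple (crossing number 1, not endpoint)
  // pixels that participate in a fully set 2x2 block.
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        if (!m[r + (size_t)nr * c]) continue;
        bool blk = false;
        for (int dr = -1; dr <= 0 && !blk; ++dr)
          for (int dc = -1; dc <= 0 && !blk; ++dc) {
            if (at(m, nr, nc, r + dr, c + dc) &&
                at(m, nr, nc, r + dr + 1, c + dc) &&
                at(m, nr, nc, r + dr, c + dc + 1) &&
                at(m, nr, nc, r + dr + 1, c + dc + 1))
              blk = true;
          }
        if (!blk) continue;
        nbrs(m, nr, nc, r, c, p);
        if (bsum(p) >= 2 && acount(p) == 1) {
          m[r + (size_t)nr * c] = 0;
          changed = true;
        }
      }
  }
  IntegerMatrix out(nr, nc);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

// 8-connected component labels of a 2D 0/1 mask (0 = background)
// [[Rcpp::export(name = ".cpp_label2d")]]
IntegerMatrix cpp_label2d(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int cur = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c) || lab(r, c)) continue;
      ++cur;
      lab(r, c) = cur;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      while (!stack.empty()) {
        std::pair<int, int> q = stack.back();
        stack.pop_back();
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b) {
            int rr = q.first + a, cc = q.second + b;
            if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
            if (img(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = cur;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
      }
    }
  return lab;
}

// 6-connected flood fill over a 3D 0/1 fluid mask from seed cells
// (1-based linear indices); returns the reachable mask.
// [[Rcpp::export(name = ".cpp_reachable3d")]]
LogicalVector cpp_reachable3d(IntegerVector fluid, IntegerVector dim,
                              IntegerVector seeds) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> vis(n, 0);
  std::vector<size_t> stack;
  for (int s = 0; s < seeds.size(); ++s) {
    size_t q = (size_t)seeds[s] - 1;
    if (q < n && fluid[q] && !vis[q]) { vis[q] = 1; stack.push_back(q); }
  }
  while (!stack.empty()) {
    size_t q = stack.back(); stack.pop_back();
    int i = q % nx, j = (q / nx) % ny, k = q / ((size_t)nx * ny);
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int t = 0; t < 6; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      size_t p = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
      if (fluid[p] && !vis[p]) { vis[p] = 1; stack.push_back(p); }
    }
  }
  LogicalVector out(n);
  for (size_t q = 0; q < n; ++q) out[q] = vis[q] != 0;
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export(name = ".cpp_neighbor_counts")]]
IntegerMatrix cpp_neighbor_counts(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> m(img.begin(), img.end());
  IntegerMatrix out(nr, nc);
  int p[8];
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!m[r + (size_t)nr * c]) { out(r, c) = NA_INTEGER; continue; }
      nbrs(m, nr, nc, r, c, p);
      out(r, c) = bsum(p);
    }
  return out;
}
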
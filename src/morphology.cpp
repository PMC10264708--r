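#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// 8-neighbour offsets, clockwise from north: N NE E SE S SW W NW
static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = { 0,  1, 1, 1, 0,-1,-1, -1};

static inline bool fg(const LogicalMatrix& g, int r, int c) {
  if (r < 0 || c < 0 || r >= g.nrow() || c >= g.ncol()) return false;
  return g(r, c) == TRUE;
}

static inline void neighbours(const LogicalMatrix& g, int r, int c, int* n) {
  for (int k = 0; k < 8; ++k) n[k] = fg(g, r + DR[k], c + DC[k]) ? 1 : 0;
}

// number of foreground neighbours
static inline int countB(const int* n) {
  int b = 0;
  for (int k = 0; k < 8; ++k) b += n[k];
  return b;
}

// crossing number: 0->1 transitions in the cyclic neighbour sequence
static inline int countA(const int* n) {
  int a = 0;
  for (int k = 0; k < 8; ++k) a += (n[k] == 0 && n[(k + 1) % 8] == 1);
  return a;
}

// Yokoi connectivity number for 8-connected foreground / 4-connected
// background: deleting the centre pixel preserves topology iff this is 1.
// (The Rutovitz crossing number misses diagonally bridged neighbour runs,
// so it cannot serve as the simple-point test.)
static inline int yokoi8(const int* n) {
  // counterclockwise from east: E NE N NW W SW S SE
  int x[8] = { n[2], n[1], n[0], n[7], n[6], n[5], n[4], n[3] };
  int c = 0;
  for (int k = 0; k < 8; k += 2) {
    int b0 = 1 - x[k], b1 = 1 - x[(k + 1) % 8], b2 = 1 - x[(k + 2) % 8];
    c += b0 - b0 * b1 * b2;
  }
  return c;
}

// Connected-component labelling; eight = TRUE for 8-connectivity,
// FALSE for 4-connectivity. Labels are 1..k in scan order, 0 = background.
// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(LogicalMatrix grid, bool eight) {
  int H = grid.nrow(), W = grid.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (grid(r0, c0) != TRUE || lab(r0, c0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r0, c0));
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        for (int k = 0; k < 8; ++k) {
          if (!eight && (k % 2 == 1)) continue;  // odd offsets are diagonal
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || cc < 0 || rr >= H || cc >= W) continue;
          if (grid(rr, cc) == TRUE && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Zhang-Suen two-subiteration thinning, with each subiteration's parallel
// candidate set applied sequentially under a live simple-point recheck
// (Yokoi connectivity number 1, at least two foreground neighbours). The
// recheck guarantees that 8-connected components and 4-connected
// background holes are preserved even for configurations (e.g. isolated
// 2x2 blocks) that plain parallel deletion would annihilate. A final
// sequential pass erodes every remaining simple non-endpoint pixel,
// which removes the staircase and corner redundancy Zhang-Suen leaves
// behind, so downstream graph construction sees genuine one-pixel
// chains. Both phases repeat until the image is a fixed point, which
// makes the whole operator idempotent.
// [[Rcpp::export(name = ".thin_skeleton")]]
LogicalMatrix thin_skeleton(LogicalMatrix mask) {
  LogicalMatrix g = clone(mask);
  int H = g.nrow(), W = g.ncol();
  int n[8];
  bool outer = true;
  while (outer) {
    outer = false;
    // phase 1: Zhang-Suen sub-iterations
    bool changed = true;
    while (changed) {
      changed = false;
      for (int sub = 0; sub < 2; ++sub) {
        std::vector<std::pair<int, int> > cand;
        for (int c = 0; c < W; ++c) {
          for (int r = 0; r < H; ++r) {
            if (g(r, c) != TRUE) continue;
            neighbours(g, r, c, n);
            // Guo-Hall deletion conditions; n: N NE E SE S SW W NW
            int C = (!n[0] && (n[1] || n[2])) + (!n[2] && (n[3] || n[4])) +
                    (!n[4] && (n[5] || n[6])) + (!n[6] && (n[7] || n[0]));
            if (C != 1) continue;
            int N1 = (n[7] || n[0]) + (n[1] || n[2]) +
                     (n[3] || n[4]) + (n[5] || n[6]);
            int N2 = (n[0] || n[1]) + (n[2] || n[3]) +
                     (n[4] || n[5]) + (n[6] || n[7]);
            int Nm = N1 < N2 ? N1 : N2;
            if (Nm < 2 || Nm > 3) continue;
            bool m = (sub == 0)
              ? ((n[4] || n[5] || !n[7]) && n[6])
              : ((n[0] || n[1] || !n[3]) && n[2]);
            if (!m) cand.push_back(std::make_pair(r, c));
          }
        }
        for (size_t i = 0; i < cand.size(); ++i) {
          int r = cand[i].first, c = cand[i].second;
          neighbours(g, r, c, n);
          if (countB(n) >= 2 && yokoi8(n) == 1) {
            g(r, c) = FALSE;
            changed = true;
            outer = true;
          }
        }
      }
    }
    // phase 2: erode the remaining simple non-endpoint pixels (staircase
    // pairs, corner and junction redundancy). Candidates are taken from a
    // snapshot and deleted in order of decreasing neighbour count so that
    // the interior of a two-pixel-wide diagonal ribbon (a Zhang-Suen
    // residue) is thinned before its end pixels are considered -- raster
    // order would instead nibble such ribbons from the tip inward and
    // shorten the skeleton's extent.
    changed = true;
    while (changed) {
      changed = false;
      std::vector<std::pair<int, std::pair<int, int> > > cand2;
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (g(r, c) != TRUE) continue;
          neighbours(g, r, c, n);
          int B = countB(n);
          if (B >= 2 && yokoi8(n) == 1)
            cand2.push_back(std::make_pair(-B, std::make_pair(r, c)));
        }
      }
      std::stable_sort(cand2.begin(), cand2.end());
      for (size_t i = 0; i < cand2.size(); ++i) {
        int r = cand2[i].second.first, c = cand2[i].second.second;
        neighbours(g, r, c, n);
        if (countB(n) >= 2 && yokoi8(n) == 1) {
          g(r, c) = FALSE;
          changed = true;
          outer = true;
        }
      }
    }
  }
  return g;
}

// Per-pixel 8-neighbour degree for skeleton pixels; -1 for background.
// [[Rcpp::export(name = ".pixel_degree")]]
IntegerMatrix pixel_degree(LogicalMatrix grid) {
  int H = grid.nrow(), W = grid.ncol();
  IntegerMatrix deg(H, W);
  int n[8];
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (grid(r, c) != TRUE) { deg(r, c) = -1; continue; }
      neighbours(grid, r, c, n);
      deg(r, c) = countB(n);
    }
  return deg;
}
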
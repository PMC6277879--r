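// Binary-morphology kernels used by the imaging and trait-feature code:
// Zhang-Suen thinning (medial skeleton) and connected-component labeling
// with explicit 4- or 8-connectivity.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix thin_zhangsuen(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  // neighbours P2..P9 clockwise starting straight up (row-1)
  const int dr[8] = {-1,-1, 0, 1, 1, 1, 0,-1};
  const int dc[8] = { 0, 1, 1, 1, 0,-1,-1,-1};
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          if (!img(r, c)) continue;
          int p[8];
          for (int k = 0; k < 8; ++k) {
            int rr = r + dr[k], cc = c + dc[k];
            p[k] = (rr >= 0 && rr < H && cc >= 0 && cc < W) ? img(rr, cc) : 0;
          }
          int B = p[0]+p[1]+p[2]+p[3]+p[4]+p[5]+p[6]+p[7];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k) if (!p[k] && p[(k+1)%8]) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p[0]*p[2]*p[4] != 0) continue;   // P2*P4*P6
            if (p[2]*p[4]*p[6] != 0) continue;   // P4*P6*P8
          } else {
            if (p[0]*p[2]*p[6] != 0) continue;   // P2*P4*P8
            if (p[0]*p[4]*p[6] != 0) continue;   // P2*P6*P8
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          img(kill[i].first, kill[i].second) = 0;
      }
    }
  }
  return img;
}

// [[Rcpp::export]]
IntegerMatrix label_components(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = { 0, 0,-1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int,int> cur = q.front(); q.pop();
        for (int k = 0; k < nn; ++k) {
          int rr = cur.first + dr[k], cc = cur.second + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (!mask(rr, cc) || lab(rr, cc)) continue;
          lab(rr, cc) = next;
          q.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return lab;
}
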
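// Morphological thinning (Zhang-Suen) of a 2D binary mask down to a
// one-pixel-wide centreline. The medial-axis radius is recovered separately
// from the Euclidean distance transform.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".thin_mask_cpp")]]
LogicalMatrix thin_mask_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img(clone(mask));
  auto at = [&](int r, int c) -> int {
    if (r < 0 || c < 0 || r >= nr || c >= nc) return 0;
    return img(r, c) ? 1 : 0;
  };
  bool changed = true;
  std::vector<std::pair<int,int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
        if (!img(r, c)) continue;
        // neighbours p2..p9 clockwise from north
        int p2 = at(r-1,c), p3 = at(r-1,c+1), p4 = at(r,c+1), p5 = at(r+1,c+1);
        int p6 = at(r+1,c), p7 = at(r+1,c-1), p8 = at(r,c-1), p9 = at(r-1,c-1);
        int B = p2+p3+p4+p5+p6+p7+p8+p9;
        if (B < 2 || B > 6) continue;
        int A = (p2==0 && p3==1) + (p3==0 && p4==1) + (p4==0 && p5==1) +
                (p5==0 && p6==1) + (p6==0 && p7==1) + (p7==0 && p8==1) +
                (p8==0 && p9==1) + (p9==0 && p2==1);
        if (A != 1) continue;
        if (pass == 0) {
          if (p2*p4*p6 != 0 || p4*p6*p8 != 0) continue;
        } else {
          if (p2*p4*p8 != 0 || p2*p6*p8 != 0) continue;
        }
        kill.emplace_back(r, c);
      }
      for (auto &rc : kill) img(rc.first, rc.second) = false;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}
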
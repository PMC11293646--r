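#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Reference folder: maximum-weight pseudoknot-free pairing (GC=3, AU=2,
// GU=1 by default, minimum hairpin loop 3) with traceback enumeration of
// co-optimal structures up to a cap. A deterministic, test-grade engine;
// production folding goes through the external RNAfold adapter.

namespace {

int Wmin_loop;
int wpair(char a, char b, int wGC, int wAU, int wGU) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wGC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return wAU;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return wGU;
  return -1;
}

struct Enumerator {
  const std::string& s;
  const std::vector<std::vector<int>>& M;
  int n, wGC, wAU, wGU, cap;
  std::vector<std::vector<int>> out;
  std::vector<int> cur;

  Enumerator(const std::string& s_, const std::vector<std::vector<int>>& M_,
             int wGC_, int wAU_, int wGU_, int cap_)
      : s(s_), M(M_), n((int)s_.size()), wGC(wGC_), wAU(wAU_), wGU(wGU_),
        cap(cap_), cur((size_t)s_.size(), 0) {}

  // enumerate optimal decompositions of the list of segments
  void go(std::vector<std::pair<int, int>> segs) {
    if ((int)out.size() >= cap) return;
    // find first non-trivial segment
    while (!segs.empty()) {
      std::pair<int, int> sg = segs.back();
      if (sg.second - sg.first >= Wmin_loop + 1) break;
      segs.pop_back();
    }
    if (segs.empty()) { out.push_back(cur); return; }
    std::pair<int, int> sg = segs.back();
    segs.pop_back();
    int i = sg.first, j = sg.second;
    int target = M[i][j];
    // option: j unpaired
    if (M[i][j - 1] == target) {
      std::vector<std::pair<int, int>> next = segs;
      next.push_back(std::make_pair(i, j - 1));
      go(next);
      if ((int)out.size() >= cap) return;
    }
    // option: j paired with k
    for (int k = i; k <= j - Wmin_loop - 1; ++k) {
      int w = wpair(s[k - 1], s[j - 1], wGC, wAU, wGU);
      if (w <= 0) continue;
      int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
      int left = (k - 1 >= i) ? M[i][k - 1] : 0;
      if (left + inner + w == target) {
        cur[(size_t)k - 1] = j;
        cur[(size_t)j - 1] = k;
        std::vector<std::pair<int, int>> next = segs;
        if (k - 1 >= i) next.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) next.push_back(std::make_pair(k + 1, j - 1));
        go(next);
        cur[(size_t)k - 1] = 0;
        cur[(size_t)j - 1] = 0;
        if ((int)out.size() >= cap) return;
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int wGC, int wAU, int wGU,
                   int min_loop, int max_structs) {
  int n = (int)seq.size();
  Wmin_loop = min_loop;
  std::vector<std::vector<int>> M((size_t)(n + 2),
                                  std::vector<int>((size_t)(n + 2), 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int w = wpair(seq[k - 1], seq[j - 1], wGC, wAU, wGU);
        if (w <= 0) continue;
        int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
        int left = (k - 1 >= i) ? M[i][k - 1] : 0;
        int v = left + inner + w;
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  Enumerator en(seq, M, wGC, wAU, wGU, max_structs);
  if (n >= 1) {
    std::vector<std::pair<int, int>> segs;
    segs.push_back(std::make_pair(1, n));
    en.go(segs);
  } else {
    en.out.push_back(std::vector<int>());
  }
  List res((int)en.out.size());
  for (int k = 0; k < (int)en.out.size(); ++k)
    res[k] = IntegerVector(en.out[(size_t)k].begin(), en.out[(size_t)k].end());
  List ret = List::create(_["score"] = (n ? M[1][n] : 0),
                          _["structures"] = res);
  return ret;
}
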
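#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Exhaustive affine-gap Smith-Waterman over one strand of one subject.
// Multiple hits are recovered greedily: best local alignment, mask its
// subject footprint, re-run until the score floor or the hit cap is reached.
// Scores: match > 0, mismatch/gap penalties given as negative numbers is NOT
// assumed -- mismatch, gap_open, gap_ext are positive costs here.

namespace {

struct Hit {
  int score;
  int qstart, qend;   // 1-based inclusive on query
  int sstart, send;   // 1-based inclusive on subject
  std::string qaln, saln;
};

inline bool base_eq(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  if (a == 'N' || b == 'N') return false;
  return a == b;
}

// One Smith-Waterman pass; masked subject columns cannot be part of an
// alignment (all cells forced to zero there).
bool sw_pass(const std::string& q, const std::string& s,
             const std::vector<char>& masked,
             int match, int mismatch, int gap_open, int gap_ext,
             Hit& out) {
  const int m = (int)q.size(), n = (int)s.size();
  const int NEG = -1000000000;
  // H: best ending in match/mismatch or anything; E: gap in query (subject
  // consumed); F: gap in subject (query consumed).
  std::vector<std::vector<int8_t>> tb((size_t)(m + 1),
                                      std::vector<int8_t>((size_t)(n + 1), 0));
  // traceback codes: 0 stop, 1 diag, 2 up (gap in subject), 3 left (gap in query)
  std::vector<std::vector<int>> Hmat((size_t)(m + 1),
                                     std::vector<int>((size_t)(n + 1), 0));
  std::vector<std::vector<int>> Emat = Hmat, Fmat = Hmat;
  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j) { Emat[i][j] = NEG; Fmat[i][j] = NEG; }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      if (masked[j - 1]) { Hmat[i][j] = 0; Emat[i][j] = NEG; Fmat[i][j] = NEG; tb[i][j] = 0; continue; }
      int e = std::max(Hmat[i][j - 1] - (gap_open + gap_ext),
                       Emat[i][j - 1] - gap_ext);
      int f = std::max(Hmat[i - 1][j] - (gap_open + gap_ext),
                       Fmat[i - 1][j] - gap_ext);
      int sub = base_eq(q[i - 1], s[j - 1]) ? match : -mismatch;
      int d = Hmat[i - 1][j - 1] + sub;
      int h = std::max(0, std::max(d, std::max(e, f)));
      Emat[i][j] = e; Fmat[i][j] = f; Hmat[i][j] = h;
      if (h == 0) tb[i][j] = 0;
      else if (h == d) tb[i][j] = 1;
      else if (h == f) tb[i][j] = 2;
      else tb[i][j] = 3;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  // traceback
  std::string qa, sa;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && Hmat[i][j] > 0 && tb[i][j] != 0) {
    int8_t t = tb[i][j];
    if (t == 1) { qa.push_back(q[i - 1]); sa.push_back(s[j - 1]); --i; --j; }
    else if (t == 2) { qa.push_back(q[i - 1]); sa.push_back('-'); --i; }
    else { qa.push_back('-'); sa.push_back(s[j - 1]); --j; }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  out.score = best;
  out.qstart = i + 1; out.qend = bi;
  out.sstart = j + 1; out.send = bj;
  out.qaln = qa; out.saln = sa;
  return true;
}

} // namespace

// [[Rcpp::export(name = ".sw_align_all")]]
DataFrame sw_align_all(std::string query, std::string subject,
                       int match, int mismatch, int gap_open, int gap_ext,
                       int min_score, int max_hits) {
  std::vector<char> masked(subject.size(), 0);
  std::vector<Hit> hits;
  for (int k = 0; k < max_hits; ++k) {
    Hit h;
    if (!sw_pass(query, subject, masked, match, mismatch, gap_open, gap_ext, h))
      break;
    if (h.score < min_score) break;
    hits.push_back(h);
    for (int j = h.sstart - 1; j < h.send; ++j) masked[j] = 1;
  }
  const int nh = (int)hits.size();
  IntegerVector score(nh), qstart(nh), qend(nh), sstart(nh), send(nh),
      nmismatch(nh), ngap(nh);
  CharacterVector qaln(nh), saln(nh);
  for (int k = 0; k < nh; ++k) {
    const Hit& h = hits[k];
    score[k] = h.score;
    qstart[k] = h.qstart; qend[k] = h.qend;
    sstart[k] = h.sstart; send[k] = h.send;
    int mm = 0, gp = 0;
    for (size_t p = 0; p < h.qaln.size(); ++p) {
      if (h.qaln[p] == '-' || h.saln[p] == '-') ++gp;
      else if (!base_eq(h.qaln[p], h.saln[p])) ++mm;
    }
    nmismatch[k] = mm; ngap[k] = gp;
    qaln[k] = h.qaln; saln[k] = h.saln;
  }
  return DataFrame::create(
      _["score"] = score, _["qstart"] = qstart, _["qend"] = qend,
      _["sstart"] = sstart, _["send"] = send, _["mismatches"] = nmismatch,
      _["gaps"] = ngap, _["qaln"] = qaln, _["saln"] = saln,
      _["stringsAsFactors"] = false);
}
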
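#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Banded global alignment (Needleman-Wunsch) with linear gap penalties.
// Cells (i, j) with |j - i| <= band are evaluated; the wrapper guarantees
// band >= |n - m| so the terminal cell is inside the band.  With the band
// spanning both sequences this is exact full NW.
//
// Returns the optimal score, per-column event counts (match / mismatch /
// ins = gap in `a` / del = gap in `b`), and optionally the aligned strings.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap,
                  int band, bool keep_alignment) {
  const int n = (int)a.size(), m = (int)b.size();
  if (band < std::abs(n - m) + 1) band = std::abs(n - m) + 1;
  if (band > std::max(n, m)) band = std::max(n, m);
  const int W = 2 * band + 1;
  const double mem = (double)(n + 1) * (double)W;
  if (mem > 6e8)
    stop("alignment band matrix too large (%d x %d); reduce input size", n + 1, W);

  const int NEG = INT_MIN / 4;
  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0); // 0 diag, 1 up, 2 left, 3 edge

  // row 0
  for (int j = 0; j <= std::min(m, band); ++j) {
    prev[j - 0 + band] = -gap * j;
    tb[j - 0 + band] = (j == 0) ? 3 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int lo = std::max(0, i - band), hi = std::min(m, i + band);
    for (int j = lo; j <= hi; ++j) {
      const int off = j - i + band;
      int best = NEG; unsigned char mv = 3;
      // up: (i-1, j) -> off in prev row = j-(i-1)+band = off+1
      if (off + 1 < W && prev[off + 1] > NEG) {
        int s = prev[off + 1] - gap;
        if (s > best) { best = s; mv = 1; }
      }
      // left: (i, j-1) -> off-1 in same row
      if (j > lo && cur[off - 1] > NEG) {
        int s = cur[off - 1] - gap;
        if (s > best) { best = s; mv = 2; }
      }
      // diag: (i-1, j-1) -> off in prev row
      if (j > 0 && prev[off] > NEG) {
        int s = prev[off] + (a[i - 1] == b[j - 1] ? match : mismatch);
        if (s >= best) { best = s; mv = 0; }
      }
      cur[off] = best;
      tb[(size_t)i * W + off] = mv;
    }
    std::swap(prev, cur);
  }
  const int score = prev[m - n + band];

  // traceback
  long n_match = 0, n_mis = 0, n_ins = 0, n_del = 0;
  std::string aa, ab;
  if (keep_alignment) { aa.reserve(n + m); ab.reserve(n + m); }
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char mv = tb[(size_t)i * W + (j - i + band)];
    if (mv == 0) {
      if (a[i - 1] == b[j - 1]) ++n_match; else ++n_mis;
      if (keep_alignment) { aa.push_back(a[i - 1]); ab.push_back(b[j - 1]); }
      --i; --j;
    } else if (mv == 1) {
      ++n_del;
      if (keep_alignment) { aa.push_back(a[i - 1]); ab.push_back('-'); }
      --i;
    } else if (mv == 2) {
      ++n_ins;
      if (keep_alignment) { aa.push_back('-'); ab.push_back(b[j - 1]); }
      --j;
    } else {
      stop("internal error: alignment traceback left the band");
    }
  }
  List out = List::create(
    _["score"] = score,
    _["n_match"] = (double)n_match, _["n_mismatch"] = (double)n_mis,
    _["n_ins"] = (double)n_ins, _["n_del"] = (double)n_del);
  if (keep_alignment) {
    std::reverse(aa.begin(), aa.end());
    std::reverse(ab.begin(), ab.end());
    out["aligned_a"] = aa;
    out["aligned_b"] = ab;
  }
  return out;
}
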
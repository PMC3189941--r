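#include <Rcpp.h>
using namespace Rcpp;

// Banded Smith-Waterman local alignment with linear gap penalty.
//
// q, s: 1-based integer-encoded sequences (values index into `mat`).
// mat:  substitution score matrix (nletters x nletters).
// gap:  gap penalty per gapped column (negative).
// d_lo, d_hi: allowed diagonal range for d = i - j (i over q, j over s,
//   both 1-based). Pass d_lo <= 1 - m and d_hi >= n - 1 for a full
//   (unbanded) Smith-Waterman.
//
// Tie-breaking is deterministic: cells are filled row-major and a new
// maximum replaces the incumbent only if strictly greater; during
// traceback diagonal moves are preferred over up (gap in s) over left
// (gap in q).
//
// Returns the best local alignment as 1-based coordinates plus the
// aligned index pairs (0 marks a gap in that sequence).
// [[Rcpp::export(name = ".sw_band")]]
List sw_band(IntegerVector q, IntegerVector s, NumericMatrix mat,
             double gap, int d_lo, int d_hi) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (d_lo > d_hi) stop("invalid diagonal band");
  if (d_lo < 1 - m) d_lo = 1 - m;
  if (d_hi > n - 1) d_hi = n - 1;
  const int width = d_hi - d_lo + 1;

  // H and pointer matrices stored band-relative: column k = (i - j) - d_lo.
  std::vector<double> H((size_t)(n + 1) * width, 0.0);
  std::vector<unsigned char> P((size_t)(n + 1) * width, 0);

  double best = 0.0;
  int bi = 0, bk = -1;

  for (int i = 1; i <= n; ++i) {
    int j_lo = i - d_hi; if (j_lo < 1) j_lo = 1;
    int j_hi = i - d_lo; if (j_hi > m) j_hi = m;
    for (int j = j_lo; j <= j_hi; ++j) {
      const int k = (i - j) - d_lo;
      double diag = H[(size_t)(i - 1) * width + k] +
        mat(q[i - 1] - 1, s[j - 1] - 1);
      double up   = (k - 1 >= 0)    ? H[(size_t)(i - 1) * width + (k - 1)] + gap : R_NegInf;
      double left = (k + 1 < width) ? H[(size_t)i * width + (k + 1)] + gap : R_NegInf;
      double v = 0.0; unsigned char p = 0;
      if (diag > v) { v = diag; p = 1; }
      if (up   > v) { v = up;   p = 2; }
      if (left > v) { v = left; p = 3; }
      H[(size_t)i * width + k] = v;
      P[(size_t)i * width + k] = p;
      if (v > best) { best = v; bi = i; bk = k; }
    }
  }

  std::vector<int> qi, sj;
  int i = bi, k = bk;
  int q_end = 0, s_end = 0, q_start = 0, s_start = 0;
  if (bk >= 0 && best > 0) {
    q_end = bi; s_end = bi - (bk + d_lo);
    while (i > 0) {
      unsigned char p = P[(size_t)i * width + k];
      if (p == 0) break;
      int j = i - (k + d_lo);
      if (p == 1)      { qi.push_back(i); sj.push_back(j); --i; }
      else if (p == 2) { qi.push_back(i); sj.push_back(0); --i; --k; }
      else             { qi.push_back(0); sj.push_back(j); ++k; }
    }
    q_start = i + 1; s_start = i - (k + d_lo) + 1;
    std::reverse(qi.begin(), qi.end());
    std::reverse(sj.begin(), sj.end());
  }

  return List::create(
    _["score"] = best,
    _["q_start"] = q_start, _["q_end"] = q_end,
    _["s_start"] = s_start, _["s_end"] = s_end,
    _["q_idx"] = wrap(qi), _["s_idx"] = wrap(sj));
}
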
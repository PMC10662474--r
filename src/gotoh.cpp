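#include <Rcpp.h>
using namespace Rcpp;

static const double NEG = -1e300;

// Three-matrix affine-gap global alignment (Gotoh). S holds the pairwise
// site scores; a gap of length k costs d + (k-1)e. End gaps are penalized
// like internal gaps. Gap-state recursions have no cross transitions
// (Ix never feeds Iy directly and vice versa), matching the printed
// recursion; this is score-equivalent for non-negative pair scores.
// Tie-breaks are fixed for reproducibility: terminal and traceback state
// choice prefer M over Ix over Iy; within a gap state, opening (from M)
// is preferred to extending on ties.
// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix S, double d, double e, bool traceback) {
  const int n = S.nrow(), m = S.ncol();
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG)),
      Ix(n + 1, std::vector<double>(m + 1, NEG)),
      Iy(n + 1, std::vector<double>(m + 1, NEG));
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) Ix[i][0] = d + (i - 1) * e;
  for (int j = 1; j <= m; ++j) Iy[0][j] = d + (j - 1) * e;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = M[i - 1][j - 1];
      if (Ix[i - 1][j - 1] > best) best = Ix[i - 1][j - 1];
      if (Iy[i - 1][j - 1] > best) best = Iy[i - 1][j - 1];
      M[i][j] = best + S(i - 1, j - 1);
      Ix[i][j] = std::max(M[i - 1][j] + d, Ix[i - 1][j] + e);
      Iy[i][j] = std::max(M[i][j - 1] + d, Iy[i][j - 1] + e);
    }
  }

  int state = 0;  // 0=M, 1=Ix, 2=Iy; prefer M > Ix > Iy on ties
  double score = M[n][m];
  if (Ix[n][m] > score) { score = Ix[n][m]; state = 1; }
  if (Iy[n][m] > score) { score = Iy[n][m]; state = 2; }

  if (!traceback) return List::create(_["score"] = score);

  std::vector<int> pi, pj;
  std::string ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pi.push_back(i); pj.push_back(j); ops.push_back('M');
      double dM = M[i - 1][j - 1], dX = Ix[i - 1][j - 1], dY = Iy[i - 1][j - 1];
      int prev = 0; double best = dM;
      if (dX > best) { best = dX; prev = 1; }
      if (dY > best) { best = dY; prev = 2; }
      --i; --j; state = prev;
    } else if (state == 1) {
      ops.push_back('X');
      state = (M[i - 1][j] + d >= Ix[i - 1][j] + e) ? 0 : 1;
      --i;
    } else {
      ops.push_back('Y');
      state = (M[i][j - 1] + d >= Iy[i][j - 1] + e) ? 0 : 2;
      --j;
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && state != 2) state = 2;  // only left gaps remain
    if (j == 0 && state != 1) state = 1;  // only up gaps remain
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  std::reverse(ops.begin(), ops.end());

  IntegerMatrix pairs(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    pairs(k, 0) = pi[k];
    pairs(k, 1) = pj[k];
  }
  return List::create(_["score"] = score, _["pairs"] = pairs,
                      _["ops"] = ops);
}
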
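#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gotoh-style local alignment of a position-specific scoring matrix to a
// protein sequence.
//
//   prof   : 20 x C matrix of per-column log-odds (bits), rows in the
//            alphabet order ACDEFGHIKLMNPQRSTVWY
//   query  : 0-based residue indices; 20 encodes 'X', which scores 0 bits
//            in every column
//   gaps   : a run of k skipped interior columns or residues costs
//            gap_open + (k - 1) * gap_ext; flanking columns/residues are
//            free (local alignment); the empty alignment scores 0
//
// Tie policy (makes the traceback deterministic): when cell values tie,
// continuing an existing alignment beats opening a fresh one, and a match
// step beats a column-skip beats a residue-skip.  The best-scoring end
// cell is the first one reached scanning columns outer, positions inner.
//
// Cell values are kept in rolling rows; the traceback pointers (2 bits per
// state per cell) are kept for the full matrix.

// [[Rcpp::export]]
List psm_align_local(const NumericMatrix& prof, const IntegerVector& query,
                     double gap_open, double gap_ext) {
  const int C = prof.ncol();
  const int L = query.size();
  const double NEG = -1e300;
  const double* P = &prof[0];  // column-major, 20 rows

  std::vector<double> Mp(L + 1, NEG), Mc(L + 1, NEG);
  std::vector<double> Dp(L + 1, NEG), Dc(L + 1, NEG);
  std::vector<double> Iyc(L + 1, NEG);
  // pointer codes: 0 fresh start, 1 from M, 2 from Dx, 3 from Iy
  std::vector<unsigned char> pM((size_t)(C + 1) * (L + 1), 0),
      pD((size_t)(C + 1) * (L + 1), 0), pI((size_t)(C + 1) * (L + 1), 0);

  double best = 0.0;
  int bi = -1, bj = -1;

  for (int i = 1; i <= C; ++i) {
    const double* col = P + (size_t)20 * (i - 1);
    unsigned char* pMi = &pM[(size_t)i * (L + 1)];
    unsigned char* pDi = &pD[(size_t)i * (L + 1)];
    unsigned char* pIi = &pI[(size_t)i * (L + 1)];
    Mc[0] = NEG; Dc[0] = NEG;
    double iyPrev = NEG;  // Iy[i][0]
    for (int j = 1; j <= L; ++j) {
      const int q = query[j - 1];
      const double s = (q == 20) ? 0.0 : col[q];

      // M[i][j]
      double m0 = 0.0;
      unsigned char pm = 0;
      const double prevM = Mp[j - 1], prevD = Dp[j - 1], prevI = Iyc[j - 1];
      if (prevM >= m0) { m0 = prevM; pm = 1; }
      if (prevD > m0)  { m0 = prevD; pm = 2; }
      if (prevI > m0)  { m0 = prevI; pm = 3; }
      const double m = s + m0;
      Mc[j] = m; pMi[j] = pm;

      // Dx[i][j]: skip column i
      const double dM = Mp[j] - gap_open;
      const double dD = Dp[j] - gap_ext;
      if (dM >= dD) { Dc[j] = dM; pDi[j] = 1; }
      else          { Dc[j] = dD; pDi[j] = 2; }

      // Iy[i][j]: skip residue j.  Entered from M, from Dx (a deletion
      // run followed by an insertion run between two matches; canonical
      // order deletions-first), or extended.
      const double iM = Mc[j - 1] - gap_open;
      const double iD = Dc[j - 1] - gap_open;
      const double iI = iyPrev - gap_ext;
      double iy;
      if (iM >= iD && iM >= iI) { iy = iM; pIi[j] = 1; }
      else if (iD >= iI)        { iy = iD; pIi[j] = 2; }
      else                      { iy = iI; pIi[j] = 3; }
      Iyc[j - 1] = iyPrev;  // retire Iy[i][j-1] (no longer needed as prev row)
      iyPrev = iy;

      if (m > best) { best = m; bi = i; bj = j; }
    }
    Iyc[L] = iyPrev;
    std::swap(Mp, Mc);
    std::swap(Dp, Dc);
    // Iyc now holds row i of Iy, used as the diagonal source for row i+1
  }

  if (bi < 0 || best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["columns"] = IntegerVector(0),
                        _["positions"] = IntegerVector(0));
  }

  std::vector<int> cols, poss;
  int i = bi, j = bj, state = 1;  // local alignments end in a match
  while (i > 0 && j > 0) {
    const size_t cur = (size_t)i * (L + 1) + j;
    if (state == 1) {
      cols.push_back(i);
      poss.push_back(j);
      state = pM[cur];
      --i; --j;
      if (state == 0) break;
    } else if (state == 2) {
      state = pD[cur];
      --i;
    } else {
      state = pI[cur];
      --j;
    }
  }
  std::reverse(cols.begin(), cols.end());
  std::reverse(poss.begin(), poss.end());

  return List::create(_["score"] = best,
                      _["columns"] = IntegerVector(cols.begin(), cols.end()),
                      _["positions"] = IntegerVector(poss.begin(), poss.end()));
}
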
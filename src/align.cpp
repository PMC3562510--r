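// Profile-profile global alignment for the progressive multiple aligner.
// Columns are scored sum-of-pairs with match +1, mismatch -1, residue/gap -2
// and gap/gap 0 (linear gap cost). Residue codes: 0 = gap, 1..4 = A,C,G,T,
// 5 = N (N scores as a mismatch against everything, including N).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double col_pair_score(const int *ca, int nA_rows,
                                    const int *cb, int nB_rows,
                                    double match, double mismatch,
                                    double gap) {
  // ca/cb: counts of codes 0..5 in the two columns
  int gA = ca[0], gB = cb[0];
  int nA = nA_rows - gA, nB = nB_rows - gB;
  double eq = 0.0;
  for (int c = 1; c <= 4; ++c) eq += (double)ca[c] * cb[c];
  double neq = (double)nA * nB - eq; // includes N-vs-anything pairs
  return eq * match + neq * mismatch + gap * ((double)nA * gB + (double)gA * nB);
}

// [[Rcpp::export]]
IntegerMatrix align_profiles_cpp(IntegerMatrix A, IntegerMatrix B,
                                 double match, double mismatch, double gap) {
  const int ra = A.nrow(), ca = A.ncol();
  const int rb = B.nrow(), cb = B.ncol();

  // per-column code counts
  std::vector<int> cntA((ca + 1) * 6, 0), cntB((cb + 1) * 6, 0);
  for (int j = 0; j < ca; ++j)
    for (int i = 0; i < ra; ++i) cntA[(j + 1) * 6 + A(i, j)]++;
  for (int j = 0; j < cb; ++j)
    for (int i = 0; i < rb; ++i) cntB[(j + 1) * 6 + B(i, j)]++;

  std::vector<double> gapA(ca + 1, 0.0), gapB(cb + 1, 0.0);
  for (int j = 1; j <= ca; ++j) // column j of A vs all-gap column in B
    gapA[j] = gap * (double)(ra - cntA[j * 6]) * rb;
  for (int j = 1; j <= cb; ++j)
    gapB[j] = gap * (double)(rb - cntB[j * 6]) * ra;

  NumericMatrix S(ca + 1, cb + 1);
  IntegerMatrix T(ca + 1, cb + 1); // 0 diag, 1 up (gap in B), 2 left (gap in A)
  for (int i = 1; i <= ca; ++i) { S(i, 0) = S(i - 1, 0) + gapA[i]; T(i, 0) = 1; }
  for (int j = 1; j <= cb; ++j) { S(0, j) = S(0, j - 1) + gapB[j]; T(0, j) = 2; }

  for (int i = 1; i <= ca; ++i) {
    const int *cai = &cntA[i * 6];
    for (int j = 1; j <= cb; ++j) {
      double d = S(i - 1, j - 1) +
        col_pair_score(cai, ra, &cntB[j * 6], rb, match, mismatch, gap);
      double u = S(i - 1, j) + gapA[i];
      double l = S(i, j - 1) + gapB[j];
      // prefer diagonal, then up, on ties (deterministic)
      if (d >= u && d >= l) { S(i, j) = d; T(i, j) = 0; }
      else if (u >= l)      { S(i, j) = u; T(i, j) = 1; }
      else                  { S(i, j) = l; T(i, j) = 2; }
    }
  }

  // traceback -> merged column list
  std::vector<int> opsA, opsB; // aligned column index or 0 for gap
  int i = ca, j = cb;
  while (i > 0 || j > 0) {
    int t = T(i, j);
    if (i > 0 && j > 0 && t == 0)      { opsA.push_back(i); opsB.push_back(j); --i; --j; }
    else if (i > 0 && (j == 0 || t == 1)) { opsA.push_back(i); opsB.push_back(0); --i; }
    else                               { opsA.push_back(0); opsB.push_back(j); --j; }
  }
  const int L = (int)opsA.size();
  IntegerMatrix M(ra + rb, L);
  for (int k = 0; k < L; ++k) {
    int col = L - 1 - k; // reverse order
    int ja = opsA[k], jb = opsB[k];
    for (int r = 0; r < ra; ++r) M(r, col) = ja ? A(r, ja - 1) : 0;
    for (int r = 0; r < rb; ++r) M(ra + r, col) = jb ? B(r, jb - 1) : 0;
  }
  M.attr("score") = S(ca, cb);
  return M;
}
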
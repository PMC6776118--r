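// Exact Smith-Waterman local alignment with affine gaps (BLAST-style cost:
// a gap of length L costs gap_open + gap_extend * L). Sequences arrive as
// 0-based integer codes indexing the substitution matrix. The all-vs-all
// proteome kernel is score-only (rolling rows, no traceback); identity and
// aligned length for accepted pairs come from the single-pair routine.
#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;
static const int NALPHA = 32; // >= substitution matrix dimension

struct Aln {
  int score, ident, alen;
  int astart, aend, bstart, bend; // 1-based, 0 when empty alignment
};

// Flatten the substitution matrix into a fixed-stride array for fast access.
static void flatten(const IntegerMatrix& S, int* flat) {
  const int d = S.nrow();
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) flat[i * NALPHA + j] = S(i, j);
}

// Score-only local alignment; two rolling rows per DP layer.
static int sw_score(const int* a, int n, const int* b, int m,
                    const int* flat, int openCost, int gapExt,
                    std::vector<int>& M, std::vector<int>& Ix, std::vector<int>& Iy) {
  for (int j = 0; j <= m; ++j) { M[j] = 0; Ix[j] = NEG; Iy[j] = NEG; }
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const int* srow = flat + a[i - 1] * NALPHA;
    int diagM = M[0], diagIx = Ix[0], diagIy = Iy[0];
    M[0] = 0; Ix[0] = NEG; Iy[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      int upM = M[j], upIx = Ix[j], upIy = Iy[j];
      int ix = std::max(upM - openCost, upIx - gapExt);
      int iy = std::max(M[j - 1] - openCost, Iy[j - 1] - gapExt);
      int pre = diagM;
      if (diagIx > pre) pre = diagIx;
      if (diagIy > pre) pre = diagIy;
      int v = pre + srow[b[j - 1]];
      if (v < 0) v = 0;
      M[j] = v; Ix[j] = ix; Iy[j] = iy;
      if (v > best) best = v;
      diagM = upM; diagIx = upIx; diagIy = upIy;
    }
  }
  return best;
}

// Full DP with traceback pointers; O(n*m) memory.
static Aln sw_trace(const std::vector<int>& a, const std::vector<int>& b,
                    const IntegerMatrix& S, int gapOpen, int gapExt) {
  const int n = (int)a.size(), m = (int)b.size();
  const int openCost = gapOpen + gapExt;
  std::vector<int> Mrow((size_t)(m + 1)), Ixrow((size_t)(m + 1)), Iyrow((size_t)(m + 1));
  std::vector<int> Mprev((size_t)(m + 1)), Ixprev((size_t)(m + 1)), Iyprev((size_t)(m + 1));
  std::vector<unsigned char> pM((size_t)(n + 1) * (m + 1), 0),
      pIx((size_t)(n + 1) * (m + 1), 0), pIy((size_t)(n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) { Mprev[j] = 0; Ixprev[j] = NEG; Iyprev[j] = NEG; }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Mrow[0] = 0; Ixrow[0] = NEG; Iyrow[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      int op = Mprev[j] - openCost, ex = Ixprev[j] - gapExt;
      if (op >= ex) { Ixrow[j] = op; pIx[idx(i, j)] = 0; }
      else          { Ixrow[j] = ex; pIx[idx(i, j)] = 1; }
      op = Mrow[j - 1] - openCost; ex = Iyrow[j - 1] - gapExt;
      if (op >= ex) { Iyrow[j] = op; pIy[idx(i, j)] = 0; }
      else          { Iyrow[j] = ex; pIy[idx(i, j)] = 1; }
      int s = S(a[(size_t)i - 1], b[(size_t)j - 1]);
      int pre = Mprev[j - 1]; unsigned char ptr = 1;
      if (Ixprev[j - 1] > pre) { pre = Ixprev[j - 1]; ptr = 2; }
      if (Iyprev[j - 1] > pre) { pre = Iyprev[j - 1]; ptr = 3; }
      int v = pre + s;
      if (v <= 0) { v = 0; ptr = 0; }
      Mrow[j] = v; pM[idx(i, j)] = ptr;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(Mrow, Mprev); std::swap(Ixrow, Ixprev); std::swap(Iyrow, Iyprev);
  }

  Aln r; r.score = best; r.ident = 0; r.alen = 0;
  r.astart = r.aend = r.bstart = r.bend = 0;
  if (best == 0) return r;
  int i = bi, j = bj, state = 0; // 0=M, 1=Ix(consume a), 2=Iy(consume b)
  r.aend = bi; r.bend = bj;
  while (true) {
    if (state == 0) {
      unsigned char ptr = pM[idx(i, j)];
      if (ptr == 0) break;
      ++r.alen;
      if (a[(size_t)i - 1] == b[(size_t)j - 1]) ++r.ident;
      --i; --j;
      state = (ptr == 1) ? 0 : (ptr == 2 ? 1 : 2);
      if (state == 0 && (i == 0 || j == 0 || pM[idx(i, j)] == 0)) break;
    } else if (state == 1) {
      ++r.alen;
      unsigned char ptr = pIx[idx(i, j)];
      --i;
      state = (ptr == 0) ? 0 : 1;
    } else {
      ++r.alen;
      unsigned char ptr = pIy[idx(i, j)];
      --j;
      state = (ptr == 0) ? 0 : 2;
    }
  }
  r.astart = i + 1; r.bstart = j + 1;
  return r;
}

static std::vector<int> to_vec(const IntegerVector& x) {
  return std::vector<int>(x.begin(), x.end());
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                  int gap_open, int gap_extend) {
  Aln r = sw_trace(to_vec(a), to_vec(b), S, gap_open, gap_extend);
  return List::create(_["score"] = r.score, _["identical"] = r.ident,
                      _["aligned_length"] = r.alen,
                      _["astart"] = r.astart, _["aend"] = r.aend,
                      _["bstart"] = r.bstart, _["bend"] = r.bend);
}

// All-vs-all optimal local-alignment scores of two proteomes (rows = A).
// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
IntegerMatrix sw_score_matrix_cpp(List A, List B, IntegerMatrix S,
                                  int gap_open, int gap_extend) {
  const int nA = A.size(), nB = B.size();
  std::vector<std::vector<int>> av(nA), bv(nB);
  int maxm = 1;
  for (int i = 0; i < nA; ++i) av[i] = to_vec(A[i]);
  for (int j = 0; j < nB; ++j) {
    bv[j] = to_vec(B[j]);
    if ((int)bv[j].size() > maxm) maxm = (int)bv[j].size();
  }
  std::vector<int> flat((size_t)NALPHA * NALPHA, 0);
  flatten(S, flat.data());
  std::vector<int> M(maxm + 1), Ix(maxm + 1), Iy(maxm + 1);
  IntegerMatrix score(nA, nB);
  const int openCost = gap_open + gap_extend;
  for (int i = 0; i < nA; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < nB; ++j)
      score(i, j) = sw_score(av[i].data(), (int)av[i].size(),
                             bv[j].data(), (int)bv[j].size(),
                             flat.data(), openCost, gap_extend, M, Ix, Iy);
  }
  return score;
}
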
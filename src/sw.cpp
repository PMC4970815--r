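// Full Smith-Waterman (Gotoh affine) reference implementation.
// Deliberately independent of the extension kernels in extend.cpp: it
// serves as the exact-alignment oracle in the test suite.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static const int SW_DELIM = 21;
static const long long SW_NEG = LLONG_MIN / 4;

static inline int swsub(const int* S, int a, int b) { return S[a + 22 * b]; }

// [[Rcpp::export]]
List cpp_smith_waterman(IntegerVector A, IntegerVector B,
                        IntegerMatrix smat, int go, int ge) {
  int m = A.size(), n = B.size();
  const int* S = smat.begin();
  long long goe = (long long)go + ge;
  size_t W = (size_t)n + 1;
  std::vector<long long> H((size_t)(m + 1) * W, 0),
      E((size_t)(m + 1) * W, SW_NEG), F((size_t)(m + 1) * W, SW_NEG);
  long long best = 0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t at = (size_t)i * W + j;
      long long e = std::max(H[at - 1] - goe,
                             E[at - 1] > SW_NEG / 2 ? E[at - 1] - ge : SW_NEG);
      long long f = std::max(H[at - W] - goe,
                             F[at - W] > SW_NEG / 2 ? F[at - W] - ge : SW_NEG);
      long long h = H[at - W - 1] + swsub(S, A[i - 1], B[j - 1]);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[at] = h;
      E[at] = e;
      F[at] = f;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> ops;
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    size_t at = (size_t)i * W + j;
    if (state == 0) {
      if (H[at] == 0) break;
      if (H[at] == H[at - W - 1] + swsub(S, A[i - 1], B[j - 1])) {
        ops.push_back(0);
        --i; --j;
      } else if (H[at] == E[at]) {
        state = 1;
      } else if (H[at] == F[at]) {
        state = 2;
      } else {
        stop("internal: inconsistent SW traceback");
      }
    } else if (state == 1) {
      ops.push_back(1);
      if (E[at] == H[at - 1] - goe) { --j; state = 0; }
      else { --j; state = 1; }
    } else {
      ops.push_back(2);
      if (F[at] == H[at - W] - goe) { --i; state = 0; }
      else { --i; state = 2; }
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = (double)best,
                      _["qstart"] = i, _["qend"] = bi,
                      _["sstart"] = j, _["send"] = bj,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

// Score-only SW of each query against each database sequence in a
// delimiter-concatenated store.  The delimiter resets the column so no
// alignment can bridge two database sequences.  Returns an nq x nseq
// integer matrix of per-sequence best scores.
// [[Rcpp::export]]
IntegerMatrix cpp_sw_scores(List qlist, IntegerVector dbcodes, int nseq,
                            IntegerMatrix smat, int go, int ge) {
  const int* S = smat.begin();
  const int* db = dbcodes.begin();
  int ncodes = dbcodes.size();
  long long goe = (long long)go + ge;
  int nq = qlist.size();
  IntegerMatrix out(nq, nseq);
  for (int qi = 0; qi < nq; ++qi) {
    IntegerVector qv = qlist[qi];
    const int* a = qv.begin();
    int m = qv.size();
    std::vector<long long> H(m + 1, 0), E(m + 1, SW_NEG);
    int curseq = -1;
    long long seqbest = 0;
    for (int j = 0; j < ncodes; ++j) {
      int b = db[j];
      if (b == SW_DELIM) {
        if (curseq >= 0) out(qi, curseq) = (int)seqbest;
        ++curseq;
        seqbest = 0;
        std::fill(H.begin(), H.end(), 0);
        std::fill(E.begin(), E.end(), SW_NEG);
        continue;
      }
      long long f = SW_NEG;
      long long diag = H[0];
      for (int i = 1; i <= m; ++i) {
        long long e = std::max(H[i] - goe,
                               E[i] > SW_NEG / 2 ? E[i] - ge : SW_NEG);
        f = std::max(H[i - 1] - goe, f > SW_NEG / 2 ? f - ge : SW_NEG);
        long long h = diag + swsub(S, a[i - 1], b);
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        diag = H[i];
        H[i] = h;
        E[i] = e;
        if (h > seqbest) seqbest = h;
      }
    }
    // trailing delimiter closes the last sequence; nothing left open
  }
  return out;
}
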
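#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static const int DELIM = 21;
static const long long NEG = LLONG_MIN / 4;

static inline int sub(const int* S, int a, int b) { return S[a + 22 * b]; }

// X-dropoff ungapped extension of a batch of seeds for one query
// segment.  Initial score is the sum over the L aligned seed columns;
// left/right walks stop when the running score falls more than Xu below
// the best seen (ties resolved toward the shortest extension) or at a
// delimiter / segment boundary.  Only segments with score >= Su are
// returned (columns: qstart, qend, dstart, dend, score).
// [[Rcpp::export]]
IntegerMatrix cpp_ungapped_extend(IntegerVector qcodes, IntegerVector dcodes,
                                  IntegerMatrix seeds, int L,
                                  IntegerMatrix smat, int Xu, int Su) {
  const int* q = qcodes.begin();
  const int* d = dcodes.begin();
  const int* S = smat.begin();
  int qlen = qcodes.size();
  std::vector<int> res;
  for (int r = 0; r < seeds.nrow(); ++r) {
    int qpos = seeds(r, 0), dpos = seeds(r, 1);
    long long score0 = 0;
    for (int i = 0; i < L; ++i) score0 += sub(S, q[qpos + i], d[dpos + i]);
    // right
    long long run = 0, bestR = 0;
    int rext = 0;
    for (int i = L; qpos + i < qlen; ++i) {
      if (d[dpos + i] == DELIM) break;
      run += sub(S, q[qpos + i], d[dpos + i]);
      if (run > bestR) { bestR = run; rext = i - L + 1; }
      if (run < bestR - Xu) break;
    }
    // left
    run = 0;
    long long bestL = 0;
    int lext = 0;
    for (int i = 1; qpos - i >= 0; ++i) {
      if (d[dpos - i] == DELIM) break;
      run += sub(S, q[qpos - i], d[dpos - i]);
      if (run > bestL) { bestL = run; lext = i; }
      if (run < bestL - Xu) break;
    }
    long long total = score0 + bestL + bestR;
    if (total >= Su) {
      res.push_back(qpos - lext);
      res.push_back(qpos + L + rext);
      res.push_back(dpos - lext);
      res.push_back(dpos + L + rext);
      res.push_back((int)total);
    }
  }
  int n = (int)res.size() / 5;
  IntegerMatrix out(n, 5);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 5; ++j) out(i, j) = res[5 * i + j];
  return out;
}

// Shared X-dropoff affine-gap extension DP (Gotoh) outward from an
// implicit anchor at (0,0): H(0,0)=0, leading gaps allowed, no local
// reset.  A cell state is pruned (set to -inf) when it falls more than
// Xg below the best score seen so far; the sweep keeps one row of the
// matrix (plus the column-wise F array).  When `keep` is non-null the
// full H/E/F matrices are stored for traceback.
struct XdropResult { long long best; int bi, bj; };

static XdropResult xdrop_dp(const int* A, int m, const int* B, int n,
                            const int* S, int go, int ge, long long Xg,
                            std::vector<long long>* keepH,
                            std::vector<long long>* keepE,
                            std::vector<long long>* keepF) {
  long long goe = (long long)go + ge;
  std::vector<long long> Hp(n + 1, NEG), Hc(n + 1, NEG), Fv(n + 1, NEG);
  long long best = 0;
  int bi = 0, bj = 0;
  size_t W = (size_t)n + 1;
  if (keepH) {
    keepH->assign((size_t)(m + 1) * W, NEG);
    keepE->assign((size_t)(m + 1) * W, NEG);
    keepF->assign((size_t)(m + 1) * W, NEG);
  }
  // row 0: leading gaps in A (consume B)
  Hp[0] = 0;
  if (keepH) (*keepH)[0] = 0;
  int phi = 0;
  {
    long long e = NEG;
    for (int j = 1; j <= n; ++j) {
      long long h = Hp[j - 1];
      e = std::max(h > NEG / 2 ? h - goe : NEG, e > NEG / 2 ? e - ge : NEG);
      if (e < best - Xg) e = NEG;
      Hp[j] = e;
      if (keepH) { (*keepH)[j] = e; (*keepE)[j] = e; }
      if (e == NEG) break;
      phi = j;
    }
  }
  int plo = 0, pvlo = 0, pvhi = phi;
  for (int i = 1; i <= m; ++i) {
    long long e = NEG;
    int nlo = -1, nhi = -1;
    int vlo = plo, vhi = plo - 1;
    for (int j = plo; j <= n; ++j) {
      long long hup = (j >= pvlo && j <= pvhi) ? Hp[j] : NEG;
      long long fup = (j >= pvlo && j <= pvhi) ? Fv[j] : NEG;
      long long f = std::max(hup > NEG / 2 ? hup - goe : NEG,
                             fup > NEG / 2 ? fup - ge : NEG);
      if (f < best - Xg) f = NEG;
      long long diag = NEG;
      if (j >= 1 && j - 1 >= pvlo && j - 1 <= pvhi) diag = Hp[j - 1];
      long long h = NEG;
      if (j >= 1 && diag > NEG / 2) h = diag + sub(S, A[i - 1], B[j - 1]);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < best - Xg) h = NEG;
      Hc[j] = h;
      Fv[j] = f;
      vhi = j;
      if (keepH) {
        size_t at = (size_t)i * W + j;
        (*keepH)[at] = h;
        (*keepE)[at] = e;
        (*keepF)[at] = f;
      }
      if (h > best) { best = h; bi = i; bj = j; }
      if (h > NEG || f > NEG || e > NEG) {
        if (nlo < 0) nlo = j;
        nhi = j;
      }
      long long enext = std::max(h > NEG / 2 ? h - goe : NEG,
                                 e > NEG / 2 ? e - ge : NEG);
      if (enext < best - Xg) enext = NEG;
      e = enext;
      if (j > pvhi + 1 && e == NEG && h == NEG && f == NEG) break;
    }
    if (nlo < 0) break;  // band empty: extension terminated
    std::swap(Hp, Hc);
    plo = nlo;
    pvlo = vlo;
    pvhi = vhi;
  }
  XdropResult r = {best, bi, bj};
  return r;
}

static void truncate_at_delim(IntegerVector& v) {
  for (int i = 0; i < v.size(); ++i) {
    if (v[i] == DELIM) stop("internal: delimiter inside extension slice");
  }
}

// [[Rcpp::export]]
IntegerVector cpp_xdrop_score(IntegerVector A, IntegerVector B,
                              IntegerMatrix smat, int go, int ge, double Xg) {
  truncate_at_delim(A);
  truncate_at_delim(B);
  long long xg = (Xg > 1e17) ? (LLONG_MAX / 8) : (long long)Xg;
  XdropResult r = xdrop_dp(A.begin(), A.size(), B.begin(), B.size(),
                           smat.begin(), go, ge, xg, 0, 0, 0);
  return IntegerVector::create((int)r.best, r.bi, r.bj);
}

// Re-runs the identical pruned DP with full matrices and returns the
// operation path from (0,0) to the recorded best cell (ei, ej).
// ops: 0 = aligned pair, 1 = gap in A (consumes B), 2 = gap in B.
// [[Rcpp::export]]
List cpp_xdrop_traceback(IntegerVector A, IntegerVector B,
                         IntegerMatrix smat, int go, int ge, double Xg,
                         int ei, int ej) {
  truncate_at_delim(A);
  truncate_at_delim(B);
  long long xg = (Xg > 1e17) ? (LLONG_MAX / 8) : (long long)Xg;
  int m = A.size(), n = B.size();
  std::vector<long long> H, E, F;
  XdropResult r = xdrop_dp(A.begin(), m, B.begin(), n, smat.begin(),
                           go, ge, xg, &H, &E, &F);
  size_t W = (size_t)n + 1;
  if (ei > m || ej > n || H[(size_t)ei * W + ej] <= NEG / 2)
    stop("internal: traceback end cell not reachable");
  long long goe = (long long)go + ge;
  const int* S = smat.begin();
  std::vector<int> ops;
  int i = ei, j = ej, state = 0;  // 0=H, 1=E, 2=F
  while (i != 0 || j != 0) {
    size_t at = (size_t)i * W + j;
    if (state == 0) {
      long long h = H[at];
      if (i > 0 && j > 0 && H[at - W - 1] > NEG / 2 &&
          h == H[at - W - 1] + sub(S, A[i - 1], B[j - 1])) {
        ops.push_back(0);
        --i; --j;
      } else if (h == E[at]) {
        state = 1;
      } else if (h == F[at]) {
        state = 2;
      } else {
        stop("internal: inconsistent traceback (H)");
      }
    } else if (state == 1) {
      long long e = E[at];
      ops.push_back(1);
      if (j > 0 && H[at - 1] > NEG / 2 && e == H[at - 1] - goe) {
        --j; state = 0;
      } else if (j > 0 && E[at - 1] > NEG / 2 && e == E[at - 1] - ge) {
        --j; state = 1;
      } else {
        stop("internal: inconsistent traceback (E)");
      }
    } else {
      long long f = F[at];
      ops.push_back(2);
      if (i > 0 && H[at - W] > NEG / 2 && f == H[at - W] - goe) {
        --i; state = 0;
      } else if (i > 0 && F[at - W] > NEG / 2 && f == F[at - W] - ge) {
        --i; state = 2;
      } else {
        stop("internal: inconsistent traceback (F)");
      }
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = IntegerVector(ops.begin(), ops.end()),
                      _["score"] = (int)H[(size_t)ei * W + ej],
                      _["best"] = (int)r.best);
}
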
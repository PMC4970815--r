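#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// base-10 positional key of the first kh group ids; -1 if the prefix
// contains the X group (10) or the delimiter group (11)
static inline int key_of(const int* g, int kh) {
  int key = 0;
  for (int i = 0; i < kh; ++i) {
    if (g[i] >= 10) return -1;
    key = key * 10 + g[i];
  }
  return key;
}

// Single-pass greedy clustering in position order: each keyable window
// joins the first existing cluster (creation order) sharing its hash
// key whose representative lies within Tc in reduced-Hamming distance,
// else founds a new cluster.
// [[Rcpp::export]]
List cpp_greedy_cluster(IntegerVector groups, IntegerVector positions,
                        int L, int Tc, int kh) {
  const int* g = groups.begin();
  std::vector<int> rep;
  std::vector< std::vector<int> > mem, dst;
  std::unordered_map<int, std::vector<int> > bykey;
  for (int idx = 0; idx < positions.size(); ++idx) {
    int p = positions[idx];
    int key = key_of(g + p, kh);
    if (key < 0) continue;  // unkeyable windows are not indexed
    std::vector<int>& cand = bykey[key];
    int joined = -1, jd = 0;
    for (size_t c = 0; c < cand.size(); ++c) {
      int cid = cand[c];
      const int* a = g + p;
      const int* b = g + rep[cid];
      int d = 0;
      for (int i = 0; i < L; ++i) d += (a[i] != b[i]);
      if (d <= Tc) { joined = cid; jd = d; break; }
    }
    if (joined >= 0) {
      mem[joined].push_back(p);
      dst[joined].push_back(jd);
    } else {
      rep.push_back(p);
      mem.push_back(std::vector<int>());
      dst.push_back(std::vector<int>());
      cand.push_back((int)rep.size() - 1);
    }
  }
  int nc = (int)rep.size();
  List members(nc), dists(nc);
  for (int c = 0; c < nc; ++c) {
    members[c] = IntegerVector(mem[c].begin(), mem[c].end());
    dists[c] = IntegerVector(dst[c].begin(), dst[c].end());
  }
  return List::create(_["rep"] = IntegerVector(rep.begin(), rep.end()),
                      _["members"] = members, _["dists"] = dists);
}

// [[Rcpp::export]]
int cpp_hamming(IntegerVector a, IntegerVector b) {
  if (a.size() != b.size()) stop("hamming_distance(): length mismatch");
  int d = 0;
  for (int i = 0; i < a.size(); ++i) d += (a[i] != b[i]);
  return d;
}
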
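#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_set>
#include <cstdlib>
using namespace Rcpp;

static inline int prefix_key(const int* g, int kh) {
  int key = 0;
  for (int i = 0; i < kh; ++i) {
    if (g[i] >= 10) return -1;
    key = key * 10 + g[i];
  }
  return key;
}

struct SeedRec { int qpos, dpos, prov, lb; };

// Seed search + triangle-inequality similarity filtering for a batch of
// query segments against one chunk's B_e/B_r/B_m tables.  Tables arrive
// flattened (sorted keys + offset arrays); dense key->slot lookups are
// rebuilt here once per call.  Returns one 4-column matrix per segment
// (qpos, dpos, provenance 0=singleton/1=representative/2=member, lb)
// plus the number of full distance evaluations performed.
// [[Rcpp::export]]
List cpp_search_seeds(List qgroups_list,
                      IntegerVector be_keys, IntegerVector be_off,
                      IntegerVector be_pos,
                      IntegerVector br_keys, IntegerVector br_off,
                      IntegerVector br_cid,
                      IntegerVector bm_rep, IntegerVector bm_off,
                      IntegerVector bm_member, IntegerVector bm_dist,
                      IntegerVector dgroups, int L, int kh, int Tf,
                      int rh) {
  int keyspace = 1;
  for (int i = 0; i < kh; ++i) keyspace *= 10;
  std::vector<int> beslot(keyspace, -1), brslot(keyspace, -1);
  for (int i = 0; i < be_keys.size(); ++i) beslot[be_keys[i]] = i;
  for (int i = 0; i < br_keys.size(); ++i) brslot[br_keys[i]] = i;
  const int* dg = dgroups.begin();
  double ndist = 0.0;
  int nseg = qgroups_list.size();
  List out(nseg);
  std::vector<int> pow10(kh);
  pow10[kh - 1] = 1;
  for (int i = kh - 2; i >= 0; --i) pow10[i] = pow10[i + 1] * 10;

  for (int si = 0; si < nseg; ++si) {
    IntegerVector qg = qgroups_list[si];
    const int* q = qg.begin();
    int qlen = qg.size();
    std::vector<SeedRec> hits;
    std::vector<int> keys;
    for (int qpos = 0; qpos + L <= qlen; ++qpos) {
      int exact = prefix_key(q + qpos, kh);
      if (exact < 0) continue;
      keys.clear();
      keys.push_back(exact);
      if (rh >= 1) {
        size_t nb0 = keys.size();
        for (int i = 0; i < kh; ++i) {
          int gi = q[qpos + i];
          for (int alt = 0; alt <= 9; ++alt) {
            if (alt == gi) continue;
            keys.push_back(exact + (alt - gi) * pow10[i]);
          }
        }
        std::sort(keys.begin() + nb0, keys.end());
      }
      size_t first_hit = hits.size();
      std::unordered_set<int> seen;
      for (size_t ki = 0; ki < keys.size(); ++ki) {
        int key = keys[ki];
        int s = beslot[key];
        if (s >= 0) {
          for (int j = be_off[s]; j < be_off[s + 1]; ++j) {
            int p = be_pos[j];
            int D = 0;
            const int* w = dg + p;
            for (int t = 0; t < L; ++t) D += (q[qpos + t] != w[t]);
            ndist += 1.0;
            if (D <= Tf && seen.insert(p).second) {
              SeedRec r = {qpos, p, 0, D};
              hits.push_back(r);
            }
          }
        }
        s = brslot[key];
        if (s >= 0) {
          for (int j = br_off[s]; j < br_off[s + 1]; ++j) {
            int cid = br_cid[j];
            int rp = bm_rep[cid];
            int D = 0;
            const int* w = dg + rp;
            for (int t = 0; t < L; ++t) D += (q[qpos + t] != w[t]);
            ndist += 1.0;
            if (D <= Tf && seen.insert(rp).second) {
              SeedRec r = {qpos, rp, 1, D};
              hits.push_back(r);
            }
            for (int t = bm_off[cid]; t < bm_off[cid + 1]; ++t) {
              int lb = std::abs(D - bm_dist[t]);
              if (lb <= Tf && seen.insert(bm_member[t]).second) {
                SeedRec r = {qpos, bm_member[t], 2, lb};
                hits.push_back(r);
              }
            }
          }
        }
      }
      std::sort(hits.begin() + first_hit, hits.end(),
                [](const SeedRec& a, const SeedRec& b) {
                  return a.dpos < b.dpos;
                });
    }
    IntegerMatrix m((int)hits.size(), 4);
    for (size_t i = 0; i < hits.size(); ++i) {
      m(i, 0) = hits[i].qpos;
      m(i, 1) = hits[i].dpos;
      m(i, 2) = hits[i].prov;
      m(i, 3) = hits[i].lb;
    }
    out[si] = m;
  }
  out.attr("n_dist_evals") = ndist;
  return out;
}
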
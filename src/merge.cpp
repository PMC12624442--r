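#include "core.h"
using namespace Rcpp;

// Linear merge of two sorted genome indices, reporting every non-repetitive
// adaptamer of G together with all its matching positions in H.  The state
// (fst, lst, L, cur, wall) is carried from one G K-mer to the next using
// only the lcp chains of the two indices; lst is capped at fst + tau + 1,
// which marks the range as repetitive without affecting correctness.
//
// Records with identical K-mers form groups (runs with lcp == K); the sweep
// walks groups, so occurrence counts are the group sizes.  A virtual
// sentinel group beyond the end of H is lexicographically larger than any
// K-mer and has lcp 0.

namespace {

struct GroupedIndex {
  const uint8_t *keys;
  const int *lcp;
  int kw, K, nrec;
  std::vector<int> gstart;   // record index of first member, + nrec sentinel
  std::vector<int> glcp;     // lcp of the group's K-mer with its predecessor
  int ng;

  void build() {
    gstart.clear();
    glcp.clear();
    for (int i = 0; i < nrec; ++i) {
      if (i == 0 || lcp[i] < K) {
        gstart.push_back(i);
        glcp.push_back(i == 0 ? 0 : lcp[i]);
      }
    }
    ng = (int)gstart.size();
    gstart.push_back(nrec);
  }
  inline int gsize(int g) const { return gstart[g + 1] - gstart[g]; }
  inline const uint8_t *gkey(int g) const {
    return keys + (size_t)gstart[g] * kw;
  }
  // base at offset j of group g's K-mer; the sentinel group reads as a
  // symbol larger than any base
  inline int gbase(int g, int j) const {
    if (g >= ng) return 4;
    return aa_key_base(gkey(g), j);
  }
  inline int group_lcp(int g) const { return g >= ng ? 0 : glcp[g]; }
};

}  // namespace

// [[Rcpp::export]]
List cpp_merge_indices(RawVector gkeys, IntegerVector glcp,
                       IntegerVector gcontig, IntegerVector gpos,
                       IntegerVector gstrand, RawVector hkeys,
                       IntegerVector hlcp, IntegerVector hcontig,
                       IntegerVector hpos, IntegerVector hstrand, int K,
                       int kw, int tau, int min_len, bool debug) {
  GroupedIndex G{RAW(gkeys), INTEGER(glcp), kw, K, (int)glcp.size()};
  GroupedIndex H{RAW(hkeys), INTEGER(hlcp), kw, K, (int)hlcp.size()};
  G.build();
  H.build();

  // prefix sums of H group sizes for the repetitiveness test
  std::vector<int> hcum(H.ng + 1, 0);
  for (int g = 0; g < H.ng; ++g) hcum[g + 1] = hcum[g] + H.gsize(g);

  std::vector<int> out_qc, out_qp, out_tc, out_tp, out_ts, out_tl;
  std::vector<int> dbg_fst, dbg_lst, dbg_L;
  long long char_cmps = 0;

  int fst = -1, lst = 0, L = K, cur = -1;
  std::vector<int> wall(K + 1, 0);
  const uint8_t *beta = nullptr;

  // extension(): advance cur until H[cur].kmer >= beta, growing L
  auto extension = [&]() {
    while (L < K) {
      int b = aa_key_base(beta, L);
      while (true) {
        ++char_cmps;
        int hb = H.gbase(cur, L);
        if (hb >= b) break;
        cur += 1;
        if (H.group_lcp(cur) < L) {
          lst = cur;
          return;
        }
      }
      if (H.gbase(cur, L) > b) break;
      L += 1;
      fst = wall[L] = cur;
    }
    lst = cur + 1;
    if (L < K) {
      while (lst < H.ng && H.group_lcp(lst) >= L && lst <= fst + tau) lst += 1;
    }
  };

  for (int i = 0; i < G.ng; ++i) {
    beta = G.gkey(i);
    int lam = G.group_lcp(i);
    if (lam == L && cur < lst) {
      extension();
    } else if (lam < L) {
      cur = lst;
      while (H.group_lcp(cur) > lam) cur += 1;
      L = lam;
      fst = wall[lam];
      if (H.group_lcp(cur) == lam)
        extension();
      else
        lst = cur;
    }
    // else lam > L: state unchanged

    if (debug) {
      dbg_fst.push_back(fst);
      dbg_lst.push_back(lst);
      dbg_L.push_back(L);
    }
    if (L >= min_len && fst >= 0) {
      int hi = std::min(lst, H.ng);
      if (hi > fst && hcum[hi] - hcum[fst] <= tau) {
        for (int gr = G.gstart[i]; gr < G.gstart[i + 1]; ++gr) {
          if (gstrand[gr] < 0) continue;  // G side: forward strand only
          for (int hg = fst; hg < hi; ++hg) {
            for (int hr = H.gstart[hg]; hr < H.gstart[hg + 1]; ++hr) {
              out_qc.push_back(gcontig[gr]);
              out_qp.push_back(gpos[gr]);
              out_tc.push_back(hcontig[hr]);
              out_tp.push_back(hpos[hr]);
              out_ts.push_back(hstrand[hr]);
              out_tl.push_back(L);
            }
          }
        }
      }
    }
  }

  List res = List::create(
      _["contig_g"] = wrap(out_qc), _["pos_g"] = wrap(out_qp),
      _["contig_h"] = wrap(out_tc), _["pos_h"] = wrap(out_tp),
      _["strand"] = wrap(out_ts), _["t"] = wrap(out_tl),
      _["char_cmps"] = (double)char_cmps);
  if (debug) {
    res["debug"] = List::create(
        _["fst"] = wrap(dbg_fst), _["lst"] = wrap(dbg_lst),
        _["L"] = wrap(dbg_L),
        _["h_group_start"] = wrap(H.gstart),
        _["g_group_start"] = wrap(G.gstart));
  }
  return res;
}
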
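#include "core.h"
using namespace Rcpp;

// Unit-cost furthest-reaching ("wave") alignment machinery:
//   cpp_align_global  - optimal global alignment with path, storing all
//                       waves for traceback (used per trace-point panel and
//                       to deliver the path between local endpoints)
//   cpp_la_finder     - local alignment through a given anti-diagonal
//                       between diagonal bounds: anchor on the best exact
//                       run crossing the anti-diagonal, extend with greedy
//                       waves in both directions under a trailing-window
//                       identity stop rule, then trim to the maximal-scoring
//                       local segment of the optimal path
//   cpp_refine_wave   - insertion-only re-alignment of a trapezoid under
//                       gap-open cost 1 / gap-extend cost 0, minimising
//                       gaps + mismatches (compressed wave with Snake)

namespace {

const int NEG = INT_MIN / 4;

// ------------------------------------------------------------------ global

struct GlobalAligner {
  const int *a, *b;
  int n, m;
  std::vector<std::vector<int>> waves;  // waves[k][d + k] = furthest i

  inline int snake(int i, int j) const {
    int s = 0;
    while (i + s < n && j + s < m && a[i + s] == b[j + s]) ++s;
    return s;
  }
  inline int getf(int k, int d) const {
    if (d < -k || d > k || d < -m || d > n) return NEG;
    return waves[k][d + k];
  }

  // returns edit distance; fills waves
  int run() {
    int dgoal = n - m;
    waves.clear();
    waves.push_back(std::vector<int>(1, snake(0, 0)));
    if (waves[0][0] >= n && dgoal == 0) return 0;
    for (int k = 1;; ++k) {
      std::vector<int> w(2 * k + 1, NEG);
      for (int d = -k; d <= k; ++d) {
        if (d < -m || d > n) continue;
        int i = NEG;
        int c = getf(k - 1, d - 1);  // consume A only (dash in B)
        if (c != NEG && c < n && c + 1 > i) i = c + 1;
        c = getf(k - 1, d + 1);      // consume B only (dash in A)
        if (c != NEG && c - d <= m && c > i) i = c;
        c = getf(k - 1, d);          // substitution
        if (c != NEG && c < n && c - d < m && c + 1 > i) i = c + 1;
        if (i == NEG) continue;
        int j = i - d;
        w[d + k] = i + snake(i, j);
      }
      waves.push_back(std::move(w));
      if (dgoal >= -k && dgoal <= k && waves[k][dgoal + k] >= n) return k;
      if (k > n + m) stop("wave failed to terminate");  // cannot happen
    }
  }

  // path ops (OP_*) from the stored waves
  std::vector<int> traceback(int kfin) const {
    std::vector<int> rops;
    int d = n - m, k = kfin, i = n;
    while (k > 0) {
      int cA = getf(k - 1, d - 1), cB = getf(k - 1, d + 1),
          cS = getf(k - 1, d);
      int bestA = (cA != NEG && cA < n) ? cA + 1 : NEG;
      int bestB = (cB != NEG && cB - d <= m) ? cB : NEG;
      int bestS = (cS != NEG && cS < n && cS - d < m) ? cS + 1 : NEG;
      int istart = std::max(bestA, std::max(bestB, bestS));
      for (int t = 0; t < i - istart; ++t) rops.push_back(OP_DIAG);
      if (bestS == istart) {  // prefer substitution
        rops.push_back(OP_DIAG);
        i = cS;
      } else if (bestA == istart) {
        rops.push_back(OP_DELB);
        i = cA;
        d = d - 1;
      } else {
        rops.push_back(OP_INSB);
        i = cB;
        d = d + 1;
      }
      --k;
    }
    for (int t = 0; t < i; ++t) rops.push_back(OP_DIAG);
    std::reverse(rops.begin(), rops.end());
    return rops;
  }
};

// ------------------------------------------------------- greedy extension

// Greedy forward extension: unit-cost waves scored as
// max_div * anti - 2k (zero slope exactly at divergence max_div), stopping
// when the wave's best score falls `xdrop` below the best seen.  The drop
// allowance is sized to cross a single gap of max_gap bases, while random
// sequence (score slope ~ -1.2 per difference) terminates the extension
// within O(xdrop) waves.  Returns the endpoint maximising the score.
struct ExtendResult {
  int ei, ej;     // best-scoring endpoint (absolute)
  int k;          // cost at the best endpoint
  int far_anti;   // furthest anti-diagonal reached (relative)
};

// Extension is confined to diagonals [dmin, dmax] (relative to the start
// point): without a band limit the furthest frontier over an ever-growing
// set of diagonals advances fast enough on random sequence that the score
// barely drops, so the band plus a drift margin keeps noise exploration
// bounded while real alignment paths, whose diagonal drifts only by the
// indel imbalance, stay well inside it.
// view of a sequence slice walked forward (dir = +1, from p) or backward
// (dir = -1, positions p[-1], p[-2], ... without copying)
struct SeqView {
  const int *p;
  int dir;
  int len;
  inline int at(int i) const { return dir > 0 ? p[i] : p[-1 - i]; }
};

static ExtendResult wave_extend(SeqView av, SeqView bv, double max_div,
                                double xdrop, int kcap, int dmin, int dmax) {
  const int n = av.len, m = bv.len;
  auto snake = [&](int i, int j) {
    int s = 0;
    while (i + s < n && j + s < m && av.at(i + s) == bv.at(j + s)) ++s;
    return s;
  };
  std::vector<int> f(1, snake(0, 0));
  int best_i = f[0], best_j = f[0], best_k = 0;
  double best_score = max_div * (2.0 * f[0]);
  int far = 2 * f[0];
  bool done = (f[0] >= n && f[0] >= m);
  for (int k = 1; !done && k <= kcap; ++k) {
    std::vector<int> nf(2 * k + 1, NEG);
    int far_k = -1;
    for (int d = -k; d <= k; ++d) {
      if (d < -m || d > n || d < dmin || d > dmax) continue;
      int i = NEG, c;
      if (d - 1 >= -(k - 1) && (c = f[d - 1 + k - 1]) != NEG && c < n)
        i = c + 1;
      if (d + 1 <= k - 1 && (c = f[d + 1 + k - 1]) != NEG && c - d <= m &&
          c > i)
        i = c;
      if (d >= -(k - 1) && d <= k - 1 && (c = f[d + k - 1]) != NEG && c < n &&
          c - d < m && c + 1 > i)
        i = c + 1;
      if (i == NEG) continue;
      int j = i - d;
      i += snake(i, j);
      j = i - d;
      nf[d + k] = i;
      int anti = i + j;
      if (anti > far_k) far_k = anti;
      double sc = max_div * anti - 2.0 * k;
      if (sc > best_score) {
        best_score = sc;
        best_i = i;
        best_j = j;
        best_k = k;
      }
      if (i >= n && j >= m) done = true;  // reached the corner
    }
    if (far_k < far) far_k = far;
    far = far_k;
    f = std::move(nf);
    if (best_score - (max_div * far - 2.0 * k) > xdrop) break;
  }
  ExtendResult r;
  r.ei = best_i;
  r.ej = best_j;
  r.k = best_k;
  r.far_anti = far;
  return r;
}

struct LAResult {
  int ab, ae, bb, be, diffs, atop;
  std::vector<int> ops;
};

// Local alignment through anti-diagonal `anti` between diagonals
// [d_low, d_high] of the matrix of A (rows) vs B (columns).
static LAResult la_core(const int *A, int n, const int *B, int m, int anti,
                        int d_low, int d_high, double max_div, int max_gap,
                        double xdrop, int kcap, double min_score) {
  // anchor: longest exact run crossing `anti` within the diagonal bounds
  int best_len = -1, ai = 0, aj = 0, afwd = 0, abwd = 0;
  for (int d = d_low; d <= d_high; ++d) {
    long long s = (long long)anti + d;
    if (s & 1) continue;
    int i = (int)(s / 2), j = anti - i;
    if (i < 0 || j < 0 || i > n || j > m) continue;
    int fwd = 0;
    while (i + fwd < n && j + fwd < m && A[i + fwd] == B[j + fwd]) ++fwd;
    int bwd = 0;
    while (i - bwd > 0 && j - bwd > 0 && A[i - bwd - 1] == B[j - bwd - 1]) ++bwd;
    if (fwd + bwd > best_len) {
      best_len = fwd + bwd;
      ai = i;
      aj = j;
      afwd = fwd;
      abwd = bwd;
    }
  }
  if (best_len < 0) {
    int i0 = std::max(0, std::min(n, anti / 2));
    return LAResult{i0, i0, 0, 0, 0, anti, {}};
  }

  // diagonal confinement: the tube band plus a drift margin
  int margin = max_gap + 60;
  // forward from the end of the anchor run
  int fi0 = ai + afwd, fj0 = aj + afwd;
  int d0f = fi0 - fj0;
  ExtendResult fw = wave_extend(SeqView{A + fi0, 1, n - fi0},
                                SeqView{B + fj0, 1, m - fj0}, max_div,
                                xdrop, kcap, d_low - margin - d0f,
                                d_high + margin - d0f);
  // backward from the start of the run, walking the prefixes in reverse;
  // a relative diagonal drel there corresponds to absolute d0b - drel
  int bi0 = ai - abwd, bj0 = aj - abwd;
  int d0b = bi0 - bj0;
  ExtendResult bw = wave_extend(SeqView{A + bi0, -1, bi0},
                                SeqView{B + bj0, -1, bj0}, max_div,
                                xdrop, kcap, d0b - (d_high + margin),
                                d0b - (d_low - margin));

  int ab = bi0 - bw.ei, bb = bj0 - bw.ej;
  int ae = fi0 + fw.ei, be = fj0 + fw.ej;

  // optimal path between the extended endpoints
  std::vector<int> sa(A + ab, A + ae), sb(B + bb, B + be);
  GlobalAligner g{sa.data(), sb.data(), (int)sa.size(), (int)sb.size()};
  int dtot = g.run();
  std::vector<int> ops = g.traceback(dtot);

  // trim to the maximal-scoring local segment (match +1, difference -mu)
  double mu = max_div < 1.0 ? (1.0 - max_div) / max_div : 0.0;
  double run = 0.0, best = 0.0;
  int i = ab, j = bb, seg_i = ab, seg_j = bb;
  int t_ab = ab, t_bb = bb, t_ae = ab, t_be = bb;
  size_t seg_start = 0, best_lo = 0, best_hi = 0;
  for (size_t t = 0; t < ops.size(); ++t) {
    double stepsc;
    int op = ops[t];
    if (op == OP_DIAG && A[i] == B[j])
      stepsc = 1.0;
    else
      stepsc = -mu;
    if (run <= 0) {
      run = 0;
      seg_i = i;
      seg_j = j;
      seg_start = t;
    }
    run += stepsc;
    if (op != OP_INSB) ++i;
    if (op != OP_DELB) ++j;
    if (run > best) {
      best = run;
      t_ab = seg_i;
      t_bb = seg_j;
      t_ae = i;
      t_be = j;
      best_lo = seg_start;
      best_hi = t + 1;
    }
  }
  if (best <= min_score) {
    return LAResult{ai, ai, aj, aj, 0, anti, {}};
  }
  std::vector<int> tops(ops.begin() + best_lo, ops.begin() + best_hi);
  // count differences along the trimmed sub-path
  int diffs = 0;
  i = t_ab;
  j = t_bb;
  for (size_t t = 0; t < tops.size(); ++t) {
    int op = tops[t];
    if (op != OP_DIAG || A[i] != B[j]) ++diffs;
    if (op != OP_INSB) ++i;
    if (op != OP_DELB) ++j;
  }
  return LAResult{t_ab, t_ae, t_bb, t_be, diffs, t_ae + t_be,
                  std::move(tops)};
}

// split a path at single gaps longer than max_gap; keep pieces passing the
// length and divergence filters
struct Piece {
  int ab, ae, bb, be, diffs;
  std::vector<int> ops;
};

static void split_and_filter(const LAResult &r, const int *A, const int *B,
                             int max_gap, int min_length, double max_div,
                             double split_drop, std::vector<Piece> &out) {
  size_t nops = r.ops.size();
  // First, segment the path wherever its local score (match +1, difference
  // -(1-e)/e) falls split_drop below the running peak: the maximal-scoring
  // trim can legitimately bridge an unalignable stretch when both flanks
  // are strong, but such a stretch is a break in similarity and the pieces
  // must be reported separately.  Each emitted segment ends at its score
  // peak and the next starts after the intervening valley.
  double mu = max_div < 1.0 ? (1.0 - max_div) / max_div : 0.0;
  std::vector<size_t> cuts;  // piece boundaries as op indices
  {
    int i = r.ab, j = r.bb;
    double cum = 0, peak = 0, vmin = 0;
    size_t piece_start = 0, peak_t = 0, v_t = 0;
    bool valley = false;
    std::vector<std::pair<size_t, size_t>> segs;
    for (size_t t = 0; t < nops; ++t) {
      int op = r.ops[t];
      double sc = (op == OP_DIAG && A[i] == B[j]) ? 1.0 : -mu;
      cum += sc;
      if (op != OP_INSB) ++i;
      if (op != OP_DELB) ++j;
      if (!valley) {
        if (cum >= peak) {
          peak = cum;
          peak_t = t + 1;
        } else if (peak - cum > split_drop) {
          segs.push_back({piece_start, peak_t});
          valley = true;
          vmin = cum;
          v_t = t + 1;
        }
      } else {
        if (cum <= vmin) {
          vmin = cum;
          v_t = t + 1;
        } else if (cum - vmin >= 1.0) {  // climbing again: new piece
          valley = false;
          piece_start = v_t;
          peak = cum;
          peak_t = t + 1;
        }
      }
    }
    if (!valley && peak_t > piece_start) segs.push_back({piece_start, peak_t});
    for (auto &sg : segs) {
      cuts.push_back(sg.first);
      // further split each segment at single gaps above max_gap
      size_t t = sg.first;
      while (t < sg.second) {
        size_t u = t;
        while (u < sg.second && r.ops[u] == r.ops[t]) ++u;
        if (r.ops[t] != OP_DIAG && (int)(u - t) > max_gap) {
          cuts.push_back(t);
          cuts.push_back(u);
        }
        t = u;
      }
      cuts.push_back(sg.second);
    }
  }
  for (size_t c = 0; c + 1 < cuts.size(); c += 2) {
    size_t lo = cuts[c], hi = cuts[c + 1];
    if (hi <= lo) continue;
    // coordinates and diffs of the piece
    int i = r.ab, j = r.bb;
    for (size_t x = 0; x < lo; ++x) {
      if (r.ops[x] != OP_INSB) ++i;
      if (r.ops[x] != OP_DELB) ++j;
    }
    int pab = i, pbb = j, diffs = 0;
    for (size_t x = lo; x < hi; ++x) {
      int op = r.ops[x];
      if (op != OP_DIAG || A[i] != B[j]) ++diffs;
      if (op != OP_INSB) ++i;
      if (op != OP_DELB) ++j;
    }
    int pae = i, pbe = j;
    if (pae - pab < min_length) continue;
    if ((double)diffs / (pae - pab) > max_div) continue;
    Piece pc;
    pc.ab = pab; pc.ae = pae; pc.bb = pbb; pc.be = pbe; pc.diffs = diffs;
    pc.ops.assign(r.ops.begin() + lo, r.ops.begin() + hi);
    out.push_back(std::move(pc));
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_align_global(IntegerVector a, IntegerVector b) {
  GlobalAligner g{INTEGER(a), INTEGER(b), (int)a.size(), (int)b.size()};
  int d = g.run();
  std::vector<int> ops = g.traceback(d);
  return List::create(_["diffs"] = d, _["ops"] = wrap(ops));
}

// [[Rcpp::export]]
List cpp_la_finder(IntegerVector a, IntegerVector b, int anti, int d_low,
                   int d_high, double max_div, int max_gap, double xdrop,
                   int kcap, double min_score) {
  LAResult r = la_core(INTEGER(a), a.size(), INTEGER(b), b.size(), anti,
                       d_low, d_high, max_div, max_gap, xdrop, kcap,
                       min_score);
  return List::create(_["ab"] = r.ab, _["ae"] = r.ae, _["bb"] = r.bb,
                      _["be"] = r.be, _["diffs"] = r.diffs,
                      _["ops"] = wrap(r.ops), _["atop"] = r.atop);
}

// Sweep a set of chain tubes of one (contig pair, strand) group: repeated
// LA-finder calls per tube (first on a_low + 2D, or the tube midpoint when
// a_low + D >= a_high; then from the far end of each returned alignment
// until the tube is exhausted), splitting returned alignments at gaps over
// max_gap and applying the length and divergence filters.
// [[Rcpp::export]]
List cpp_sweep_tubes(IntegerVector a, IntegerVector b, IntegerVector dlo,
                     IntegerVector dhi, IntegerVector alo, IntegerVector ahi,
                     int D, double max_div, int max_gap, double xdrop,
                     int kcap, double min_score, int min_length) {
  const int *A = INTEGER(a), *B = INTEGER(b);
  int n = a.size(), m = b.size();
  int ntubes = dlo.size();
  std::vector<Piece> pieces;
  std::vector<int> tube_of;
  for (int ti = 0; ti < ntubes; ++ti) {
    int a_low = alo[ti], a_high = ahi[ti];
    while (true) {
      // the midpoint probe is the terminal one: it is issued when less
      // than one band-width of tube remains, and its extension explores
      // the whole remainder
      bool final_probe = a_low + D >= a_high;
      int anti = final_probe ? (a_low + a_high) / 2 : a_low + 2 * D;
      if (anti < 0) anti = 0;
      if (anti > n + m) anti = n + m;
      LAResult r = la_core(A, n, B, m, anti, dlo[ti], dhi[ti], max_div,
                           max_gap, xdrop, kcap, min_score);
      if (r.ae > r.ab) {
        size_t before = pieces.size();
        split_and_filter(r, A, B, max_gap, min_length, max_div, xdrop,
                         pieces);
        for (size_t x = before; x < pieces.size(); ++x)
          tube_of.push_back(ti + 1);
      }
      if (final_probe || r.atop >= a_high) break;
      int anew = std::max(r.atop, anti);
      if (anew <= a_low) break;  // cannot advance further
      a_low = anew;
    }
  }
  int np = (int)pieces.size();
  IntegerVector oab(np), oae(np), obb(np), obe(np), odf(np), otb(np);
  List oops(np);
  for (int p = 0; p < np; ++p) {
    oab[p] = pieces[p].ab; oae[p] = pieces[p].ae;
    obb[p] = pieces[p].bb; obe[p] = pieces[p].be;
    odf[p] = pieces[p].diffs; otb[p] = tube_of[p];
    oops[p] = wrap(pieces[p].ops);
  }
  return List::create(_["ab"] = oab, _["ae"] = oae, _["bb"] = obb,
                      _["be"] = obe, _["diffs"] = odf, _["tube"] = otb,
                      _["ops"] = oops);
}

// Insertion-only minimum (gaps + mismatches) re-alignment of a trapezoid:
// a = A-segment (L bases), b = B-segment (L + D bases), D insertions to be
// placed.  Diagonal e in [0, D] counts insertions used; the B position on
// diagonal e at A position i is i + e.
// [[Rcpp::export]]
List cpp_refine_wave(IntegerVector a, IntegerVector b, int D) {
  const int *A = INTEGER(a), *B = INTEGER(b);
  int L = a.size();
  if ((int)b.size() != L + D) stop("B segment must have length L + D");
  auto snake = [&](int i, int e) {
    int s = 0;
    while (i + s < L && A[i + s] == B[i + s + e]) ++s;
    return s;
  };
  std::vector<std::vector<int>> waves;
  std::vector<int> F(D + 1, NEG);
  F[0] = snake(0, 0);
  waves.push_back(F);
  int k = 0;
  while (!(F[D] >= L)) {
    ++k;
    if (k > L + D + 2) stop("refine wave failed to terminate");
    std::vector<int> nF(D + 1, NEG);
    int mfar = NEG;
    for (int e = 0; e <= D; ++e) {
      int i = NEG;
      if (F[e] != NEG && F[e] < L) i = F[e] + 1;  // substitution
      if (mfar != NEG && mfar > i) i = mfar;      // gap from a lower diagonal
      if (F[e] > mfar) mfar = F[e];
      if (i == NEG) continue;
      nF[e] = i + snake(i, e);
    }
    F = nF;
    waves.push_back(F);
  }

  // traceback over the stored waves.  A predecessor is valid when its
  // furthest-reaching point, plus the intervening edit edge and Snake
  // matches, covers the current position (the forward pass only records
  // the furthest point per diagonal, so validity must be re-checked with
  // Snake here).  Substitutions are preferred over gap-opens, and a gap
  // jumps from the smallest valid source diagonal, so the traced path
  // keeps the number of gaps minimal.
  std::vector<int> rops;
  int e = D, i = L, gaps = 0, mism = 0;
  int kk = k;
  while (kk > 0) {
    const std::vector<int> &P = waves[kk - 1];
    bool mis_ok = P[e] != NEG && P[e] < L && P[e] + 1 <= i &&
                  P[e] + 1 + snake(P[e] + 1, e) >= i;
    if (mis_ok) {
      for (int t = 0; t < i - (P[e] + 1); ++t) rops.push_back(OP_DIAG);
      rops.push_back(OP_DIAG);  // the substitution itself
      ++mism;
      i = P[e];
    } else {
      int ebest = -1;
      for (int t = 0; t < e; ++t) {
        if (P[t] != NEG && P[t] <= i && P[t] + snake(P[t], e) >= i) {
          ebest = t;
          break;
        }
      }
      if (ebest < 0) stop("refine traceback failed");
      for (int t = 0; t < i - P[ebest]; ++t) rops.push_back(OP_DIAG);
      for (int t = 0; t < e - ebest; ++t) rops.push_back(OP_INSB);
      ++gaps;
      i = P[ebest];
      e = ebest;
    }
    --kk;
  }
  if (e != 0) stop("refine traceback did not reach diagonal 0");
  for (int t = 0; t < i; ++t) rops.push_back(OP_DIAG);
  std::reverse(rops.begin(), rops.end());
  return List::create(_["k"] = k, _["gaps"] = gaps, _["mismatches"] = mism,
                      _["ops"] = wrap(rops));
}
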
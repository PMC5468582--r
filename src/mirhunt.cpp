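#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Hairpin-restricted folding and miRNA-target complementarity scoring.
//
// fold_hairpin_cpp: the 5' side of the sequence is globally aligned
// against the reverse complement of the 3' side over all loop splits.
// Aligned columns that form an allowed pair (G:C, A:U, G:U) take the
// pair score; aligned non-pairable columns (internal-loop mismatches)
// cost 0; a bulge run of length g costs gap_open + g * gap_extend
// (affine). The reported structure minimizes the total score over all
// splits with loop length >= min_loop; ties prefer the smallest loop,
// then the leftmost loop.

static const double INF = std::numeric_limits<double>::infinity();

static inline double pair_score(char a, char b, double gc, double au,
                                double gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return gu;
  return 0.0;  // aligned, not paired
}

static inline bool pairable(char a, char b) {
  return pair_score(a, b, -1, -1, -1) < 0;
}

// [[Rcpp::export]]
List fold_hairpin_cpp(std::string seq, double score_gc, double score_au,
                      double score_gu, double gap_open, double gap_extend,
                      int min_loop) {
  const int n = (int)seq.size();
  // state matrices over (a, b): a 5'-side chars consumed, b 3'-side chars
  // consumed (from the right). M = last column aligned, X = gap run
  // consuming 5' chars, Y = gap run consuming 3' chars.
  const int w = n + 1;
  std::vector<double> M((size_t)w * w, INF), X((size_t)w * w, INF),
      Y((size_t)w * w, INF);
  // traceback: 0 = from M, 1 = from X, 2 = from Y, -1 = none
  std::vector<signed char> pM((size_t)w * w, -1), pX((size_t)w * w, -1),
      pY((size_t)w * w, -1);
  M[0] = 0.0;

  for (int a = 0; a <= n; ++a) {
    for (int b = 0; b <= n - a; ++b) {
      size_t at = (size_t)a * w + b;
      if (a >= 1 && b >= 1) {
        size_t prev = (size_t)(a - 1) * w + (b - 1);
        double col = pair_score(seq[a - 1], seq[n - b], score_gc, score_au,
                                score_gu);
        double best = M[prev]; signed char who = 0;
        if (X[prev] < best) { best = X[prev]; who = 1; }
        if (Y[prev] < best) { best = Y[prev]; who = 2; }
        if (best < INF) { M[at] = best + col; pM[at] = who; }
      }
      if (a >= 1) {
        size_t up = (size_t)(a - 1) * w + b;
        double open_from = std::min(M[up], Y[up]);
        double best; signed char who;
        if (X[up] + gap_extend <= open_from + gap_open + gap_extend) {
          best = X[up] + gap_extend; who = 1;
        } else {
          best = open_from + gap_open + gap_extend;
          who = (M[up] <= Y[up]) ? 0 : 2;
        }
        if (best < INF) { X[at] = best; pX[at] = who; }
      }
      if (b >= 1) {
        size_t left = (size_t)a * w + (b - 1);
        double open_from = std::min(M[left], X[left]);
        double best; signed char who;
        if (Y[left] + gap_extend <= open_from + gap_open + gap_extend) {
          best = Y[left] + gap_extend; who = 2;
        } else {
          best = open_from + gap_open + gap_extend;
          who = (M[left] <= X[left]) ? 0 : 1;
        }
        if (best < INF) { Y[at] = best; pY[at] = who; }
      }
    }
  }

  // pick terminal cell: min score; tie -> smallest loop (largest a+b);
  // tie -> leftmost loop (smallest a)
  double best = INF; int ba = 0, bb = 0; signed char bstate = 0;
  for (int a = 0; a <= n; ++a) {
    for (int b = 0; b <= n - a; ++b) {
      if (n - a - b < min_loop) continue;
      size_t at = (size_t)a * w + b;
      double vals[3] = {M[at], X[at], Y[at]};
      for (int s = 0; s < 3; ++s) {
        double v = vals[s];
        if (v >= INF) continue;
        bool better = v < best - 1e-12;
        if (!better && std::abs(v - best) <= 1e-12) {
          int loop = n - a - b, bloop = n - ba - bb;
          if (loop < bloop || (loop == bloop && a < ba) ||
              (loop == bloop && a == ba && s < bstate))
            better = true;
        }
        if (better) { best = v; ba = a; bb = b; bstate = (signed char)s; }
      }
    }
  }

  // traceback
  std::vector<int> pi, pj;
  std::string db(n, '.');
  int a = ba, b = bb; signed char st = bstate;
  while (a > 0 || b > 0) {
    size_t at = (size_t)a * w + b;
    if (st == 0) {
      signed char prev = pM[at];
      if (pairable(seq[a - 1], seq[n - b])) {
        pi.push_back(a); pj.push_back(n - b + 1);
        db[a - 1] = '('; db[n - b] = ')';
      }
      --a; --b; st = prev;
    } else if (st == 1) {
      st = pX[at]; --a;
    } else {
      st = pY[at]; --b;
    }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());

  return List::create(
      _["score"] = best, _["pair_i"] = wrap(pi), _["pair_j"] = wrap(pj),
      _["arm5_end"] = ba, _["arm3_start"] = n - bb + 1,
      _["loop_start"] = ba + 1, _["loop_end"] = n - bb,
      _["dotbracket"] = db);
}

// ---------------------------------------------------------------------
// miRNA-target complementarity scoring (expectation penalties).
// miRNA is read 5'->3'; the target site is read 3'->5' so that miRNA
// position 1 pairs with the site's 3'-most base. Penalties: mismatch 1.0,
// G:U wobble 0.5, each gap position 2.0; doubled when the column falls at
// miRNA positions 2-13 counted from the 5' end (for a target bulge the
// position of the next miRNA base is used). At most one gap per side.

static inline int col_kind(char m, char t) {
  // 0 = Watson-Crick, 1 = wobble, 2 = mismatch; m is a miRNA base, t a
  // target (mRNA-sense) base
  if ((m == 'A' && t == 'U') || (m == 'U' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G')) return 0;
  if ((m == 'G' && t == 'U') || (m == 'U' && t == 'G')) return 1;
  return 2;
}

static inline double seed_mult(int mir_pos, int seed_lo, int seed_hi) {
  return (mir_pos >= seed_lo && mir_pos <= seed_hi) ? 2.0 : 1.0;
}

struct Aln {
  double expectation;
  int tgt_used;          // target chars consumed
  std::string a_mir, a_match, a_tgt;  // tgt written 3'->5'
  bool central_bad;      // mismatch or gap at miRNA positions 9-11
};

// Align full miRNA against target chars ending at position e (1-based),
// reading the target downwards. Returns best alignment or expectation INF.
static Aln align_site(const std::string &mir, const std::string &tgt, int e,
                      double p_mismatch, double p_gu, double p_gap,
                      int seed_lo, int seed_hi, int central_lo,
                      int central_hi) {
  const int m = (int)mir.size();
  // dp over i (mir consumed), d = k - i in {-1,0,1} (k target consumed),
  // gA (mir-gap used: target bulge), gB (target-gap used: mir bulge)
  // value + parent op: 0 aligned, 1 mir-gap (consumes target), 2 target-gap
  static const double BIG = 1e18;
  auto idx = [m](int i, int d, int gA, int gB) {
    return ((i * 3 + (d + 1)) * 2 + gA) * 2 + gB;
  };
  std::vector<double> V((size_t)(m + 1) * 12, BIG);
  std::vector<signed char> P((size_t)(m + 1) * 12, -1);
  V[idx(0, 0, 0, 0)] = 0.0;
  for (int i = 0; i <= m; ++i) {
    for (int d = -1; d <= 1; ++d) {
      int k = i + d;
      if (k < 0 || e - k < 0) continue;
      for (int gA = 0; gA <= 1; ++gA) for (int gB = 0; gB <= 1; ++gB) {
        double v = V[idx(i, d, gA, gB)];
        if (v >= BIG) continue;
        // aligned column: consume mir i+1 and target e-k
        if (i < m && e - k - 1 >= 0) {
          char mc = mir[i], tc = tgt[e - k - 1];
          int kind = col_kind(mc, tc);
          double pen = (kind == 0) ? 0.0 : (kind == 1 ? p_gu : p_mismatch);
          pen *= seed_mult(i + 1, seed_lo, seed_hi);
          double nv = v + pen;
          size_t ni = idx(i + 1, d, gA, gB);
          if (nv < V[ni]) { V[ni] = nv; P[ni] = 0; }
        }
        // mir-gap (target bulge): consume target char only
        if (gA == 0 && d < 1 && e - k - 1 >= 0) {
          double pen = p_gap * seed_mult(i + 1, seed_lo, seed_hi);
          double nv = v + pen;
          size_t ni = idx(i, d + 1, 1, gB);
          if (nv < V[ni]) { V[ni] = nv; P[ni] = 1; }
        }
        // target-gap: consume mir char only
        if (gB == 0 && d > -1 && i < m) {
          double pen = p_gap * seed_mult(i + 1, seed_lo, seed_hi);
          double nv = v + pen;
          size_t ni = idx(i + 1, d - 1, gA, 1);
          if (nv < V[ni]) { V[ni] = nv; P[ni] = 2; }
        }
      }
    }
  }
  // best final state at i = m
  Aln best; best.expectation = BIG; best.tgt_used = 0; best.central_bad = false;
  int bd = 0, bgA = 0, bgB = 0;
  for (int d = -1; d <= 1; ++d) for (int gA = 0; gA <= 1; ++gA)
    for (int gB = 0; gB <= 1; ++gB) {
      int k = m + d;
      if (k < 0 || e - k < 0) continue;
      double v = V[idx(m, d, gA, gB)];
      if (v < best.expectation) {
        best.expectation = v; bd = d; bgA = gA; bgB = gB;
      }
    }
  if (best.expectation >= BIG) return best;
  // traceback
  std::string am, mm, at;
  int i = m, d = bd, gA = bgA, gB = bgB;
  bool central_bad = false;
  while (i > 0 || d != 0 || gA != 0 || gB != 0) {
    signed char op = P[idx(i, d, gA, gB)];
    if (op < 0) break;
    int k = i + d;
    if (op == 0) {
      char mc = mir[i - 1], tc = tgt[e - k];
      am.push_back(mc); at.push_back(tc);
      int kind = col_kind(mc, tc);
      mm.push_back(kind == 0 ? '|' : (kind == 1 ? 'o' : ' '));
      if (kind == 2 && i >= central_lo && i <= central_hi) central_bad = true;
      --i;  // aligned column consumes one char on each side: d unchanged
    } else if (op == 1) {
      am.push_back('-'); at.push_back(tgt[e - k]); mm.push_back(' ');
      if (i + 1 >= central_lo && i + 1 <= central_hi) central_bad = true;
      --d; gA = 0;
    } else {
      am.push_back(mir[i - 1]); at.push_back('-'); mm.push_back(' ');
      if (i >= central_lo && i <= central_hi) central_bad = true;
      --i; ++d; gB = 0;
    }
  }
  std::reverse(am.begin(), am.end());
  std::reverse(mm.begin(), mm.end());
  std::reverse(at.begin(), at.end());
  best.a_mir = am; best.a_match = mm; best.a_tgt = at;
  best.tgt_used = m + bd;
  best.central_bad = central_bad;
  return best;
}

// [[Rcpp::export]]
List scan_target_cpp(std::string mir, std::string tgt, double max_expectation,
                     double p_mismatch, double p_gu, double p_gap,
                     int seed_lo, int seed_hi, int central_lo, int central_hi,
                     bool allow_gaps) {
  const int m = (int)mir.size(), n = (int)tgt.size();
  std::vector<int> starts, ends;
  std::vector<double> exps;
  std::vector<std::string> amir, amatch, atgt;
  std::vector<bool> central;
  for (int e = m - 1; e <= n; ++e) {  // e = target chars available below end
    // end position on transcript is e (1-based); need e >= tgt_used
    if (e < m - 1) continue;
    Aln a;
    if (allow_gaps) {
      a = align_site(mir, tgt, e, p_mismatch, p_gu, p_gap, seed_lo, seed_hi,
                     central_lo, central_hi);
    } else {
      // ungapped fast path
      a.expectation = 0.0; a.tgt_used = m; a.central_bad = false;
      if (e - m < 0) { a.expectation = 1e18; }
      else {
        std::string am, mm, at;
        for (int i = 1; i <= m; ++i) {
          char mc = mir[i - 1], tc = tgt[e - i];
          int kind = col_kind(mc, tc);
          double pen = (kind == 0) ? 0.0 : (kind == 1 ? p_gu : p_mismatch);
          a.expectation += pen * seed_mult(i, seed_lo, seed_hi);
          am.push_back(mc); at.push_back(tc);
          mm.push_back(kind == 0 ? '|' : (kind == 1 ? 'o' : ' '));
          if (kind == 2 && i >= central_lo && i <= central_hi)
            a.central_bad = true;
        }
        a.a_mir = am; a.a_match = mm; a.a_tgt = at;
      }
    }
    if (a.expectation <= max_expectation && e - a.tgt_used >= 0 && e <= n) {
      starts.push_back(e - a.tgt_used + 1);
      ends.push_back(e);
      exps.push_back(a.expectation);
      amir.push_back(a.a_mir); amatch.push_back(a.a_match);
      atgt.push_back(a.a_tgt);
      central.push_back(a.central_bad);
    }
  }
  return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                      _["expectation"] = wrap(exps), _["aln_mir"] = wrap(amir),
                      _["aln_match"] = wrap(amatch), _["aln_tgt"] = wrap(atgt),
                      _["central_bad"] = wrap(central));
}
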
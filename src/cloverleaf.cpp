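#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Rule-based cloverleaf folding. All stems must close with Watson-Crick or
// G.U wobble pairs; pair_score counts paired nucleotides of the four
// canonical stems (2 per base pair, wobble included). The variable-arm
// stem is detected and reported for Sec-tRNA classification but does not
// add to the score: in random sequence a short stem somewhere in a
// 10-23 nt window is almost free, and scoring it would flood the scan
// with spurious arm-bearing layouts.

// Search windows (in bp / nt):
//   acceptor stem 6-9, acceptor-to-D spacer 1-3, D stem 3-4, D loop 4-12,
//   anticodon stem 5-6, anticodon loop fixed 7 (anticodon at loop 3-5),
//   variable region 3-23 (arm when >=10 nt with internal stem >=3 bp),
//   T stem 4-5, T loop 5-9.

static const int ACC_LO = 6, ACC_HI = 9;
static const int SP_LO = 1, SP_HI = 3;
static const int D_LO = 3, D_HI = 4;
static const int DL_LO = 4, DL_HI = 12;
static const int AC_LO = 5, AC_HI = 6;
static const int ACLOOP = 7;
static const int V_LO = 3, V_HI = 23;
static const int T_LO = 4, T_HI = 5;
static const int TL_LO = 5, TL_HI = 9;

// encode: A=0 C=1 G=2 T/U=3, other=-1
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

// 0 = no pair, 1 = Watson-Crick, 2 = G.U wobble
static inline int pairtype(int x, int y) {
  if (x < 0 || y < 0) return 0;
  if ((x == 0 && y == 3) || (x == 3 && y == 0)) return 1;
  if ((x == 1 && y == 2) || (x == 2 && y == 1)) return 1;
  if ((x == 2 && y == 3) || (x == 3 && y == 2)) return 2;
  return 0;
}

struct Layout {
  int acc, sp, d, dl, ac, v, vstem, t, tl;
  bool varm;
  int score, gu;
  bool found;
};

// check a stem seq[i..i+len-1] pairing seq[j-k] (5' arm vs 3' arm given as
// the index of the pairing partner of seq[i+k] being jhi-k); returns gu
// count or -1 when any position fails to pair
static inline int stem_ok(const int* s, int i, int jhi, int len) {
  int gu = 0;
  for (int k = 0; k < len; ++k) {
    int pt = pairtype(s[i + k], s[jhi - k]);
    if (pt == 0) return -1;
    if (pt == 2) ++gu;
  }
  return gu;
}

// longest fully paired hairpin stem inside region s[i..i+v-1] with loop >= 3
static int var_arm_stem(const int* s, int i, int v) {
  int best = 0;
  for (int o = 0; o < v; ++o) {
    for (int e = v - 1; e >= o; --e) {
      int span = e - o + 1;
      int kmax = (span - 3) / 2;
      if (kmax <= best) continue;
      int k = 0;
      while (k < kmax) {
        if (pairtype(s[i + o + k], s[i + e - k]) == 0) break;
        ++k;
      }
      if (k > best) best = k;
    }
  }
  return best;
}

static Layout fold_region(const int* s, int L) {
  Layout best;
  best.found = false;
  best.score = -1;
  best.gu = 1 << 20;
  for (int a = ACC_LO; a <= ACC_HI; ++a) {
    int agu = stem_ok(s, 0, L - 1, a);
    if (agu < 0) continue;
    for (int sp = SP_LO; sp <= SP_HI; ++sp) {
      int ds = a + sp;
      for (int d = D_LO; d <= D_HI; ++d) {
        for (int dl = DL_LO; dl <= DL_HI; ++dl) {
          if (ds + 2 * d + dl >= L - a) continue;
          int dgu = stem_ok(s, ds, ds + 2 * d + dl - 1, d);
          if (dgu < 0) continue;
          int acs = ds + 2 * d + dl;
          for (int ac = AC_LO; ac <= AC_HI; ++ac) {
            int acend = acs + 2 * ac + ACLOOP; // one past anticodon arm
            if (acend >= L - a) continue;
            int acgu = stem_ok(s, acs, acend - 1, ac);
            if (acgu < 0) continue;
            int rest = (L - a) - acend; // v + 2t + tl
            for (int t = T_LO; t <= T_HI; ++t) {
              for (int tl = TL_LO; tl <= TL_HI; ++tl) {
                int v = rest - 2 * t - tl;
                if (v < V_LO || v > V_HI) continue;
                int ts = acend + v;
                int tgu = stem_ok(s, ts, ts + 2 * t + tl - 1, t);
                if (tgu < 0) continue;
                int vstem = 0;
                bool varm = false;
                if (v >= 10) {
                  vstem = var_arm_stem(s, acend, v);
                  varm = vstem >= 3;
                  if (!varm) vstem = 0;
                }
                int score = 2 * (a + d + ac + t);
                int gu = agu + dgu + acgu + tgu;
                if (score > best.score ||
                    (score == best.score && gu < best.gu)) {
                  best.found = true;
                  best.acc = a; best.sp = sp; best.d = d; best.dl = dl;
                  best.ac = ac; best.v = v; best.vstem = vstem;
                  best.t = t; best.tl = tl; best.varm = varm;
                  best.score = score; best.gu = gu;
                }
              }
            }
          }
        }
      }
    }
  }
  return best;
}

static List layout_to_list(const Layout& b, const int* s, int offset, int L) {
  // anticodon: loop positions 3-5 (1-based) of the 7-nt anticodon loop
  int acs = b.acc + b.sp + 2 * b.d + b.dl;
  int apos = acs + b.ac + 2; // 0-based first anticodon base within region
  const char* bases = "ACGU";
  char antic[4] = {0, 0, 0, 0};
  for (int k = 0; k < 3; ++k) {
    int x = s[offset + apos + k];
    antic[k] = (x >= 0) ? bases[x] : 'N';
  }
  return List::create(
    _["acceptor_stem"] = b.acc, _["acc_d_spacer"] = b.sp,
    _["d_stem"] = b.d, _["d_loop"] = b.dl,
    _["ac_stem"] = b.ac, _["ac_loop"] = ACLOOP,
    _["var_region"] = b.v, _["var_arm"] = b.varm,
    _["var_stem"] = b.vstem,
    _["t_stem"] = b.t, _["t_loop"] = b.tl,
    _["pair_score"] = b.score, _["gu_pairs"] = b.gu,
    _["anticodon"] = std::string(antic),
    _["length"] = L);
}

// [[Rcpp::export(name = ".fold_cloverleaf_cpp")]]
SEXP fold_cloverleaf_cpp(std::string seq) {
  int L = (int)seq.size();
  std::vector<int> s(L);
  for (int i = 0; i < L; ++i) s[i] = enc(seq[i]);
  Layout b = fold_region(s.data(), L);
  if (!b.found) return R_NilValue;
  return layout_to_list(b, s.data(), 0, L);
}

// Scan one strand of a contig: all start positions x window lengths.
// Returns a data.frame of placements whose best layout reaches min_score.
// [[Rcpp::export(name = ".scan_trna_cpp")]]
DataFrame scan_trna_cpp(std::string seq, int min_len, int max_len,
                        int min_score) {
  int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  std::vector<int> start, len, score, gu;
  std::vector<std::string> antic;
  std::vector<List> layouts;
  for (int i = 0; i + min_len <= n; ++i) {
    for (int L = min_len; L <= max_len && i + L <= n; ++L) {
      // cheap prefilter: outermost 6 acceptor pairs must close
      bool ok = true;
      for (int k = 0; k < ACC_LO; ++k) {
        if (pairtype(s[i + k], s[i + L - 1 - k]) == 0) { ok = false; break; }
      }
      if (!ok) continue;
      Layout b = fold_region(s.data() + i, L);
      if (!b.found || b.score < min_score) continue;
      start.push_back(i + 1);
      len.push_back(L);
      score.push_back(b.score);
      gu.push_back(b.gu);
      List li = layout_to_list(b, s.data(), i, L);
      antic.push_back(as<std::string>(li["anticodon"]));
      layouts.push_back(li);
    }
  }
  List lay(layouts.size());
  for (size_t k = 0; k < layouts.size(); ++k) lay[k] = layouts[k];
  DataFrame out = DataFrame::create(
    _["start"] = start, _["length"] = len, _["pair_score"] = score,
    _["gu_pairs"] = gu, _["anticodon"] = antic,
    _["stringsAsFactors"] = false);
  out.attr("layouts") = lay;
  return out;
}

// Exhaustive stem-loop search. score = 2*WC + 1*GU - 2*mismatch.
// Ties: higher score, then fewer mismatches, then leftmost start, then
// longer stem, then smaller loop.
// [[Rcpp::export(name = ".find_hairpin_cpp")]]
SEXP find_hairpin_cpp(std::string seq, int min_stem, int loop_lo, int loop_hi,
                      int max_mismatch, int max_start) {
  int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  int b_score = INT_MIN, b_start = -1, b_stem = 0, b_loop = 0, b_mm = 0,
      b_gu = 0, b_wc = 0;
  int startmax = (max_start > 0 && max_start < n) ? max_start : n;
  for (int i = 0; i < startmax; ++i) {
    for (int loop = loop_lo; loop <= loop_hi; ++loop) {
      int smax = (n - i - loop) / 2;
      for (int st = min_stem; st <= smax; ++st) {
        int wc = 0, guc = 0, mm = 0;
        for (int k = 0; k < st; ++k) {
          int pt = pairtype(s[i + k], s[i + 2 * st + loop - 1 - k]);
          if (pt == 1) ++wc;
          else if (pt == 2) ++guc;
          else ++mm;
        }
        if (mm > max_mismatch) continue;
        int sc = 2 * wc + guc - 2 * mm;
        bool better = sc > b_score ||
          (sc == b_score && (mm < b_mm ||
            (mm == b_mm && (i + 1 < b_start ||
              (i + 1 == b_start && (st > b_stem ||
                (st == b_stem && loop < b_loop)))))));
        if (better) {
          b_score = sc; b_start = i + 1; b_stem = st; b_loop = loop;
          b_mm = mm; b_gu = guc; b_wc = wc;
        }
      }
    }
  }
  if (b_start < 0) return R_NilValue;
  return List::create(
    _["start"] = b_start, _["stem_bp"] = b_stem, _["loop_nt"] = b_loop,
    _["wc_pairs"] = b_wc, _["gu_pairs"] = b_gu, _["mismatches"] = b_mm,
    _["span_nt"] = 2 * b_stem + b_loop, _["score"] = b_score);
}
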
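// Multi-strand RNA secondary-structure MFE by dynamic programming.
//
// Zuker-style recursions over the concatenation of up to three strands,
// nick-aware: any loop whose accessible region contains a strand nick is
// scored as an exterior-like region (no loop penalty, no minimum hairpin
// size).  Energies are integer centi-kcal/mol; all parameter tables are
// precomputed in R and passed in, so the R-side enumeration oracle scores
// structures with bit-identical arithmetic.
//
// Arrays:
//   V[i][j]   : MFE given (i,j) paired
//   WM1[i][j] : multiloop segment, exactly one branch starting at i,
//               nick-free trailing gap
//   WM[i][j]  : multiloop segment, >= 1 branch, nick-free accessible gaps
//   WX[i][j]  : exterior-style region (no penalties), used for the
//               whole-complex top level and for nick-containing loops
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int INF = 100000000;

struct FoldCtx {
  int n;
  std::vector<int> s;          // base codes 0..3
  std::vector<int> nextNick;   // nextNick[p]: smallest q >= p with nick at q (gap q,q+1); n if none
  std::vector<char> nickat;    // nickat[p], p in [0, n-2]
  const IntegerMatrix* ptype;  // 4x4, 0 = not pairable, else 1..6
  const IntegerMatrix* stack;  // 6x6 centi-kcal
  const IntegerVector* hp;     // hairpin penalty by loop size (INF where invalid)
  const IntegerVector* bulge;  // by size (index 1..), INF beyond cap
  const IntegerVector* intl;   // by total size, INF beyond cap
  int ml_a, ml_b, ml_c;
  std::vector<std::vector<int>> V, WM, WM1, WX;

  inline bool canPair(int i, int j) const { return (*ptype)(s[i], s[j]) != 0; }
  inline int pt(int i, int j) const { return (*ptype)(s[i], s[j]); }
  // gaps [a..b] (each gap p sits between positions p and p+1) nick-free?
  inline bool nickFree(int a, int b) const { return a > b || nextNick[a] > b; }
  inline int wx(int a, int b) const { return a > b ? 0 : WX[a][b]; }
  inline int hpPen(int sz) const { return sz >= 0 && sz < (int)hp->size() ? (*hp)[sz] : INF; }
  inline int bulgePen(int sz) const { return sz >= 1 && sz < (int)bulge->size() ? (*bulge)[sz] : INF; }
  inline int intlPen(int sz) const { return sz >= 2 && sz < (int)intl->size() ? (*intl)[sz] : INF; }
};

static inline int addE(int a, int b) {
  if (a >= INF || b >= INF) return INF;
  return a + b;
}

static int interiorCost(const FoldCtx& C, int i, int j, int k, int l) {
  // loop closed by (i,j) with single branch (k,l); caller guarantees the
  // gaps [i..k-1], [l..j-1] are nick-free
  int s1 = k - i - 1, s2 = j - l - 1;
  if (s1 == 0 && s2 == 0) return (*C.stack)(C.pt(i, j) - 1, C.pt(k, l) - 1);
  if (s1 == 0 || s2 == 0) return C.bulgePen(s1 + s2);
  return C.intlPen(s1 + s2);
}

static void fill(FoldCtx& C) {
  int n = C.n;
  C.V.assign(n, std::vector<int>(n, INF));
  C.WM.assign(n, std::vector<int>(n, INF));
  C.WM1.assign(n, std::vector<int>(n, INF));
  C.WX.assign(n, std::vector<int>(n, 0));

  for (int span = 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // ---- V ----
      if (C.canPair(i, j)) {
        int best = INF;
        // hairpin (nick-free interior)
        if (C.nickFree(i, j - 1)) {
          int p = C.hpPen(j - i - 1);
          if (p < best) best = p;
        }
        // interior / bulge / stack
        for (int k = i + 1; k < j; ++k) {
          if (k - i - 1 > 30) break;
          if (!C.nickFree(i, k - 1)) break;     // gap only grows with k
          for (int l = j - 1; l > k; --l) {
            int s2 = j - l - 1;
            if ((k - i - 1) + s2 > 30) break;
            if (!C.nickFree(l, j - 1)) continue; // shrinking gap: keep scanning
            if (C.V[k][l] >= INF) continue;
            int e = addE(C.V[k][l], interiorCost(C, i, j, k, l));
            if (e < best) best = e;
          }
        }
        // multiloop, nick-free accessible region
        if (j - i >= 4 && !C.nickat[i] && !C.nickat[j - 1]) {
          for (int k = i + 2; k <= j - 2; ++k) {
            if (C.nickat[k - 1]) continue;
            int e = addE(C.WM[i + 1][k - 1], C.WM1[k][j - 1]);
            e = addE(e, C.ml_a + C.ml_b);
            if (e < best) best = e;
          }
        }
        // loop containing a nick: exterior-like, zero penalty
        for (int p = i; p < j; ++p) {
          if (!C.nickat[p]) continue;
          int e = addE(C.wx(i + 1, p), C.wx(p + 1, j - 1));
          if (e < best) best = e;
        }
        C.V[i][j] = best;
      }
      // ---- WM1 ----
      {
        int best = INF;
        if (C.V[i][j] < INF) best = C.V[i][j] + C.ml_b;
        if (j > i && !C.nickat[j - 1] && C.WM1[i][j - 1] < INF) {
          int e = C.WM1[i][j - 1] + C.ml_c;
          if (e < best) best = e;
        }
        C.WM1[i][j] = best;
      }
      // ---- WM ----
      {
        int best = C.WM1[i][j];
        if (!C.nickat[j - 1] && C.WM[i][j - 1] < INF) {
          int e = C.WM[i][j - 1] + C.ml_c;
          if (e < best) best = e;
        }
        if (!C.nickat[i] && C.WM[i + 1][j] < INF) {
          int e = C.WM[i + 1][j] + C.ml_c;
          if (e < best) best = e;
        }
        for (int k = i + 1; k <= j; ++k) {
          if (C.nickat[k - 1]) continue;
          int e = addE(C.WM[i][k - 1], C.WM1[k][j]);
          if (e < best) best = e;
        }
        C.WM[i][j] = best;
      }
      // ---- WX ----
      {
        int best = C.wx(i, j - 1);
        for (int k = i; k < j; ++k) {
          if (C.V[k][j] >= INF) continue;
          int e = addE(k > i ? C.WX[i][k - 1] : 0, C.V[k][j]);
          if (e < best) best = e;
        }
        C.WX[i][j] = best;
      }
    }
  }
}

// ---- traceback (deterministic fixed case order) ----

static void traceV(FoldCtx& C, int i, int j, std::vector<std::pair<int,int>>& out);

static void traceWX(FoldCtx& C, int a, int b, std::vector<std::pair<int,int>>& out) {
  while (a <= b) {
    if (C.WX[a][b] == C.wx(a, b - 1)) { --b; continue; }
    bool done = false;
    for (int k = a; k <= b && !done; ++k) {
      if (C.V[k][b] >= INF) continue;
      if (addE(k > a ? C.WX[a][k - 1] : 0, C.V[k][b]) == C.WX[a][b]) {
        traceV(C, k, b, out);
        b = k - 1;
        done = true;
      }
    }
    if (!done) stop("traceback failure in exterior region");
  }
}

static void traceWM1(FoldCtx& C, int i, int j, std::vector<std::pair<int,int>>& out) {
  while (true) {
    if (C.V[i][j] < INF && C.WM1[i][j] == C.V[i][j] + C.ml_b) { traceV(C, i, j, out); return; }
    if (j > i && !C.nickat[j - 1] && C.WM1[i][j - 1] < INF &&
        C.WM1[i][j] == C.WM1[i][j - 1] + C.ml_c) { --j; continue; }
    stop("traceback failure in WM1");
  }
}

static void traceWM(FoldCtx& C, int i, int j, std::vector<std::pair<int,int>>& out) {
  while (true) {
    if (C.WM[i][j] == C.WM1[i][j]) { traceWM1(C, i, j, out); return; }
    if (!C.nickat[j - 1] && C.WM[i][j - 1] < INF &&
        C.WM[i][j] == C.WM[i][j - 1] + C.ml_c) { --j; continue; }
    if (!C.nickat[i] && C.WM[i + 1][j] < INF &&
        C.WM[i][j] == C.WM[i + 1][j] + C.ml_c) { ++i; continue; }
    for (int k = i + 1; k <= j; ++k) {
      if (C.nickat[k - 1]) continue;
      if (addE(C.WM[i][k - 1], C.WM1[k][j]) == C.WM[i][j]) {
        traceWM(C, i, k - 1, out);
        traceWM1(C, k, j, out);
        return;
      }
    }
    stop("traceback failure in WM");
  }
}

static void traceV(FoldCtx& C, int i, int j, std::vector<std::pair<int,int>>& out) {
  out.push_back({i, j});
  int target = C.V[i][j];
  if (C.nickFree(i, j - 1) && C.hpPen(j - i - 1) == target) return;
  for (int p = i; p < j; ++p) {
    if (!C.nickat[p]) continue;
    if (addE(C.wx(i + 1, p), C.wx(p + 1, j - 1)) == target) {
      if (i + 1 <= p) traceWX(C, i + 1, p, out);
      if (p + 1 <= j - 1) traceWX(C, p + 1, j - 1, out);
      return;
    }
  }
  for (int k = i + 1; k < j; ++k) {
    if (k - i - 1 > 30) break;
    if (!C.nickFree(i, k - 1)) break;
    for (int l = j - 1; l > k; --l) {
      int s2 = j - l - 1;
      if ((k - i - 1) + s2 > 30) break;
      if (!C.nickFree(l, j - 1)) continue;
      if (C.V[k][l] >= INF) continue;
      if (addE(C.V[k][l], interiorCost(C, i, j, k, l)) == target) {
        traceV(C, k, l, out);
        return;
      }
    }
  }
  if (j - i >= 4 && !C.nickat[i] && !C.nickat[j - 1]) {
    for (int k = i + 2; k <= j - 2; ++k) {
      if (C.nickat[k - 1]) continue;
      if (addE(addE(C.WM[i + 1][k - 1], C.WM1[k][j - 1]), C.ml_a + C.ml_b) == target) {
        traceWM(C, i + 1, k - 1, out);
        traceWM1(C, k, j - 1, out);
        return;
      }
    }
  }
  stop("traceback failure in V");
}

// [[Rcpp::export(name = ".mfe_fold_cpp")]]
List mfe_fold_cpp(IntegerVector seq_codes, LogicalVector nick_at,
                  IntegerMatrix ptype, IntegerMatrix stack_cc,
                  IntegerVector hairpin_cc, IntegerVector bulge_cc,
                  IntegerVector internal_cc,
                  int ml_a, int ml_b, int ml_c) {
  FoldCtx C;
  C.n = seq_codes.size();
  if (C.n == 0) stop("empty sequence");
  C.s.assign(seq_codes.begin(), seq_codes.end());
  C.nickat.assign(C.n > 1 ? C.n - 1 : 0, 0);
  for (int p = 0; p < (int)C.nickat.size(); ++p) C.nickat[p] = nick_at[p] ? 1 : 0;
  C.nextNick.assign(C.n, C.n);
  for (int p = C.n - 2; p >= 0; --p)
    C.nextNick[p] = C.nickat[p] ? p : C.nextNick[p + 1];
  C.ptype = &ptype; C.stack = &stack_cc;
  C.hp = &hairpin_cc; C.bulge = &bulge_cc; C.intl = &internal_cc;
  C.ml_a = ml_a; C.ml_b = ml_b; C.ml_c = ml_c;

  if (C.n == 1)
    return List::create(_["energy_cc"] = 0,
                        _["pairs"] = IntegerMatrix(0, 2));

  fill(C);
  int mfe = C.wx(0, C.n - 1);
  std::vector<std::pair<int,int>> pairs;
  traceWX(C, 0, C.n - 1, pairs);

  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first + 1;   // 1-based for R
    pm(r, 1) = pairs[r].second + 1;
  }
  return List::create(_["energy_cc"] = mfe, _["pairs"] = pm);
}
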
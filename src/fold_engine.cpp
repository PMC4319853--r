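// Embedded nearest-neighbor RNA secondary-structure engine.
//
// Model (deliberately small so an exhaustive enumeration oracle is feasible):
//   - canonical pairs AU/UA/GC/CG/GU/UG, minimum hairpin loop 3 nt
//   - stacked pairs scored by a 6x6 table (strand-flip symmetric)
//   - hairpin / bulge / internal loops scored by logarithmic size penalties
//   - interior loops with > 30 unpaired nt are disallowed (part of the model)
//   - multibranch loops: a + b per branch (closing helix included), unpaired free
//   - no dangles, no coaxial stacking, no pseudoknots; lonely pairs allowed
// Energies are "engine units ~ kcal/mol"; absolute values are model dependent.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;

// pair codes: AU=0 UA=1 GC=2 CG=3 GU=4 UG=5, -1 = not pairable
static inline int baseCode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'U': return 3;
  default: return -1;
  }
}

static inline int pairCode(int a, int b) {
  if (a == 0 && b == 3) return 0; // AU
  if (a == 3 && b == 0) return 1; // UA
  if (a == 2 && b == 1) return 2; // GC
  if (a == 1 && b == 2) return 3; // CG
  if (a == 2 && b == 3) return 4; // GU
  if (a == 3 && b == 2) return 5; // UG
  return -1;
}

// stack[p][q]: pair p = (i,j) closing, q = (i+1,j-1) inner.
// Satisfies the strand-reversal symmetry E(p,q) == E(flip(q), flip(p)),
// flip: AU<->UA, GC<->CG, GU<->UG.
static const double STACK[6][6] = {
  /* AU */ {-0.9, -1.1, -2.1, -2.2, -0.6, -1.4},
  /* UA */ {-1.3, -0.9, -2.1, -2.4, -1.0, -1.3},
  /* GC */ {-2.4, -2.2, -3.3, -3.4, -1.5, -2.1},
  /* CG */ {-2.1, -2.1, -2.4, -3.3, -1.4, -2.1},
  /* GU */ {-1.3, -1.4, -2.1, -2.1, -0.5, -0.6},
  /* UG */ {-1.0, -0.6, -1.4, -1.5, -0.7, -0.5}
};

static const double LOOP_SLOPE = 1.0774;   // 1.75 * RT at 37C
static const double HAIRPIN_BASE = 5.4;    // size-3 hairpin
static const double BULGE_BASE = 3.8;      // size-1 bulge
static const double INTERNAL_BASE = 4.1;   // size-2 internal loop
static const int    MAX_INTERIOR = 30;     // max unpaired nt in an interior loop
static const double MULTI_A = 4.6;         // multiloop closing penalty
static const double MULTI_B = 0.4;         // per branch (closing helix included)
static const double DUPLEX_INIT = 4.1;     // duplex initiation

static inline double hairpinE(int n) {
  return HAIRPIN_BASE + LOOP_SLOPE * std::log((double)n / 3.0);
}
static inline double bulgeE(int n) {
  return BULGE_BASE + LOOP_SLOPE * std::log((double)n);
}
static inline double internalE(int n) {
  return INTERNAL_BASE + LOOP_SLOPE * std::log((double)n / 2.0);
}

struct FoldState {
  int n;
  std::vector<int> b;                 // base codes
  std::vector<std::vector<double> > V, M, M2;
  std::vector<double> W;              // external, W[j] over prefix [0..j]
};

static inline double getV(const FoldState& st, int i, int j) {
  return (j - i >= 4) ? st.V[i][j] : INF;
}

// best interior-loop continuation for pair (i,j); fills *ki,*li on request
static double interiorBest(const FoldState& st, int i, int j,
                           int* ki = NULL, int* li = NULL) {
  double best = INF;
  int p = pairCode(st.b[i], st.b[j]);
  for (int k = i + 1; k <= j - 5; ++k) {
    int n1 = k - i - 1;
    if (n1 > MAX_INTERIOR) break;
    for (int l = j - 1; l >= k + 4; --l) {
      int n2 = j - l - 1;
      if (n1 + n2 > MAX_INTERIOR) break;
      int q = pairCode(st.b[k], st.b[l]);
      if (q < 0) continue;
      double loop;
      if (n1 == 0 && n2 == 0) loop = STACK[p][q];
      else if (n1 == 0 || n2 == 0) loop = bulgeE(n1 + n2);
      else loop = internalE(n1 + n2);
      double e = loop + getV(st, k, l);
      if (e < best) {
        best = e;
        if (ki) { *ki = k; *li = l; }
      }
    }
  }
  return best;
}

static void fillTables(FoldState& st) {
  int n = st.n;
  st.V.assign(n, std::vector<double>(n, INF));
  st.M.assign(n, std::vector<double>(n, INF));
  st.M2.assign(n, std::vector<double>(n, INF));
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // V
      if (pairCode(st.b[i], st.b[j]) >= 0) {
        double best = hairpinE(j - i - 1);
        double ib = interiorBest(st, i, j);
        if (ib < best) best = ib;
        if (j - 1 - (i + 1) >= 0 && st.M2[i + 1][j - 1] < INF / 2) {
          double e = MULTI_A + MULTI_B + st.M2[i + 1][j - 1];
          if (e < best) best = e;
        }
        st.V[i][j] = best;
      }
      // M: >= 1 branch in [i..j]
      double m = (i + 1 <= j) ? st.M[i + 1][j] : INF;
      for (int q = i + 4; q <= j; ++q) {
        double v = getV(st, i, q);
        if (v >= INF / 2) continue;
        double rest = 0.0;
        if (q + 1 <= j && st.M[q + 1][j] < 0.0) rest = st.M[q + 1][j];
        double e = v + MULTI_B + rest;
        if (e < m) m = e;
      }
      st.M[i][j] = m;
      // M2: >= 2 branches in [i..j]
      double m2 = (i + 1 <= j) ? st.M2[i + 1][j] : INF;
      for (int q = i + 4; q <= j; ++q) {
        double v = getV(st, i, q);
        if (v >= INF / 2) continue;
        if (q + 1 > j || st.M[q + 1][j] >= INF / 2) continue;
        double e = v + MULTI_B + st.M[q + 1][j];
        if (e < m2) m2 = e;
      }
      st.M2[i][j] = m2;
    }
  }
  st.W.assign(n + 1, 0.0); // W[t] = prefix [0..t-1]
  for (int j = 0; j < n; ++j) {
    double w = st.W[j];
    for (int i = 0; i <= j - 4; ++i) {
      double v = getV(st, i, j);
      if (v >= INF / 2) continue;
      double e = st.W[i] + v;
      if (e < w) w = e;
    }
    st.W[j + 1] = w;
  }
}

static inline bool close2(double a, double b) { return std::fabs(a - b) < 1e-7; }

struct TBItem { int i, j, state; }; // state: 0 = V, 1 = M, 2 = M2

static void traceback(const FoldState& st, std::vector<int>& pt) {
  int n = st.n;
  pt.assign(n, -1);
  std::vector<TBItem> stack;
  // external
  int j = n;
  while (j > 0) {
    if (close2(st.W[j], st.W[j - 1])) { --j; continue; }
    bool found = false;
    for (int i = 0; i <= j - 1 - 4; ++i) {
      double v = getV(st, i, j - 1);
      if (v < INF / 2 && close2(st.W[j], st.W[i] + v)) {
        TBItem it; it.i = i; it.j = j - 1; it.state = 0;
        stack.push_back(it);
        j = i;
        found = true;
        break;
      }
    }
    if (!found) --j; // numerical safety; should not happen
  }
  while (!stack.empty()) {
    TBItem it = stack.back();
    stack.pop_back();
    int i = it.i; j = it.j;
    if (it.state == 0) { // V
      pt[i] = j; pt[j] = i;
      double v = st.V[i][j];
      if (close2(v, hairpinE(j - i - 1))) continue;
      int k = -1, l = -1;
      double ib = interiorBest(st, i, j, &k, &l);
      if (k >= 0 && close2(v, ib)) {
        TBItem nx; nx.i = k; nx.j = l; nx.state = 0;
        stack.push_back(nx);
        continue;
      }
      // multiloop
      TBItem nx; nx.i = i + 1; nx.j = j - 1; nx.state = 2;
      stack.push_back(nx);
    } else if (it.state == 1) { // M
      while (i < j && close2(st.M[i][j], st.M[i + 1][j])) ++i;
      for (int q = i + 4; q <= j; ++q) {
        double v = getV(st, i, q);
        if (v >= INF / 2) continue;
        double rest = 0.0;
        bool useRest = (q + 1 <= j && st.M[q + 1][j] < 0.0);
        if (useRest) rest = st.M[q + 1][j];
        if (close2(st.M[i][j], v + MULTI_B + rest)) {
          TBItem nx; nx.i = i; nx.j = q; nx.state = 0;
          stack.push_back(nx);
          if (useRest) {
            TBItem nr; nr.i = q + 1; nr.j = j; nr.state = 1;
            stack.push_back(nr);
          }
          break;
        }
      }
    } else { // M2
      while (i < j && close2(st.M2[i][j], st.M2[i + 1][j])) ++i;
      for (int q = i + 4; q <= j; ++q) {
        double v = getV(st, i, q);
        if (v >= INF / 2) continue;
        if (q + 1 > j || st.M[q + 1][j] >= INF / 2) continue;
        if (close2(st.M2[i][j], v + MULTI_B + st.M[q + 1][j])) {
          TBItem nx; nx.i = i; nx.j = q; nx.state = 0;
          stack.push_back(nx);
          TBItem nr; nr.i = q + 1; nr.j = j; nr.state = 1;
          stack.push_back(nr);
          break;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".foldEngine")]]
List foldEngine(std::string seq) {
  int n = (int)seq.size();
  FoldState st;
  st.n = n;
  st.b.resize(n);
  for (int i = 0; i < n; ++i) {
    int c = baseCode(seq[i]);
    if (c < 0) stop("fold engine: non-RNA character '%c' at position %d",
                    seq[i], i + 1);
    st.b[i] = c;
  }
  if (n < 5) {
    std::string dots(n, '.');
    return List::create(_["structure"] = dots, _["energy"] = 0.0,
                        _["pairs"] = IntegerVector(n, NA_INTEGER));
  }
  fillTables(st);
  double mfe = st.W[n];
  if (mfe > 0.0) mfe = 0.0; // empty structure always available
  std::vector<int> pt;
  traceback(st, pt);
  std::string db(n, '.');
  IntegerVector pairs(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (pt[i] >= 0) {
      pairs[i] = pt[i] + 1; // 1-based partner
      db[i] = (pt[i] > i) ? '(' : ')';
    }
  }
  return List::create(_["structure"] = db, _["energy"] = mfe,
                      _["pairs"] = pairs);
}

// [[Rcpp::export(name = ".engineParams")]]
List engineParams() {
  NumericMatrix stack(6, 6);
  CharacterVector pn = CharacterVector::create("AU", "UA", "GC", "CG", "GU", "UG");
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) stack(i, j) = STACK[i][j];
  stack.attr("dimnames") = List::create(pn, pn);
  return List::create(
    _["version"] = "pomiR-nn-1",
    _["stack"] = stack,
    _["loop_slope"] = LOOP_SLOPE,
    _["hairpin_base"] = HAIRPIN_BASE,
    _["bulge_base"] = BULGE_BASE,
    _["internal_base"] = INTERNAL_BASE,
    _["max_interior"] = MAX_INTERIOR,
    _["multi_a"] = MULTI_A,
    _["multi_b"] = MULTI_B,
    _["duplex_init"] = DUPLEX_INIT,
    _["min_hairpin_loop"] = 3);
}
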
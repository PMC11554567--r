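// Minimum-free-energy folding of short RNA windows under a simplified
// nearest-neighbour model: 6 canonical pair strengths (stack energy = mean
// of the two stacked pairs' strengths), linear-in-size hairpin / bulge /
// internal loop penalties, affine multiloop cost, free exterior bases.
// Non-crossing structures only; hairpin loops hold >= min_hairpin bases.
// Energy constants are supplied from R so the R-side oracle and this DP
// share a single definition.

#include <Rcpp.h>
#include <vector>
#include <functional>
using namespace Rcpp;

static const double INF = 1e9;
static const double TOL = 1e-9;

// base codes: A=0, C=1, G=2, U=3, N=4 (never pairs)
// pair types: AU=0, UA=1, GC=2, CG=3, GU=4, UG=5, none=-1
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Params {
  double strength[6];
  double hp_a, hp_b, bulge_a, bulge_b, int_a, int_b;
  double ml_a, ml_b, ml_c;
  int max_loop, min_hairpin;
};

// [[Rcpp::export]]
List fold_seq_cpp(IntegerVector seq, List par) {
  Params P;
  NumericVector ps = par["pair_strength"];
  for (int t = 0; t < 6; ++t) P.strength[t] = ps[t];
  P.hp_a = par["hp_a"]; P.hp_b = par["hp_b"];
  P.bulge_a = par["bulge_a"]; P.bulge_b = par["bulge_b"];
  P.int_a = par["int_a"]; P.int_b = par["int_b"];
  P.ml_a = par["ml_a"]; P.ml_b = par["ml_b"]; P.ml_c = par["ml_c"];
  P.max_loop = par["max_loop"]; P.min_hairpin = par["min_hairpin"];

  const int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  if (n == 0) return List::create(_["mfe"] = 0.0, _["dotbracket"] = "");

  auto hp = [&](int size) { return P.hp_a + P.hp_b * (size - P.min_hairpin); };
  auto il = [&](int s1, int s2) {
    if (s1 == 0 || s2 == 0) return P.bulge_a + P.bulge_b * (s1 + s2);
    return P.int_a + P.int_b * (s1 + s2);
  };
  auto stackE = [&](int t_out, int t_in) {
    return 0.5 * (P.strength[t_out] + P.strength[t_in]);
  };

  std::vector<double> V((size_t)n * n, INF), WM((size_t)n * n, INF);
  auto ix = [&](int i, int j) { return (size_t)i * n + j; };

  // canonical partners l > k of each position k (candidate inner pairs)
  std::vector<std::vector<int>> partners(n);
  for (int k = 0; k < n; ++k)
    for (int l = k + P.min_hairpin + 1; l < n; ++l)
      if (pair_type(s[k], s[l]) >= 0) partners[k].push_back(l);

  for (int span = P.min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int tij = pair_type(s[i], s[j]);
      if (tij >= 0) {
        double best = hp(j - i - 1);
        // stack
        int tin = pair_type(s[i + 1], s[j - 1]);
        if (tin >= 0 && V[ix(i + 1, j - 1)] < INF / 2) {
          double e = stackE(tij, tin) + V[ix(i + 1, j - 1)];
          if (e < best) best = e;
        }
        // internal / bulge loops
        for (int k = i + 1; k <= j - 2; ++k) {
          int s1 = k - i - 1;
          if (s1 > P.max_loop) break;
          for (int l : partners[k]) {
            if (l >= j) break;
            int s2 = j - l - 1;
            if (s1 + s2 == 0 || s1 + s2 > P.max_loop) continue;
            if (V[ix(k, l)] >= INF / 2) continue;
            double e = il(s1, s2) + V[ix(k, l)];
            if (e < best) best = e;
          }
        }
        // multiloop: closing pair counts as one branch
        for (int k = i + 1; k < j - 1; ++k) {
          if (WM[ix(i + 1, k)] >= INF / 2 || WM[ix(k + 1, j - 1)] >= INF / 2)
            continue;
          double e = P.ml_a + P.ml_b + WM[ix(i + 1, k)] + WM[ix(k + 1, j - 1)];
          if (e < best) best = e;
        }
        V[ix(i, j)] = best;
      }
      // WM: segment inside a multiloop, >= 1 branch
      {
        double best = INF;
        if (V[ix(i, j)] < INF / 2) best = V[ix(i, j)] + P.ml_b;
        if (i + 1 <= j && WM[ix(i + 1, j)] < INF / 2)
          best = std::min(best, WM[ix(i + 1, j)] + P.ml_c);
        if (i <= j - 1 && WM[ix(i, j - 1)] < INF / 2)
          best = std::min(best, WM[ix(i, j - 1)] + P.ml_c);
        for (int k = i; k < j; ++k) {
          if (WM[ix(i, k)] < INF / 2 && WM[ix(k + 1, j)] < INF / 2)
            best = std::min(best, WM[ix(i, k)] + WM[ix(k + 1, j)]);
        }
        WM[ix(i, j)] = best;
      }
    }
  }

  // exterior: W[i] = mfe of suffix i..n-1, unpaired bases free
  std::vector<double> W(n + 1, 0.0);
  std::vector<int> Wmate(n, -1); // pairing choice for traceback
  for (int i = n - 1; i >= 0; --i) {
    double best = W[i + 1];
    int mate = -1;
    for (int j = i + P.min_hairpin + 1; j < n; ++j) {
      if (V[ix(i, j)] >= INF / 2) continue;
      double e = V[ix(i, j)] + W[j + 1];
      if (e < best - TOL) { best = e; mate = j; }
    }
    W[i] = best;
    Wmate[i] = mate;
  }

  // traceback (prefers unpaired, then hairpin/stack/internal/multi in order)
  std::string db(n, '.');
  std::function<void(int, int)> traceV;
  std::function<void(int, int)> traceWM;

  traceV = [&](int i, int j) {
    db[i] = '('; db[j] = ')';
    int tij = pair_type(s[i], s[j]);
    double v = V[ix(i, j)];
    if (std::abs(v - hp(j - i - 1)) < TOL) return;
    int tin = pair_type(s[i + 1], s[j - 1]);
    if (tin >= 0 && V[ix(i + 1, j - 1)] < INF / 2 &&
        std::abs(v - (stackE(tij, tin) + V[ix(i + 1, j - 1)])) < TOL) {
      traceV(i + 1, j - 1);
      return;
    }
    for (int k = i + 1; k <= j - 2; ++k) {
      int s1 = k - i - 1;
      if (s1 > P.max_loop) break;
      for (int l = j - 1; l > k; --l) {
        int s2 = j - l - 1;
        if (s1 + s2 == 0) continue;
        if (s1 + s2 > P.max_loop) break;
        if (pair_type(s[k], s[l]) < 0 || V[ix(k, l)] >= INF / 2) continue;
        if (std::abs(v - (il(s1, s2) + V[ix(k, l)])) < TOL) {
          traceV(k, l);
          return;
        }
      }
    }
    for (int k = i + 1; k < j - 1; ++k) {
      if (WM[ix(i + 1, k)] >= INF / 2 || WM[ix(k + 1, j - 1)] >= INF / 2)
        continue;
      if (std::abs(v - (P.ml_a + P.ml_b + WM[ix(i + 1, k)] +
                        WM[ix(k + 1, j - 1)])) < TOL) {
        traceWM(i + 1, k);
        traceWM(k + 1, j - 1);
        return;
      }
    }
    Rcpp::stop("fold traceback failed (V)");
  };

  traceWM = [&](int i, int j) {
    double w = WM[ix(i, j)];
    if (i + 1 <= j && WM[ix(i + 1, j)] < INF / 2 &&
        std::abs(w - (WM[ix(i + 1, j)] + P.ml_c)) < TOL) {
      traceWM(i + 1, j);
      return;
    }
    if (i <= j - 1 && WM[ix(i, j - 1)] < INF / 2 &&
        std::abs(w - (WM[ix(i, j - 1)] + P.ml_c)) < TOL) {
      traceWM(i, j - 1);
      return;
    }
    if (V[ix(i, j)] < INF / 2 && std::abs(w - (V[ix(i, j)] + P.ml_b)) < TOL) {
      traceV(i, j);
      return;
    }
    for (int k = i; k < j; ++k) {
      if (WM[ix(i, k)] < INF / 2 && WM[ix(k + 1, j)] < INF / 2 &&
          std::abs(w - (WM[ix(i, k)] + WM[ix(k + 1, j)])) < TOL) {
        traceWM(i, k);
        traceWM(k + 1, j);
        return;
      }
    }
    Rcpp::stop("fold traceback failed (WM)");
  };

  int i = 0;
  while (i < n) {
    if (Wmate[i] < 0) { ++i; continue; }
    traceV(i, Wmate[i]);
    i = Wmate[i] + 1;
  }

  return List::create(_["mfe"] = W[0], _["dotbracket"] = db);
}
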
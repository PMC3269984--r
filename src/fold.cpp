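#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <stack>
using namespace Rcpp;

// Minimum-free-energy secondary structure folding (Zuker-type recursions,
// no pseudoknots).  The energy model is a simplified nearest-neighbour set:
// stacking energies for all canonical pairs (Watson-Crick + G:U), tabulated
// hairpin/bulge/internal loop initiation penalties with log extrapolation of
// hairpin loops, a linear asymmetry penalty for internal loops, and an affine
// multibranch-loop model.  All parameters come from R so that the independent
// structure-enumeration evaluator shares the exact same tables.

static const double INF = 1e9;

// base codes: A=0, C=1, G=2, U=3
static inline int pairType(int a, int b) {
  if (a == 0 && b == 3) return 0; // AU
  if (a == 3 && b == 0) return 1; // UA
  if (a == 1 && b == 2) return 2; // CG
  if (a == 2 && b == 1) return 3; // GC
  if (a == 2 && b == 3) return 4; // GU
  if (a == 3 && b == 2) return 5; // UG
  return -1;
}

struct EnergyModel {
  NumericMatrix stack;     // 6 x 6, indexed by pairType of outer, inner
  NumericVector hairpin;   // length 30, loop sizes 1..30 (sizes < 3 unused)
  NumericVector bulge;     // length 30
  NumericVector internal;  // length 30 (total loop size)
  double asym, asymMax, multiA, multiB, multiC, jsCoef;
  int maxLoop;

  double hairpinE(int l) const {
    if (l < 3) return INF;
    if (l <= 30) return hairpin[l - 1];
    return hairpin[29] + jsCoef * std::log((double)l / 30.0);
  }
  double bulgeE(int l) const {
    if (l < 1 || l > 30) return INF;
    return bulge[l - 1];
  }
  double internalE(int l1, int l2) const {
    int l = l1 + l2;
    if (l > maxLoop || l > 30) return INF;
    return internal[l - 1] + std::min(asymMax, asym * std::abs(l1 - l2));
  }
};

static EnergyModel readModel(List par) {
  EnergyModel em;
  em.stack = as<NumericMatrix>(par["stack"]);
  em.hairpin = as<NumericVector>(par["hairpin"]);
  em.bulge = as<NumericVector>(par["bulge"]);
  em.internal = as<NumericVector>(par["internal"]);
  em.asym = as<double>(par["asym"]);
  em.asymMax = as<double>(par["asym_max"]);
  em.multiA = as<double>(par["multi_a"]);
  em.multiB = as<double>(par["multi_b"]);
  em.multiC = as<double>(par["multi_c"]);
  em.jsCoef = as<double>(par["js_coef"]);
  em.maxLoop = as<int>(par["max_loop"]);
  return em;
}

// [[Rcpp::export(name = ".foldCpp")]]
List foldCpp(IntegerVector seq, List par) {
  const EnergyModel em = readModel(par);
  const int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());

  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > WM(n, std::vector<double>(n, INF));
  std::vector<double> W(n, 0.0);

  // interior-loop candidate energy for closing pair (i,j) and inner (p,q)
  auto loopE = [&](int i, int j, int p, int q) -> double {
    int l1 = p - i - 1, l2 = j - q - 1;
    if (l1 == 0 && l2 == 0)
      return em.stack(pairType(s[i], s[j]), pairType(s[p], s[q]));
    if (l1 == 0 || l2 == 0) {
      int l = l1 + l2;
      double e = em.bulgeE(l);
      if (l == 1 && e < INF) // helix stacks across a single-nt bulge
        e += em.stack(pairType(s[i], s[j]), pairType(s[p], s[q]));
      return e;
    }
    return em.internalE(l1, l2);
  };

  for (int j = 4; j < n; ++j) {
    for (int i = j - 4; i >= 0; --i) {
      if (pairType(s[i], s[j]) >= 0) {
        double best = em.hairpinE(j - i - 1);
        // stack / bulge / internal
        int pmax = std::min(i + em.maxLoop + 1, j - 4);
        for (int p = i + 1; p <= pmax; ++p) {
          int l1 = p - i - 1;
          int qmin = std::max(p + 4, j - 1 - (em.maxLoop - l1));
          for (int q = j - 1; q >= qmin; --q) {
            if (pairType(s[p], s[q]) < 0) continue;
            double le = loopE(i, j, p, q);
            if (le >= INF) continue;
            double e = le + V[p][q];
            if (e < best) best = e;
          }
        }
        // multibranch
        for (int k = i + 2; k <= j - 2; ++k) {
          double e = em.multiA + em.multiB + WM[i + 1][k] + WM[k + 1][j - 1];
          if (e < best) best = e;
        }
        V[i][j] = best;
      }
      // WM: >= 1 branch in multiloop context
      double wm = INF;
      if (i + 1 <= j) wm = std::min(wm, WM[i + 1][j] + em.multiC);
      if (i <= j - 1) wm = std::min(wm, WM[i][j - 1] + em.multiC);
      if (V[i][j] < INF) wm = std::min(wm, V[i][j] + em.multiB);
      for (int k = i; k < j; ++k)
        if (WM[i][k] < INF && WM[k + 1][j] < INF)
          wm = std::min(wm, WM[i][k] + WM[k + 1][j]);
      WM[i][j] = wm;
    }
  }

  for (int j = 0; j < n; ++j) {
    double w = (j > 0) ? W[j - 1] : 0.0;
    for (int i = 0; i <= j - 4; ++i) {
      double prev = (i > 0) ? W[i - 1] : 0.0;
      if (V[i][j] < INF) w = std::min(w, prev + V[i][j]);
    }
    W[j] = w;
  }
  double mfe = (n > 0) ? W[n - 1] : 0.0;

  // traceback -------------------------------------------------------------
  const double EPS = 1e-7;
  std::vector<int> partner(n, -1);
  struct Task { int type, i, j; }; // 0 = W up to j, 1 = V(i,j), 2 = WM(i,j)
  std::stack<Task> tasks;
  if (n > 0 && W[n - 1] < -EPS) tasks.push({0, 0, n - 1});

  while (!tasks.empty()) {
    Task t = tasks.top(); tasks.pop();
    int i = t.i, j = t.j;
    if (t.type == 0) { // external segment ending at j
      while (j >= 4 && W[j] < -EPS) {
        if (std::abs(W[j] - W[j - 1]) < EPS) { --j; continue; }
        bool found = false;
        for (int i2 = 0; i2 <= j - 4 && !found; ++i2) {
          double prev = (i2 > 0) ? W[i2 - 1] : 0.0;
          if (V[i2][j] < INF && std::abs(W[j] - (prev + V[i2][j])) < EPS) {
            tasks.push({1, i2, j});
            found = true;
            j = i2 - 1;
          }
        }
        if (!found) stop("fold traceback failed in W");
      }
    } else if (t.type == 1) { // V(i,j): i pairs j
      partner[i] = j; partner[j] = i;
      double v = V[i][j];
      if (std::abs(v - em.hairpinE(j - i - 1)) < EPS) continue;
      bool done = false;
      int pmax = std::min(i + em.maxLoop + 1, j - 4);
      for (int p = i + 1; p <= pmax && !done; ++p) {
        int l1 = p - i - 1;
        int qmin = std::max(p + 4, j - 1 - (em.maxLoop - l1));
        for (int q = j - 1; q >= qmin && !done; --q) {
          if (pairType(s[p], s[q]) < 0) continue;
          double le = loopE(i, j, p, q);
          if (le >= INF || V[p][q] >= INF) continue;
          if (std::abs(v - (le + V[p][q])) < EPS) {
            tasks.push({1, p, q});
            done = true;
          }
        }
      }
      if (done) continue;
      for (int k = i + 2; k <= j - 2 && !done; ++k) {
        if (WM[i + 1][k] >= INF || WM[k + 1][j - 1] >= INF) continue;
        if (std::abs(v - (em.multiA + em.multiB + WM[i + 1][k] + WM[k + 1][j - 1])) < EPS) {
          tasks.push({2, i + 1, k});
          tasks.push({2, k + 1, j - 1});
          done = true;
        }
      }
      if (!done) stop("fold traceback failed in V");
    } else { // WM(i,j)
      double wm = WM[i][j];
      if (wm >= INF) stop("fold traceback failed in WM");
      if (i + 1 <= j && std::abs(wm - (WM[i + 1][j] + em.multiC)) < EPS) {
        tasks.push({2, i + 1, j}); continue;
      }
      if (i <= j - 1 && std::abs(wm - (WM[i][j - 1] + em.multiC)) < EPS) {
        tasks.push({2, i, j - 1}); continue;
      }
      if (V[i][j] < INF && std::abs(wm - (V[i][j] + em.multiB)) < EPS) {
        tasks.push({1, i, j}); continue;
      }
      bool done = false;
      for (int k = i; k < j && !done; ++k) {
        if (WM[i][k] >= INF || WM[k + 1][j] >= INF) continue;
        if (std::abs(wm - (WM[i][k] + WM[k + 1][j])) < EPS) {
          tasks.push({2, i, k});
          tasks.push({2, k + 1, j});
          done = true;
        }
      }
      if (!done) stop("fold traceback failed in WM split");
    }
  }

  std::string db(n, '.');
  for (int i = 0; i < n; ++i)
    if (partner[i] > i) { db[i] = '('; db[partner[i]] = ')'; }

  double e = (mfe < 0.0) ? mfe : 0.0;
  if (mfe >= -EPS) { // open chain
    e = 0.0;
    db.assign(n, '.');
  }
  return List::create(_["structure"] = db, _["mfe"] = e);
}
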
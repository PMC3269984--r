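#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted penalty scoring of an antiparallel miRNA:mRNA duplex.
// The miRNA (5'->3') is aligned against the reverse of the target site so
// that miRNA position i faces site base rs[j]; a Watson-Crick pair costs 0,
// a G:U wobble gu_penalty, any other apposition mismatch_penalty and each
// gap position gap_penalty.  Penalties incurred at miRNA positions inside
// the seed range are multiplied by seed_mult.  At most max_gaps total gap
// positions are allowed; both sequences must be consumed end to end.

static const double BIG = 1e9;

// base codes: A=0, C=1, G=2, U=3
static inline bool watsonCrick(int a, int b) {
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 1 && b == 2) || (a == 2 && b == 1);
}
static inline bool wobble(int a, int b) {
  return (a == 2 && b == 3) || (a == 3 && b == 2);
}

struct Schema {
  double mismatch, gu, gap, seedMult;
  int seedLo, seedHi, maxGaps;
  double mult(int pos1based) const {
    return (pos1based >= seedLo && pos1based <= seedHi) ? seedMult : 1.0;
  }
};

static Schema readSchema(List sc) {
  Schema s;
  s.mismatch = as<double>(sc["mismatch_penalty"]);
  s.gu = as<double>(sc["gu_penalty"]);
  s.gap = as<double>(sc["gap_penalty"]);
  s.seedMult = as<double>(sc["seed_multiplier"]);
  s.seedLo = as<int>(sc["seed_start"]);
  s.seedHi = as<int>(sc["seed_end"]);
  s.maxGaps = as<int>(sc["max_gaps"]);
  return s;
}

// pairing cost of miRNA base m at 1-based miRNA position pos vs site base b
static inline double pairCost(const Schema& s, int m, int pos, int b) {
  double c;
  if (watsonCrick(m, b)) c = 0.0;
  else if (wobble(m, b)) c = s.gu;
  else c = s.mismatch;
  return c * s.mult(pos);
}

// DP over (i miRNA bases consumed, j reversed-site bases consumed, g gaps used)
static double duplexDP(const std::vector<int>& mir, const std::vector<int>& rs,
                       const Schema& sc,
                       std::vector<std::vector<std::vector<double> > >* keep) {
  const int L = mir.size(), S = rs.size(), G = sc.maxGaps;
  std::vector<std::vector<std::vector<double> > > D(
      L + 1, std::vector<std::vector<double> >(S + 1, std::vector<double>(G + 1, BIG)));
  D[0][0][0] = 0.0;
  for (int i = 0; i <= L; ++i)
    for (int j = 0; j <= S; ++j)
      for (int g = 0; g <= G; ++g) {
        double d = D[i][j][g];
        if (d >= BIG) continue;
        if (i < L && j < S) {
          double e = d + pairCost(sc, mir[i], i + 1, rs[j]);
          if (e < D[i + 1][j + 1][g]) D[i + 1][j + 1][g] = e;
        }
        if (g < G) {
          if (i < L) { // miRNA base unopposed (gap in target)
            double e = d + sc.gap * sc.mult(i + 1);
            if (e < D[i + 1][j][g + 1]) D[i + 1][j][g + 1] = e;
          }
          if (j < S) { // site base unopposed (gap in miRNA)
            double e = d + sc.gap * sc.mult(std::min(i + 1, L));
            if (e < D[i][j + 1][g + 1]) D[i][j + 1][g + 1] = e;
          }
        }
      }
  double best = BIG;
  for (int g = 0; g <= G; ++g) best = std::min(best, D[L][S][g]);
  if (keep) *keep = D;
  return best;
}

static const char* BASES = "ACGU";

// [[Rcpp::export(name = ".scoreDuplexCpp")]]
List scoreDuplexCpp(IntegerVector mirna, IntegerVector site, List schema) {
  Schema sc = readSchema(schema);
  std::vector<int> mir(mirna.begin(), mirna.end());
  std::vector<int> st(site.begin(), site.end());
  std::vector<int> rs(st.rbegin(), st.rend());
  std::vector<std::vector<std::vector<double> > > D;
  double best = duplexDP(mir, rs, sc, &D);
  if (best >= BIG) stop("no admissible duplex alignment under the gap cap");

  // traceback for the three-line duplex rendering
  const int L = mir.size(), S = rs.size(), G = sc.maxGaps;
  int bg = 0;
  for (int g = 0; g <= G; ++g) if (D[L][S][g] < D[L][S][bg]) bg = g;
  int i = L, j = S, g = bg;
  const double EPS = 1e-9;
  std::string mline, pline, sline; // built 3'->5' of miRNA, reversed later
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(D[i][j][g] - (D[i - 1][j - 1][g] + pairCost(sc, mir[i - 1], i, rs[j - 1]))) < EPS) {
      mline += BASES[mir[i - 1]];
      sline += BASES[rs[j - 1]];
      if (watsonCrick(mir[i - 1], rs[j - 1])) pline += '|';
      else if (wobble(mir[i - 1], rs[j - 1])) pline += 'o';
      else pline += ' ';
      --i; --j;
    } else if (g > 0 && i > 0 &&
               std::abs(D[i][j][g] - (D[i - 1][j][g - 1] + sc.gap * sc.mult(i))) < EPS) {
      mline += BASES[mir[i - 1]]; sline += '-'; pline += ' ';
      --i; --g;
    } else if (g > 0 && j > 0 &&
               std::abs(D[i][j][g] - (D[i][j - 1][g - 1] + sc.gap * sc.mult(std::min(i + 1, L)))) < EPS) {
      mline += '-'; sline += BASES[rs[j - 1]]; pline += ' ';
      --j; --g;
    } else {
      stop("duplex traceback failed");
    }
  }
  std::string m(mline.rbegin(), mline.rend());
  std::string p(pline.rbegin(), pline.rend());
  std::string s(sline.rbegin(), sline.rend());
  // s currently runs along the reversed site, i.e. 3'->5' of the mRNA when
  // read left to right alongside the 5'->3' miRNA
  return List::create(_["penalty"] = best,
                      _["mirna_line"] = m,
                      _["pairing_line"] = p,
                      _["site_line"] = s);
}

// flat-buffer DP for the window scan: miRNA vs reversed site slice
// rs[j] = tr[p + slen - 1 - j]
static double duplexDPFlat(const std::vector<int>& mir, const std::vector<int>& tr,
                           int p, int slen, const Schema& sc,
                           std::vector<double>& buf) {
  const int L = mir.size(), S = slen, G = sc.maxGaps;
  const int w = (S + 1) * (G + 1);
  std::fill(buf.begin(), buf.begin() + (L + 1) * w, BIG);
  buf[0] = 0.0;
  for (int i = 0; i <= L; ++i)
    for (int j = 0; j <= S; ++j)
      for (int g = 0; g <= G; ++g) {
        double d = buf[i * w + j * (G + 1) + g];
        if (d >= BIG) continue;
        if (i < L && j < S) {
          double e = d + pairCost(sc, mir[i], i + 1, tr[p + S - 1 - j]);
          double& tgt = buf[(i + 1) * w + (j + 1) * (G + 1) + g];
          if (e < tgt) tgt = e;
        }
        if (g < G) {
          if (i < L) {
            double e = d + sc.gap * sc.mult(i + 1);
            double& tgt = buf[(i + 1) * w + j * (G + 1) + g + 1];
            if (e < tgt) tgt = e;
          }
          if (j < S) {
            double e = d + sc.gap * sc.mult(std::min(i + 1, L));
            double& tgt = buf[i * w + (j + 1) * (G + 1) + g + 1];
            if (e < tgt) tgt = e;
          }
        }
      }
  double best = BIG;
  for (int g = 0; g <= G; ++g) best = std::min(best, buf[L * w + S * (G + 1) + g]);
  return best;
}

// [[Rcpp::export(name = ".scanTargetsCpp")]]
DataFrame scanTargetsCpp(IntegerVector mirna, IntegerVector transcript,
                         List schema, double cutoff) {
  Schema sc = readSchema(schema);
  std::vector<int> mir(mirna.begin(), mirna.end());
  std::vector<int> tr(transcript.begin(), transcript.end());
  const int L = mir.size(), n = tr.size(), G = sc.maxGaps;
  std::vector<int> starts, ends;
  std::vector<double> pens;
  std::vector<double> buf((L + 1) * (L + G + 1) * (G + 1));
  for (int p = 0; p < n; ++p) {
    // sound lower bound: in any admissible duplex at this window start,
    // miRNA base i either faces a site base within +-2G of its ungapped
    // apposition, or is unopposed at cost gap * mult(i); summing the
    // per-base minimum therefore never exceeds the true optimum
    {
      double bound = 0.0;
      for (int i = 0; i < L; ++i) {
        double m = sc.gap * sc.mult(i + 1);
        int center = p + L - 1 - i;
        for (int d = -2 * G; d <= 2 * G; ++d) {
          int t = center + d;
          if (t < p || t >= n) continue;
          double c = pairCost(sc, mir[i], i + 1, tr[t]);
          if (c < m) m = c;
        }
        bound += m;
        if (bound > cutoff + 1e-9) break;
      }
      if (bound > cutoff + 1e-9) continue;
    }
    double best = BIG; int bestLen = -1;
    for (int slen = L - G; slen <= L + G; ++slen) {
      if (slen < 1 || p + slen > n) continue;
      double d = duplexDPFlat(mir, tr, p, slen, sc, buf);
      if (d < best) { best = d; bestLen = slen; }
    }
    if (best <= cutoff + 1e-9) {
      starts.push_back(p);
      ends.push_back(p + bestLen);
      pens.push_back(best);
    }
  }
  return DataFrame::create(_["t_start"] = wrap(starts), _["t_end"] = wrap(ends),
                           _["penalty"] = wrap(pens));
}
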
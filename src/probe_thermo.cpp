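// Thermodynamic sequence kernels for capture probes.
//
// PMFE is a weighted Nussinov-style folding recursion: maximize the total
// pair weight over non-crossing structures with a minimum hairpin loop of
// 3 unpaired bases; weights GC=3, AT=2, GT=1 (wobble).  The reported
// energy is the negative of the optimum (negative = stable).
// pmfe_enum_cpp explores the full recursion tree without memoization and
// serves as the exhaustive oracle for short sequences.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

static inline bool wc_complement(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G');
}

// [[Rcpp::export]]
double pmfe_dp_cpp(std::string s, int minloop = 3) {
  int n = (int)s.size();
  if (n < minloop + 2) return 0.0;
  std::vector<std::vector<int> > E(n, std::vector<int>(n, 0));
  for (int i = n - 2; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) {
      int best = E[i + 1][j];  // i unpaired
      for (int k = i + minloop + 1; k <= j; ++k) {
        int w = pair_weight(s[i], s[k]);
        if (!w) continue;
        int v = w;
        if (k - 1 >= i + 1) v += E[i + 1][k - 1];
        if (k + 1 <= j) v += E[k + 1][j];
        if (v > best) best = v;
      }
      E[i][j] = best;
    }
  }
  return -(double)E[0][n - 1];
}

static int enum_best(const std::string& s, int i, int j, int minloop) {
  if (j - i < minloop + 1) return 0;
  int best = enum_best(s, i + 1, j, minloop);
  for (int k = i + minloop + 1; k <= j; ++k) {
    int w = pair_weight(s[i], s[k]);
    if (!w) continue;
    int v = w + enum_best(s, i + 1, k - 1, minloop) +
            enum_best(s, k + 1, j, minloop);
    if (v > best) best = v;
  }
  return best;
}

// exhaustive oracle: full recursion tree, no memoization
// [[Rcpp::export]]
double pmfe_enum_cpp(std::string s, int minloop = 3) {
  int n = (int)s.size();
  if (n < minloop + 2) return 0.0;
  return -(double)enum_best(s, 0, n - 1, minloop);
}

// longest self-complementary stem with an internal loop of >= minloop
// unpaired bases; Watson-Crick pairs only
// [[Rcpp::export]]
int hairpin_score_cpp(std::string s, int minloop = 3) {
  int n = (int)s.size();
  if (n < minloop + 2) return 0;
  // inrun[i][j]: consecutive complementary pairs starting at (i, j)
  // going inward (i+1, j-1), computed on demand via recurrence order
  std::vector<std::vector<int> > inrun(n, std::vector<int>(n, 0));
  int best = 0;
  for (int span = 1; span < n; ++span) {     // span = j - i, increasing
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (!wc_complement(s[i], s[j])) continue;
      int inner = (j - 1 > i + 1) ? inrun[i + 1][j - 1] : 0;
      inrun[i][j] = 1 + inner;
      int geom_max = (j - i + 1 - minloop) / 2;  // loop >= minloop
      int L = std::min(inrun[i][j], geom_max);
      if (L > best) best = L;
    }
  }
  return best;
}

// maximum contiguous complementary duplex between two copies of s in
// antiparallel orientation (no loop constraint; indices independent)
// [[Rcpp::export]]
int dimer_score_cpp(std::string s) {
  int n = (int)s.size();
  if (n == 0) return 0;
  // run[i][j]: duplex length with outermost pair (i on copy 1, j on copy 2)
  // extending inward to (i+1, j-1)
  std::vector<std::vector<int> > run(n, std::vector<int>(n, 0));
  int best = 0;
  // (i, j) depends on (i+1, j-1): same anti-diagonal i+j, larger i first
  for (int t = 0; t <= 2 * (n - 1); ++t) {
    int ihi = std::min(t, n - 1);
    int ilo = std::max(0, t - (n - 1));
    for (int i = ihi; i >= ilo; --i) {
      int j = t - i;
      if (!wc_complement(s[i], s[j])) continue;
      int inner = (i + 1 < n && j - 1 >= 0) ? run[i + 1][j - 1] : 0;
      run[i][j] = 1 + inner;
      if (run[i][j] > best) best = run[i][j];
    }
  }
  return best;
}
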
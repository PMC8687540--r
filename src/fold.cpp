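#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair energy under the built-in nested-structure model:
// GC/CG = -3, AU/UA = -2, GU/UG = -1, otherwise not pairable.
static inline int pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1;
  return 0;
}

// Nussinov-style dynamic program minimizing total pair energy over all
// nested (pseudoknot-free) structures with a minimum hairpin loop of
// `min_loop` unpaired bases. Returns the minimum free energy (<= 0).
// [[Rcpp::export(name = ".fold_mfe_cpp")]]
double fold_mfe_cpp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  if (n == 0) return 0.0;
  std::vector<std::vector<double>> E(n, std::vector<double>(n, 0.0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[i][j - 1];  // j unpaired
      // j paired with k in [i, j - min_loop - 1]
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int e = pair_energy(seq[k], seq[j]);
        if (e == 0) continue;
        double left = (k > i) ? E[i][k - 1] : 0.0;
        double inside = (k + 1 <= j - 1) ? E[k + 1][j - 1] : 0.0;
        double cand = left + e + inside;
        if (cand < best) best = cand;
      }
      E[i][j] = best;
    }
  }
  return E[0][n - 1];
}
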
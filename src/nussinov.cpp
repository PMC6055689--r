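#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick (+ optional G.U wobble) pairability
static inline bool can_pair(char a, char b, bool wobble) {
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return true;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
  if (wobble && ((a == 'G' && b == 'U') || (a == 'U' && b == 'G'))) return true;
  return false;
}

// Nussinov-style base-pair maximization with a minimum hairpin-loop size.
// Returns the 1-based pairing vector (0 = unpaired) of one maximizing
// nested structure, chosen by a fixed traceback order (prefer the 3' end
// unpaired, else the 5'-most pairing partner), so the output is
// deterministic.
// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerVector nussinov_pairs(std::string rna, int min_loop, bool wobble) {
  int n = rna.size();
  IntegerVector pairing(n, 0);
  if (n < 2) return pairing;

  // M[i][j]: max pairs on subsequence [i, j], 0-based
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];                       // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) { // j pairs with k
        if (!can_pair(rna[k], rna[j], wobble)) continue;
        int v = 1 + (k > i ? M[i][k - 1] : 0)
                  + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  // iterative traceback with an explicit stack of [i, j] intervals
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    if (M[i][j] == M[i][j - 1]) {       // fixed order: 3' end unpaired first
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(rna[k], rna[j], wobble)) continue;
      int v = 1 + (k > i ? M[i][k - 1] : 0)
                + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
      if (v == M[i][j]) {               // 5'-most maximizing partner
        pairing[k] = j + 1;
        pairing[j] = k + 1;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return pairing;
}
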
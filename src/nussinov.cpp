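#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted maximum base-pairing (Nussinov-style) secondary structure.
// Pair weights in tenths of kcal/mol: GC 20, AU 10, GU 10; N never pairs.
// Minimum hairpin loop of 3 unpaired bases (pair (i,j) requires j - i >= 4).
// Pseudoknot-free by construction.  Deterministic traceback: at ties the
// "leave i unpaired" branch wins, then the smallest pairing partner.

static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 20;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 10;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 10;
  return 0;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = (int) seq.size();
  for (int i = 0; i < n; ++i) {
    char c = toupper(seq[i]);
    if (c == 'T') c = 'U';
    seq[i] = c;
  }
  std::string db(n, '.');
  if (n == 0)
    return List::create(_["structure"] = db, _["mfe"] = 0.0);

  // S[i][j], 0-based, j >= i
  std::vector< std::vector<int> > S(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = S[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (w == 0) continue;
        int cand = w + (k - i >= 2 ? S[i + 1][k - 1] : 0) +
                   (k < j ? S[k + 1][j] : 0);
        if (cand > best) best = cand;
      }
      S[i][j] = best;
    }
  }

  // iterative traceback over segments
  std::vector< std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (S[i][j] == S[i + 1][j]) {  // i unpaired (tie-break branch)
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      int w = pair_weight(seq[i], seq[k]);
      if (w == 0) continue;
      int cand = w + (k - i >= 2 ? S[i + 1][k - 1] : 0) +
                 (k < j ? S[k + 1][j] : 0);
      if (cand == S[i][j]) {
        db[i] = '(';
        db[k] = ')';
        if (k - i >= 2) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }

  double mfe = -S[0][n - 1] / 10.0;
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
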
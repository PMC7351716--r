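#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Longest exact common substring of two DNA strings by dynamic programming
// over suffix-match lengths, O(|a|*|b|) time, O(|b|) memory. Ties are broken
// by smallest start in a, then smallest start in b. Returns 1-based starts;
// zero-length matches report start 0.
// [[Rcpp::export(name = ".lcs_dp")]]
IntegerVector lcs_dp(std::string a, std::string b) {
  const int na = a.size(), nb = b.size();
  std::vector<int> prev(nb + 1, 0), cur(nb + 1, 0);
  int best = 0, best_ai = 0, best_bj = 0; // 1-based starts
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      if (a[i - 1] == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        const int len = cur[j];
        if (len > best) {
          best = len;
          best_ai = i - len + 1;
          best_bj = j - len + 1;
        } else if (len == best && best > 0) {
          const int ai = i - len + 1, bj = j - len + 1;
          if (ai < best_ai || (ai == best_ai && bj < best_bj)) {
            best_ai = ai;
            best_bj = bj;
          }
        }
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return IntegerVector::create(best, best_ai, best_bj);
}
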
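#include <Rcpp.h>
using namespace Rcpp;

// Longest-match lengths for the increasing-window entropy-rate estimator.
// For each position i (2..n, 1-based), returns the length of the longest
// contiguous subsequence starting at i that also occurs entirely within
// positions 1..i-1. Tokens arrive as integer codes.
// [[Rcpp::export(name = ".lz78_match_lengths")]]
IntegerVector lz78_match_lengths(IntegerVector tokens) {
  int n = tokens.size();
  if (n < 2) return IntegerVector(0);
  IntegerVector out(n - 1);
  for (int i = 1; i < n; ++i) { // 0-based position of the window start
    int best = 0;
    for (int start = 0; start < i; ++start) {
      // match must stay within the prefix: start + len - 1 <= i - 1
      int cap = i - start;
      if (n - i < cap) cap = n - i;
      if (cap <= best) continue;
      int len = 0;
      while (len < cap && tokens[start + len] == tokens[i + len]) ++len;
      if (len > best) best = len;
    }
    out[i - 1] = best;
  }
  return out;
}
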
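#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

// Semi-global unit-cost edit distance: the pattern (read) must align
// end-to-end, both ends of the text (reference window) are free. Standard
// DP with two rolling rows; O(|pattern| * |text|) time, O(|text|) space.
// Returns the minimum edit distance over all end positions in the text.
// [[Rcpp::export(name = ".semiglobal_edit_distance")]]
int semiglobal_edit_distance(std::string pattern, std::string text) {
  const int m = pattern.size();
  const int n = text.size();
  if (m == 0) return 0;
  if (n == 0) return m;
  std::vector<int> prev(n + 1), cur(n + 1);
  // Row 0: aligning an empty pattern prefix; text start is free.
  for (int j = 0; j <= n; ++j) prev[j] = 0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;  // pattern prefix vs empty text: i deletions from pattern
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int sub = prev[j - 1] + (pc == text[j - 1] ? 0 : 1);
      const int del = prev[j] + 1;  // consume pattern base, no text base
      const int ins = cur[j - 1] + 1;  // consume text base, no pattern base
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  // Free text end: minimum over the last row.
  return *std::min_element(prev.begin(), prev.end());
}
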
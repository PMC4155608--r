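#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Levenshtein distance, unit costs. 'X' (unknown residue) never matches,
// not even another 'X', so X/X substitution costs 1.
// [[Rcpp::export(name = ".edit_distance_c")]]
int edit_distance_c(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = (a[i - 1] == b[j - 1] && a[i - 1] != 'X') ? 0 : 1;
      cur[j] = std::min({prev[j - 1] + sub, prev[j] + 1, cur[j - 1] + 1});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Class-weighted Levenshtein: substitution costs 0 (identical, non-X),
// 0.5 (different residues sharing a scheme class), 1 otherwise (different
// class, or either side unclassified, e.g. 'X'); indels cost 1.
// class_of maps char codes 0..127 to a class id, -1 = unclassified.
// [[Rcpp::export(name = ".weighted_edit_distance_c")]]
double weighted_edit_distance_c(const std::string& a, const std::string& b,
                                const IntegerVector& class_of) {
  const size_t n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (double)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (double)i;
    const char ca = a[i - 1];
    const int cla = (ca >= 0 && ca < 128) ? class_of[(int)ca] : -1;
    for (size_t j = 1; j <= m; ++j) {
      const char cb = b[j - 1];
      double sub;
      if (ca == cb && ca != 'X') {
        sub = 0.0;
      } else {
        const int clb = (cb >= 0 && cb < 128) ? class_of[(int)cb] : -1;
        sub = (cla >= 0 && cla == clb) ? 0.5 : 1.0;
      }
      cur[j] = std::min({prev[j - 1] + sub, prev[j] + 1.0, cur[j - 1] + 1.0});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
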
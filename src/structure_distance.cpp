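#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Edit distance between two dot-bracket strings under the cost model of
// full-structure string alignment: indel = 1, substitution between a bracket
// and a dot = 1, substitution '(' <-> ')' = 2 (a bracket flip is a
// delete + insert).  Removing or creating one base pair therefore always
// costs 2 edits.
static double db_edit_one(const std::string& a, const std::string& b) {
  const size_t la = a.size(), lb = b.size();
  std::vector<double> prev(lb + 1), cur(lb + 1);
  for (size_t j = 0; j <= lb; ++j) prev[j] = (double)j;
  for (size_t i = 1; i <= la; ++i) {
    cur[0] = (double)i;
    const char ca = a[i - 1];
    for (size_t j = 1; j <= lb; ++j) {
      const char cb = b[j - 1];
      double sub;
      if (ca == cb) sub = 0.0;
      else if ((ca == '(' && cb == ')') || (ca == ')' && cb == '(')) sub = 2.0;
      else sub = 1.0;
      double best = prev[j - 1] + sub;
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      if (del < best) best = del;
      if (ins < best) best = ins;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// [[Rcpp::export(name = ".db_edit_distance")]]
NumericVector db_edit_distance(CharacterVector s1, CharacterVector s2) {
  if (s1.size() != s2.size())
    stop("s1 and s2 must have equal length");
  const R_xlen_t n = s1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(s1[i]);
    std::string b = as<std::string>(s2[i]);
    out[i] = db_edit_one(a, b);
  }
  return out;
}
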
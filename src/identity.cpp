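#include <Rcpp.h>
using namespace Rcpp;

// Maximum number of identical aligned residue pairs between a and b under
// optimal global alignment scored match = 1, mismatch = 0, linear gap = 0.
// With that scoring the optimum equals the longest common subsequence, so a
// two-row LCS recurrence suffices: O(|a|*|b|) time, O(|b|) space.
// [[Rcpp::export(name = ".align_matches")]]
int align_matches(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      if (ai == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
      } else {
        cur[j] = prev[j] > cur[j - 1] ? prev[j] : cur[j - 1];
      }
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All-pairs identity matrix (identities / shorter length); used by the
// brute-force clustering oracle.
// [[Rcpp::export(name = ".identity_matrix")]]
NumericMatrix identity_matrix(const std::vector<std::string>& seqs) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const int shorter = std::min(seqs[i].size(), seqs[j].size());
      const double id =
          shorter == 0 ? 0.0
                       : (double)align_matches(seqs[i], seqs[j]) / shorter;
      out(i, j) = id;
      out(j, i) = id;
    }
  }
  return out;
}
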
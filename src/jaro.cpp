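// Jaro-Winkler similarity kernel. Pair scoring compares every blocked
// candidate pair on two name fields, so this is the pipeline's hot loop.
#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static double jaro_one(const std::string& a, const std::string& b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  const int window = std::max(std::max(la, lb) / 2 - 1, 0);
  std::vector<bool> matched_b(lb, false);
  std::vector<int> ma;
  std::vector<int> mb;
  ma.reserve(std::min(la, lb));
  for (int i = 0; i < la; ++i) {
    const int lo = std::max(0, i - window);
    const int hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!matched_b[j] && a[i] == b[j]) {
        matched_b[j] = true;
        ma.push_back(i);
        mb.push_back(j);
        break;
      }
    }
  }
  const int m = ma.size();
  if (m == 0) return 0.0;
  std::vector<int> mb_sorted(mb);
  std::sort(mb_sorted.begin(), mb_sorted.end());
  double t = 0.0;
  for (int k = 0; k < m; ++k) {
    if (a[ma[k]] != b[mb_sorted[k]]) t += 0.5;
  }
  return (double(m) / la + double(m) / lb + (m - t) / m) / 3.0;
}

// [[Rcpp::export]]
NumericVector jw_sim_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("length mismatch");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) {
      out[i] = NA_REAL;
      continue;
    }
    const std::string sa = as<std::string>(a[i]);
    const std::string sb = as<std::string>(b[i]);
    double j = jaro_one(sa, sb);
    int prefix = 0;
    const int maxp = std::min({4, (int)sa.size(), (int)sb.size()});
    for (int k = 0; k < maxp; ++k) {
      if (sa[k] == sb[k]) prefix = k + 1; else break;
    }
    out[i] = j + prefix * 0.1 * (1.0 - j);
  }
  return out;
}
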
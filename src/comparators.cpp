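#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Jaro similarity. Matches are counted within a window of
// floor(max(|a|,|b|)/2) - 1 positions; t is half the number of matched
// characters read back in different order (Winkler's formulation).
static double jaro_one(const std::string &a, const std::string &b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0) return (la == 0 && lb == 0) ? 1.0 : 0.0;
  const int window = std::max(std::max(la, lb) / 2 - 1, 0);
  std::vector<bool> amatch(la, false), bmatch(lb, false);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    const int lo = std::max(0, i - window), hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!bmatch[j] && a[i] == b[j]) {
        amatch[i] = bmatch[j] = true;
        ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;
  int half_transposed = 0, j = 0;
  for (int i = 0; i < la; ++i) {
    if (!amatch[i]) continue;
    while (!bmatch[j]) ++j;
    if (a[i] != b[j]) ++half_transposed;
    ++j;
  }
  const double t = half_transposed / 2.0;
  return ((double)m / la + (double)m / lb + (m - t) / m) / 3.0;
}

static double jw_one(const std::string &a, const std::string &b,
                     double prefix_scale, int max_prefix) {
  const double dj = jaro_one(a, b);
  int l = 0;
  const int lim = std::min((int)std::min(a.size(), b.size()), max_prefix);
  while (l < lim && a[l] == b[l]) ++l;
  return dj + l * prefix_scale * (1.0 - dj);
}

// Restricted Damerau-Levenshtein (optimal string alignment): insertions,
// deletions, substitutions and adjacent transpositions, no substring edited
// twice.
static int osa_one(const std::string &a, const std::string &b) {
  const int la = a.size(), lb = b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  std::vector<int> prev2(lb + 1), prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int d = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        d = std::min(d, prev2[j - 2] + 1);
      cur[j] = d;
    }
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  return prev[lb];
}

// [[Rcpp::export(name = ".jaro_cpp")]]
NumericVector jaro_cpp(CharacterVector s1, CharacterVector s2) {
  const R_xlen_t n = std::max(s1.size(), s2.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String x = s1[i % s1.size()], y = s2[i % s2.size()];
    if (x == NA_STRING || y == NA_STRING) { out[i] = NA_REAL; continue; }
    out[i] = jaro_one(std::string(x.get_cstring()), std::string(y.get_cstring()));
  }
  return out;
}

// [[Rcpp::export(name = ".jaro_winkler_cpp")]]
NumericVector jaro_winkler_cpp(CharacterVector s1, CharacterVector s2,
                               double prefix_scale, int max_prefix) {
  const R_xlen_t n = std::max(s1.size(), s2.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String x = s1[i % s1.size()], y = s2[i % s2.size()];
    if (x == NA_STRING || y == NA_STRING) { out[i] = NA_REAL; continue; }
    out[i] = jw_one(std::string(x.get_cstring()), std::string(y.get_cstring()),
                    prefix_scale, max_prefix);
  }
  return out;
}

// [[Rcpp::export(name = ".osa_cpp")]]
IntegerVector osa_cpp(CharacterVector s1, CharacterVector s2) {
  const R_xlen_t n = std::max(s1.size(), s2.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String x = s1[i % s1.size()], y = s2[i % s2.size()];
    if (x == NA_STRING || y == NA_STRING) { out[i] = NA_INTEGER; continue; }
    out[i] = osa_one(std::string(x.get_cstring()), std::string(y.get_cstring()));
  }
  return out;
}

// [[Rcpp::export(name = ".hamming_cpp")]]
IntegerVector hamming_cpp(CharacterVector s1, CharacterVector s2) {
  const R_xlen_t n = std::max(s1.size(), s2.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String x = s1[i % s1.size()], y = s2[i % s2.size()];
    if (x == NA_STRING || y == NA_STRING) { out[i] = NA_INTEGER; continue; }
    std::string a(x.get_cstring()), b(y.get_cstring());
    if (a.size() != b.size())
      stop("hamming distance requires equal-width inputs (got %d and %d)",
           (int)a.size(), (int)b.size());
    int d = 0;
    for (size_t k = 0; k < a.size(); ++k) if (a[k] != b[k]) ++d;
    out[i] = d;
  }
  return out;
}
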
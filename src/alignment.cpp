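#include <Rcpp.h>
using namespace Rcpp;

// Unit-cost Levenshtein distance, two-row DP.
// [[Rcpp::export(name = ".lev_cpp")]]
int lev_cpp(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Traceback tie-breaking: prefer diagonal, then up (gap in b), then left
// (gap in a). Scores are resolved the same way during the fill so the
// traceback is unambiguous.
// [[Rcpp::export(name = ".nw_cpp")]]
List nw_cpp(const std::string& a, const std::string& b,
            double match, double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 0 diag, 1 up, 2 left
  for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; P(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = S(i - 1, j) + gap;
      double l = S(i, j - 1) + gap;
      double best = d; int ptr = 0;
      if (u > best) { best = u; ptr = 1; }
      if (l > best) { best = l; ptr = 2; }
      S(i, j) = best; P(i, j) = ptr;
    }
  }
  std::string aa, bb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int ptr = P(i, j);
    if (i > 0 && j > 0 && ptr == 0) {
      aa.push_back(a[--i]);
      bb.push_back(b[--j]);
    } else if (i > 0 && (ptr == 1 || j == 0)) {
      aa.push_back(a[--i]); bb.push_back('-');
    } else {
      aa.push_back('-'); bb.push_back(b[--j]);
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["aligned_a"] = aa, _["aligned_b"] = bb,
                      _["score"] = S(n, m));
}

// Fraction of identical columns over the global-alignment length.
// [[Rcpp::export(name = ".nw_identity_cpp")]]
double nw_identity_cpp(const std::string& a, const std::string& b,
                       double match, double mismatch, double gap) {
  List al = nw_cpp(a, b, match, mismatch, gap);
  std::string aa = al[0], bb = al[1];
  int id = 0;
  for (size_t k = 0; k < aa.size(); ++k) if (aa[k] == bb[k]) ++id;
  return aa.empty() ? 0.0 : (double)id / (double)aa.size();
}

// For each query, the maximum alignment identity against any reference.
// Used by the train/test redundancy filter.
// [[Rcpp::export(name = ".max_identity_cpp")]]
NumericVector max_identity_cpp(const std::vector<std::string>& queries,
                               const std::vector<std::string>& refs,
                               double match, double mismatch, double gap) {
  NumericVector out(queries.size());
  for (size_t q = 0; q < queries.size(); ++q) {
    double best = 0.0;
    for (size_t r = 0; r < refs.size(); ++r) {
      double id = nw_identity_cpp(queries[q], refs[r], match, mismatch, gap);
      if (id > best) best = id;
      if (best == 1.0) break;
    }
    out[q] = best;
  }
  return out;
}
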
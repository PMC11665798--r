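#include <Rcpp.h>
using namespace Rcpp;

static int lev_core(const int* a, int na, const int* b, int nb,
                    std::vector<int>& prev, std::vector<int>& curr) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    curr[0] = i;
    for (int j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = curr[j - 1] + 1;
      curr[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, curr);
  }
  return prev[nb];
}

// [[Rcpp::export]]
int lev_dist_cpp(IntegerVector a, IntegerVector b) {
  std::vector<int> prev(b.size() + 1), curr(b.size() + 1);
  return lev_core(a.begin(), a.size(), b.begin(), b.size(), prev, curr);
}

// Distance from one query sequence to each sequence in a list.
// [[Rcpp::export]]
IntegerVector lev_dist_many_cpp(IntegerVector a, List bs) {
  int n = bs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector b = bs[i];
    std::vector<int> prev(b.size() + 1), curr(b.size() + 1);
    out[i] = lev_core(a.begin(), a.size(), b.begin(), b.size(), prev, curr);
  }
  return out;
}

// Elementwise distances for paired lists (used by exhaustive checks).
// [[Rcpp::export]]
IntegerVector lev_dist_pairs_cpp(List as, List bs) {
  int n = as.size();
  if (bs.size() != n) stop("paired lists must have equal length");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = as[i];
    IntegerVector b = bs[i];
    std::vector<int> prev(b.size() + 1), curr(b.size() + 1);
    out[i] = lev_core(a.begin(), a.size(), b.begin(), b.size(), prev, curr);
  }
  return out;
}
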
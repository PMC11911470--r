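#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted KS running-sum extremum for a sorted 0-based index set.
// w holds |stat|^q for every position of the ranked universe.
static double es_from_indices(const NumericVector& w, const std::vector<int>& idx,
                              int N, bool pos_only) {
  const int k = (int) idx.size();
  double W = 0.0;
  for (int j = 0; j < k; ++j) W += w[idx[j]];
  const bool unit = !(W > 0.0);  // all-zero weights: uniform hit increments
  const double denom = (double) (N - k);
  double cum = 0.0, esmax = R_NegInf, esmin = R_PosInf;
  for (int j = 0; j < k; ++j) {
    const double pmiss = (double) (idx[j] - j) / denom;
    const double before = cum - pmiss;
    cum += unit ? 1.0 / k : w[idx[j]] / W;
    const double after = cum - pmiss;
    if (after > esmax) esmax = after;
    if (before < esmin) esmin = before;
  }
  if (pos_only) return esmax;
  return (esmax >= -esmin) ? esmax : esmin;
}

// [[Rcpp::export]]
double gsea_es_cpp(NumericVector w, IntegerVector idx, bool pos_only) {
  const int N = w.size();
  const int k = idx.size();
  if (k < 1 || k >= N) stop("degenerate set in gsea_es_cpp");
  std::vector<int> ix(k);
  for (int j = 0; j < k; ++j) {
    ix[j] = idx[j] - 1;  // R 1-based -> 0-based
    if (ix[j] < 0 || ix[j] >= N) stop("index out of range in gsea_es_cpp");
  }
  std::sort(ix.begin(), ix.end());
  return es_from_indices(w, ix, N, pos_only);
}

// Null ES from random same-size member sets drawn without replacement.
// Uses R's RNG (so set.seed() in R governs reproducibility).
// [[Rcpp::export]]
NumericVector gsea_null_es_cpp(NumericVector w, int k, int n_perm,
                               bool pos_only) {
  const int N = w.size();
  if (k < 1 || k >= N) stop("degenerate set size in gsea_null_es_cpp");
  NumericVector out(n_perm);
  std::vector<int> pool(N);
  for (int i = 0; i < N; ++i) pool[i] = i;
  std::vector<int> idx(k);
  for (int p = 0; p < n_perm; ++p) {
    // partial Fisher-Yates: first k entries become a uniform k-subset
    for (int j = 0; j < k; ++j) {
      int r = j + (int) (unif_rand() * (N - j));
      if (r >= N) r = N - 1;
      std::swap(pool[j], pool[r]);
      idx[j] = pool[j];
    }
    std::sort(idx.begin(), idx.end());
    out[p] = es_from_indices(w, idx, N, pos_only);
  }
  return out;
}
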
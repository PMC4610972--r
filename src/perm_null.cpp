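#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Pooled permutation-null exceedance counts for per-marker G-scores.
//
// For each of n_perm permutations, every sample's marker amplitudes are
// shuffled independently (Fisher-Yates driven by R's RNG, so results are
// reproducible under set.seed) and per-marker amplification/deletion
// G-scores are computed. For each observed sorted G value the number of
// pooled null scores at or above it is accumulated via an exceedance
// histogram.
//
// Returns counts aligned with the *sorted* observed scores.
// [[Rcpp::export]]
List perm_null_counts(NumericMatrix A, double theta, int n_perm,
                      NumericVector g_amp_sorted,
                      NumericVector g_del_sorted) {
  const int S = A.nrow(), M = A.ncol();
  std::vector<int> idx(M);
  std::vector<double> Gamp(M), Gdel(M);
  // hist[u] counts null scores whose upper_bound position in the sorted
  // observed vector is u; counts[i] = sum_{u > i} hist[u]
  std::vector<double> hist_amp(M + 1, 0.0), hist_del(M + 1, 0.0);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    std::fill(Gamp.begin(), Gamp.end(), 0.0);
    std::fill(Gdel.begin(), Gdel.end(), 0.0);
    for (int s = 0; s < S; ++s) {
      for (int j = 0; j < M; ++j) idx[j] = j;
      for (int j = M - 1; j > 0; --j) {
        int k = (int)(unif_rand() * (j + 1));
        if (k > j) k = j;
        std::swap(idx[j], idx[k]);
      }
      for (int j = 0; j < M; ++j) {
        const double a = A(s, idx[j]);
        if (a >= theta) Gamp[j] += a;
        if (a <= -theta) Gdel[j] -= a;
      }
    }
    for (int j = 0; j < M; ++j) {
      const double ga = Gamp[j] / S;
      const double gd = Gdel[j] / S;
      int ua = std::upper_bound(g_amp_sorted.begin(), g_amp_sorted.end(), ga) -
               g_amp_sorted.begin();
      int ud = std::upper_bound(g_del_sorted.begin(), g_del_sorted.end(), gd) -
               g_del_sorted.begin();
      hist_amp[ua] += 1.0;
      hist_del[ud] += 1.0;
    }
  }
  NumericVector counts_amp(M), counts_del(M);
  double acc_a = 0.0, acc_d = 0.0;
  for (int i = M; i >= 1; --i) {
    acc_a += hist_amp[i];
    acc_d += hist_del[i];
    counts_amp[i - 1] = acc_a;
    counts_del[i - 1] = acc_d;
  }
  return List::create(_["amp"] = counts_amp, _["del"] = counts_del);
}
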
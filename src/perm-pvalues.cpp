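#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive permutation p-values for Spearman and Kendall tau-b in one
// pass over all n! index permutations (n <= 10). The statistics used are
// monotone in the respective coefficients: Spearman's rho is monotone in
// S = sum(rx_i * ry_i) over tie-averaged ranks, and Kendall's tau-b is
// monotone in the concordant-minus-discordant numerator (tied pairs
// contribute 0; the tie-correction denominator is permutation-invariant).
// Two-sided p = proportion of permutations whose centered |statistic|
// reaches the observed value.

static double kendall_num(const std::vector<int>& idx,
                          const NumericVector& x, const NumericVector& y) {
  const int n = idx.size();
  double s = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double p = (x[idx[i]] - x[idx[j]]) * (y[i] - y[j]);
      if (p > 0) s += 1.0; else if (p < 0) s -= 1.0;
    }
  return s;
}

// [[Rcpp::export(name = ".perm_rank_pvalues")]]
NumericVector perm_rank_pvalues(NumericVector rx, NumericVector ry,
                                NumericVector x, NumericVector y) {
  const int n = rx.size();
  if (n != ry.size() || n != x.size() || n != y.size())
    stop("length mismatch");
  if (n < 3) stop("need at least 3 pairs");
  if (n > 10) stop("exhaustive enumeration limited to n <= 10");

  double sum_ry = 0.0, mean_rx = 0.0;
  for (int i = 0; i < n; ++i) { sum_ry += ry[i]; mean_rx += rx[i]; }
  mean_rx /= n;
  const double mu_s = mean_rx * sum_ry;  // E[S] under permutation

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  double s_obs = 0.0;
  for (int i = 0; i < n; ++i) s_obs += rx[i] * ry[i];
  const double s_dev_obs = std::fabs(s_obs - mu_s);
  const double k_obs = std::fabs(kendall_num(idx, x, y));

  const double eps = 1e-9;
  long double count_s = 0, count_k = 0, total = 0;
  std::sort(idx.begin(), idx.end());
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[idx[i]] * ry[i];
    if (std::fabs(s - mu_s) >= s_dev_obs - eps) count_s += 1;
    if (std::fabs(kendall_num(idx, x, y)) >= k_obs - eps) count_k += 1;
    total += 1;
  } while (std::next_permutation(idx.begin(), idx.end()));

  return NumericVector::create(
      Named("spearman_p") = (double)(count_s / total),
      Named("kendall_p") = (double)(count_k / total));
}
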
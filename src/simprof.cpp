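#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Row-standardize X (m x n, row-major buffer) to zero mean and unit norm.
// Rows with zero variance are flagged; their correlations are taken as 0
// inside permutation profiles (tied values, e.g. repeated zeros, can make a
// permuted row constant even when the observed rows are not).
static void standardize_rows(const std::vector<double>& X, int m, int n,
                             std::vector<double>& Z, std::vector<char>& ok) {
  for (int i = 0; i < m; ++i) {
    double mean = 0.0;
    for (int t = 0; t < n; ++t) mean += X[i * n + t];
    mean /= n;
    double ss = 0.0;
    for (int t = 0; t < n; ++t) {
      double d = X[i * n + t] - mean;
      Z[i * n + t] = d;
      ss += d * d;
    }
    if (ss > 0.0) {
      double inv = 1.0 / std::sqrt(ss);
      for (int t = 0; t < n; ++t) Z[i * n + t] *= inv;
      ok[i] = 1;
    } else {
      ok[i] = 0;
    }
  }
}

// Ordered (ascending) profile of all pairwise Pearson correlations.
static void sorted_profile(const std::vector<double>& X, int m, int n,
                           std::vector<double>& Z, std::vector<char>& ok,
                           std::vector<double>& prof) {
  standardize_rows(X, m, n, Z, ok);
  int k = 0;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double r = 0.0;
      if (ok[i] && ok[j]) {
        for (int t = 0; t < n; ++t) r += Z[i * n + t] * Z[j * n + t];
        if (r > 1.0) r = 1.0;
        if (r < -1.0) r = -1.0;
      }
      prof[k++] = r;
    }
  }
  std::sort(prof.begin(), prof.end());
}

// In-place independent shuffle of each column (values permuted across the
// group's rows within every sample), using R's RNG so set.seed() governs it.
static void permute_columns(std::vector<double>& X, int m, int n) {
  for (int t = 0; t < n; ++t) {
    for (int i = m - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(X[i * n + t], X[j * n + t]);
    }
  }
}

//' SIMPROF permutation kernel
//'
//' Given a group's expression submatrix (members x samples), builds the mean
//' ordered similarity profile from B1 within-sample permutations, scores the
//' observed profile's summed absolute deviation (the pi statistic) against
//' it, and returns B2 further permuted pi values forming the null.
//' Randomness comes from R's RNG stream.
//'
//' @param x numeric matrix, group members in rows, samples in columns.
//' @param B1 permutations for the mean profile.
//' @param B2 permutations for the pi null distribution.
//' @return list with `obs_profile`, `mean_profile`, `pi_obs`, `perm_pi`.
//' @keywords internal
// [[Rcpp::export]]
List simprof_kernel(NumericMatrix x, int B1, int B2) {
  const int m = x.nrow(), n = x.ncol();
  if (m < 2) stop("group must have at least 2 members");
  if (n < 2) stop("group must span at least 2 samples");
  const int npair = m * (m - 1) / 2;

  // row-major working copy
  std::vector<double> X((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int t = 0; t < n; ++t) X[(size_t)i * n + t] = x(i, t);

  std::vector<double> Z((size_t)m * n), prof(npair);
  std::vector<char> ok(m);

  std::vector<double> obs(npair);
  sorted_profile(X, m, n, Z, ok, obs);

  std::vector<double> mean_prof(npair, 0.0);
  for (int b = 0; b < B1; ++b) {
    permute_columns(X, m, n);
    sorted_profile(X, m, n, Z, ok, prof);
    for (int k = 0; k < npair; ++k) mean_prof[k] += prof[k];
  }
  for (int k = 0; k < npair; ++k) mean_prof[k] /= B1;

  double pi_obs = 0.0;
  for (int k = 0; k < npair; ++k) pi_obs += std::fabs(obs[k] - mean_prof[k]);

  NumericVector perm_pi(B2);
  for (int b = 0; b < B2; ++b) {
    permute_columns(X, m, n);
    sorted_profile(X, m, n, Z, ok, prof);
    double pi = 0.0;
    for (int k = 0; k < npair; ++k) pi += std::fabs(prof[k] - mean_prof[k]);
    perm_pi[b] = pi;
  }

  return List::create(
      _["obs_profile"] = NumericVector(obs.begin(), obs.end()),
      _["mean_profile"] = NumericVector(mean_prof.begin(), mean_prof.end()),
      _["pi_obs"] = pi_obs, _["perm_pi"] = perm_pi);
}
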
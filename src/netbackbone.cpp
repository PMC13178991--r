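#include <Rcpp.h>
using namespace Rcpp;

// Exact Poisson-binomial tails by dynamic-programming convolution with the
// count axis capped at `observed`: probability mass above the cap is
// absorbed, so the cost is O(n * observed) instead of O(n^2).
// Returns c(P(X >= observed), P(X <= observed)), both inclusive.
// [[Rcpp::export(name = "pb_tails_dp")]]
NumericVector pb_tails_dp(NumericVector probs, int observed) {
  int n = probs.size();
  if (observed < 0 || observed > n) stop("observed out of range");
  std::vector<double> dp(observed + 1, 0.0);
  dp[0] = 1.0;
  double absorbed = 0.0;
  for (int t = 0; t < n; ++t) {
    double p = probs[t];
    if (p == 0.0) continue;
    absorbed += dp[observed] * p;
    for (int k = observed; k >= 1; --k) {
      dp[k] = dp[k] * (1.0 - p) + dp[k - 1] * p;
    }
    dp[0] *= (1.0 - p);
  }
  double lower = 0.0;
  for (int k = 0; k <= observed; ++k) lower += dp[k];
  double upper = absorbed + dp[observed];
  if (lower > 1.0) lower = 1.0;
  if (upper > 1.0) upper = 1.0;
  return NumericVector::create(upper, lower);
}

// Curveball trades on a binary matrix: pick two distinct rows, pool the
// columns held by exactly one of them, reshuffle the pool, and hand the
// first |A-only| columns back to row a and the rest to row b. Row and
// column sums are preserved exactly by construction. Uses R's RNG, so
// results are reproducible under set.seed().
// [[Rcpp::export(name = "fastball_trades")]]
IntegerMatrix fastball_trades(IntegerMatrix B, int trades) {
  int m = B.nrow(), n = B.ncol();
  if (m < 2) stop("fastball needs at least 2 rows");
  IntegerMatrix M = clone(B);
  std::vector<int> pool;
  pool.reserve(n);
  for (int t = 0; t < trades; ++t) {
    int a = (int)(unif_rand() * m);
    if (a == m) a = m - 1;
    int b = (int)(unif_rand() * (m - 1));
    if (b >= a) b += 1;
    pool.clear();
    int na = 0;
    for (int k = 0; k < n; ++k) {
      int va = M(a, k), vb = M(b, k);
      if (va == 1 && vb == 0) {
        pool.push_back(k);
        ++na;
      }
    }
    for (int k = 0; k < n; ++k) {
      if (M(a, k) == 0 && M(b, k) == 1) pool.push_back(k);
    }
    int tot = (int)pool.size();
    if (tot < 2 || na == 0 || na == tot) continue;
    for (int k = tot - 1; k > 0; --k) {
      int j = (int)(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(pool[k], pool[j]);
    }
    for (int k = 0; k < tot; ++k) {
      int col = pool[k];
      if (k < na) {
        M(a, col) = 1;
        M(b, col) = 0;
      } else {
        M(a, col) = 0;
        M(b, col) = 1;
      }
    }
  }
  return M;
}
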
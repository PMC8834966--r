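#include <Rcpp.h>
using namespace Rcpp;

// Maximal-magnitude contiguous sum of elementwise products over all
// alignments with |delay| <= maxd (Kadane's scan per delay).  Returns the
// signed best sum; a positive run wins ties against an equal negative run.
static double lsa_best(const std::vector<double>& x,
                       const std::vector<double>& y, int maxd) {
  const int T = (int)x.size();
  double best_pos = 0.0, best_neg = 0.0;
  for (int d = -maxd; d <= maxd; ++d) {
    const int lo = std::max(0, -d);
    const int hi = std::min(T, T - d);
    double cur_p = 0.0, cur_n = 0.0;
    for (int t = lo; t < hi; ++t) {
      const double p = x[t] * y[t + d];
      cur_p = std::max(0.0, cur_p + p);
      cur_n = std::min(0.0, cur_n + p);
      if (cur_p > best_pos) best_pos = cur_p;
      if (cur_n < best_neg) best_neg = cur_n;
    }
  }
  return (best_pos >= -best_neg) ? best_pos : best_neg;
}

// Local similarity of two normal-score series: signed best local sum / T,
// with a permutation p-value (nboot shuffles of y using R's RNG; the
// p-value is the fraction of replicates with |score| >= |observed|).
// [[Rcpp::export]]
List lsa_pair_cpp(NumericVector xs, NumericVector ys, int maxd, int nboot) {
  std::vector<double> x(xs.begin(), xs.end()), y(ys.begin(), ys.end());
  const int T = (int)x.size();
  const double obs = lsa_best(x, y, maxd);
  double pval = NA_REAL;
  if (nboot > 0) {
    int cnt = 0;
    std::vector<double> yp(y);
    for (int b = 0; b < nboot; ++b) {
      for (int i = T - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(yp[i], yp[j]);
      }
      if (std::fabs(lsa_best(x, yp, maxd)) >= std::fabs(obs)) ++cnt;
    }
    pval = (double)cnt / nboot;
  }
  return List::create(_["score"] = obs / T, _["pval"] = pval);
}

// Exhaustive-search oracle used by the test suite: enumerates every
// (start, end, delay) window.  O(T^2 * delays); for short series only.
// [[Rcpp::export]]
double lsa_brute_cpp(NumericVector xs, NumericVector ys, int maxd) {
  const int T = xs.size();
  double best = 0.0;
  for (int d = -maxd; d <= maxd; ++d) {
    const int lo = std::max(0, -d);
    const int hi = std::min(T, T - d);
    for (int s = lo; s < hi; ++s) {
      double sum = 0.0;
      for (int e = s; e < hi; ++e) {
        sum += xs[e] * ys[e + d];
        if (std::fabs(sum) > std::fabs(best) ||
            (std::fabs(sum) == std::fabs(best) && sum > best))
          best = sum;
      }
    }
  }
  return best / T;
}
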
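#include <Rcpp.h>
using namespace Rcpp;

// Sequentially rejective graph test applied independently to each row of a
// p-value matrix, with numeric weights/transitions (epsilon edges evaluated
// at a small concrete value upstream). Used by the Monte Carlo harness,
// where exact arithmetic would be needless overhead: simulated p-values are
// continuous, so ties and knife-edge comparisons have probability zero.
//
// rel_tol guards the p <= alpha*w comparison against one-ulp noise in
// levels such as 0.05 * 0.25.

// [[Rcpp::export]]
LogicalMatrix run_graph_many(NumericVector w0, NumericMatrix G0,
                             NumericMatrix P, double alpha,
                             double rel_tol = 1e-12) {
  const int n = w0.size();
  if (G0.nrow() != n || G0.ncol() != n)
    stop("transition matrix does not match weight vector");
  if (P.ncol() != n)
    stop("p-value matrix must have one column per hypothesis");
  const int reps = P.nrow();
  LogicalMatrix out(reps, n);
  std::vector<double> w(n), g(n * n);

  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i) w[i] = w0[i];
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) g[i * n + j] = G0(i, j);
    std::vector<bool> active(n, true);

    for (;;) {
      int best = -1;
      double best_ratio = 0.0;
      for (int i = 0; i < n; ++i) {
        if (!active[i]) continue;
        double level = alpha * w[i];
        double p = P(r, i);
        if (p <= level * (1.0 + rel_tol)) {
          double ratio = (level > 0.0) ? p / level : 0.0;
          if (best < 0 || ratio < best_ratio) {
            best = i;
            best_ratio = ratio;
          }
        }
      }
      if (best < 0) break;
      const int j = best;
      active[j] = false;
      out(r, j) = true;
      for (int l = 0; l < n; ++l) {
        if (!active[l]) continue;
        w[l] += w[j] * g[j * n + l];
      }
      std::vector<double> g2(g);
      for (int l = 0; l < n; ++l) {
        if (!active[l]) continue;
        const double glj = g[l * n + j];
        const double gjl = g[j * n + l];
        const double den = 1.0 - glj * gjl;
        for (int k = 0; k < n; ++k) {
          if (!active[k] || k == l) continue;
          g2[l * n + k] = (den > 0.0)
            ? (g[l * n + k] + glj * g[j * n + k]) / den
            : 0.0;
        }
        g2[l * n + j] = 0.0;
      }
      for (int k = 0; k < n; ++k) g2[j * n + k] = 0.0;
      g.swap(g2);
      w[j] = 0.0;
    }
  }
  return out;
}
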
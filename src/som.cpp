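#include <Rcpp.h>
using namespace Rcpp;

// Online SOM training with a bubble neighborhood.  All stochastic inputs
// (initial codebook, presentation orders) are produced in R so the loop is
// fully deterministic.  `orders` is n_rows x n_iter (1-based row indices),
// `unit_dist` the grid-space distance matrix between units.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix x, NumericMatrix codebook0,
                   IntegerMatrix orders, NumericVector alphas,
                   NumericVector radii, NumericMatrix unit_dist) {
  const int n = x.nrow(), d = x.ncol(), k = codebook0.nrow();
  const int n_iter = orders.ncol();
  NumericMatrix w = clone(codebook0);
  NumericVector mean_dist(n_iter);

  for (int t = 0; t < n_iter; ++t) {
    const double alpha = alphas[t];
    const double radius = radii[t] + 1e-12;
    double sumd = 0.0;
    for (int p = 0; p < n; ++p) {
      const int i = orders(p, t) - 1;
      int best = 0;
      double bestd = R_PosInf;
      for (int u = 0; u < k; ++u) {
        double dd = 0.0;
        for (int j = 0; j < d; ++j) {
          const double diff = x(i, j) - w(u, j);
          dd += diff * diff;
        }
        if (dd < bestd) {  // strict: ties go to the lowest unit index
          bestd = dd;
          best = u;
        }
      }
      sumd += std::sqrt(bestd);
      for (int u = 0; u < k; ++u) {
        if (unit_dist(u, best) <= radius) {
          for (int j = 0; j < d; ++j)
            w(u, j) += alpha * (x(i, j) - w(u, j));
        }
      }
    }
    mean_dist[t] = sumd / n;
  }
  return List::create(_["codebook"] = w, _["mean_dist"] = mean_dist);
}

// Nearest codebook unit per row (1-based), ties to the lowest index.
// [[Rcpp::export]]
List som_assign_cpp(NumericMatrix x, NumericMatrix w) {
  const int n = x.nrow(), d = x.ncol(), k = w.nrow();
  IntegerVector unit(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bestd = R_PosInf;
    for (int u = 0; u < k; ++u) {
      double dd = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = x(i, j) - w(u, j);
        dd += diff * diff;
      }
      if (dd < bestd) {
        bestd = dd;
        best = u;
      }
    }
    unit[i] = best + 1;
    dist[i] = std::sqrt(bestd);
  }
  return List::create(_["unit"] = unit, _["distance"] = dist);
}
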
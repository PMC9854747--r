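#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

// Online SOM training with a bubble neighborhood.
// X: n x d standardized samples; W: K x d initial weights; coords: K x 2 grid
// coordinates. Per iteration one sample is drawn uniformly with replacement;
// the winner is the neuron with minimal Euclidean distance (ties resolved to
// the lowest index, i.e. lexicographically smallest grid coordinate); the
// winner and all neurons within the current bubble radius (Euclidean grid
// distance) receive the full update lr * (x - w).
// lr(t) = lr0 / (1 + t / (T/2)); radius decays linearly from radius0 to 1.
// [[Rcpp::export]]
arma::mat som_train_cpp(const arma::mat& X, arma::mat W,
                        const arma::mat& coords, double lr0, int iterations,
                        double radius0, int seed) {
  std::mt19937 rng((unsigned int)seed);
  std::uniform_int_distribution<int> pick(0, (int)X.n_rows - 1);
  const int K = (int)W.n_rows;
  const double T = (double)iterations;
  for (int t = 0; t < iterations; ++t) {
    arma::rowvec x = X.row(pick(rng));
    int best = 0;
    double bestd = arma::datum::inf;
    for (int k = 0; k < K; ++k) {
      double d = arma::accu(arma::square(W.row(k) - x));
      if (d < bestd) { bestd = d; best = k; }
    }
    double lr = lr0 / (1.0 + (double)t / (T / 2.0));
    double radius = radius0 - (radius0 - 1.0) * ((double)t / T);
    double r2 = radius * radius;
    for (int k = 0; k < K; ++k) {
      double dg = arma::accu(arma::square(coords.row(k) - coords.row(best)));
      if (dg <= r2) W.row(k) += lr * (x - W.row(k));
    }
  }
  return W;
}
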
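#include <Rcpp.h>
using namespace Rcpp;

// Numerically safe logistic: never overflows for large |z|.
static inline double sigmoid(double z) {
  if (z >= 0.0) {
    return 1.0 / (1.0 + std::exp(-z));
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

// Per-pattern (stochastic) delta-rule training of a single logistic unit.
//
// pat_idx: 0-based configuration index of each training row (length n)
// patterns: 16 x 4 matrix of cue indicators, enumeration order
// targets: 0/1 reward targets per row
// w0/bias0: initial weights (length 4) and bias
// cross_entropy: TRUE -> delta = (t - a), the Bernoulli log-likelihood
//   gradient; FALSE -> squared-error delta = (t - a) a (1 - a)
// record_epochs: 1-based epochs after which the 16 responses are stored
//
// Presentation order is re-randomized every epoch by a Fisher-Yates
// shuffle driven by R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".train_sgd")]]
List train_sgd(IntegerVector pat_idx, NumericMatrix patterns,
               IntegerVector targets, NumericVector w0, double bias0,
               double eta, int epochs, bool cross_entropy,
               IntegerVector record_epochs) {
  const int n = pat_idx.size();
  if (targets.size() != n) stop("targets and pat_idx differ in length");
  const int npat = patterns.nrow(), ncue = patterns.ncol();
  if (w0.size() != ncue) stop("w0 length must match pattern columns");

  std::vector<double> w(w0.begin(), w0.end());
  double bias = bias0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<bool> record(epochs + 1, false);
  for (int k = 0; k < record_epochs.size(); ++k) {
    int e = record_epochs[k];
    if (e < 1 || e > epochs) stop("record_epochs outside [1, epochs]");
    record[e] = true;
  }
  NumericMatrix traj(record_epochs.size(), npat);
  int traj_row = 0;

  RNGScope scope;
  for (int epoch = 1; epoch <= epochs; ++epoch) {
    // Fisher-Yates shuffle of the presentation order
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;  // guard against unif_rand() == 1.0
      std::swap(order[i], order[j]);
    }
    for (int r = 0; r < n; ++r) {
      const int row = order[r];
      const int p = pat_idx[row];
      double net = bias;
      for (int c = 0; c < ncue; ++c) net += w[c] * patterns(p, c);
      const double a = sigmoid(net);
      double delta = targets[row] - a;
      if (!cross_entropy) delta *= a * (1.0 - a);
      const double step = eta * delta;
      for (int c = 0; c < ncue; ++c) w[c] += step * patterns(p, c);
      bias += step;
      if (!std::isfinite(bias) || !std::isfinite(w[0]) ||
          !std::isfinite(w[1]) || !std::isfinite(w[2]) ||
          !std::isfinite(w[3])) {
        stop("weights diverged (non-finite) at epoch %d, row %d",
             epoch, row + 1);
      }
    }
    if (record[epoch]) {
      for (int p = 0; p < npat; ++p) {
        double net = bias;
        for (int c = 0; c < ncue; ++c) net += w[c] * patterns(p, c);
        traj(traj_row, p) = sigmoid(net);
      }
      ++traj_row;
    }
  }
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["bias"] = bias, _["trajectory"] = traj);
}
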
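#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Online Kohonen / counterpropagation training loop.
//
// Neurons are indexed row-major: k = row * width + col, so index order equals
// lexicographic (row, col) order and the strict "<" winner comparison yields
// the documented tie-break (smallest (row, col)).
//
// X   : n x d input matrix
// W   : d x K codebook (copied, updated, returned)
// O   : m x K output look-up layer (m == 0 for a plain SOM)
// Y   : n x m supervised targets (one-hot blocks per task)
// ord : epochs x n presentation order, 0-based (RNG stays on the R side)
//
// Learning rate decays linearly lr0 -> lr1 over epochs; the Gaussian
// neighbourhood radius decays linearly radius0 -> 0. Both the codebook and
// the output layer move toward the presented object / target with the same
// rate * neighbourhood factor, which keeps output entries inside [0, 1]
// when initialised there.
// [[Rcpp::export]]
List kohonen_train_cpp(NumericMatrix X, NumericMatrix W, NumericMatrix O,
                       NumericMatrix Y, IntegerMatrix ord,
                       int width, int height,
                       double lr0, double lr1, double radius0, bool toroidal) {
  const int n = X.nrow(), d = X.ncol(), K = W.ncol(), m = O.nrow();
  const int epochs = ord.nrow();
  NumericMatrix Wc = clone(W), Oc = clone(O);

  for (int e = 0; e < epochs; ++e) {
    double frac = (epochs == 1) ? 1.0 : (double)e / (epochs - 1);
    double lr = lr0 + (lr1 - lr0) * frac;
    double sigma = radius0 * (1.0 - frac);
    for (int t = 0; t < n; ++t) {
      int i = ord(e, t);
      // winner: minimal squared Euclidean distance, first index on ties
      int win = 0;
      double best = R_PosInf;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < d; ++j) {
          double diff = X(i, j) - Wc(j, k);
          s += diff * diff;
        }
        if (s < best) { best = s; win = k; }
      }
      int wr = win / width, wc = win % width;
      for (int k = 0; k < K; ++k) {
        int kr = k / width, kc = k % width;
        double dr = std::abs(kr - wr), dc = std::abs(kc - wc);
        if (toroidal) {
          dr = std::min(dr, height - dr);
          dc = std::min(dc, width - dc);
        }
        double d2 = dr * dr + dc * dc;
        double h;
        if (sigma > 1e-12) {
          h = std::exp(-d2 / (2.0 * sigma * sigma));
          if (h < 1e-12) continue;
        } else {
          if (d2 > 0) continue;
          h = 1.0;
        }
        double step = lr * h;
        for (int j = 0; j < d; ++j)
          Wc(j, k) += step * (X(i, j) - Wc(j, k));
        for (int j = 0; j < m; ++j)
          Oc(j, k) += step * (Y(i, j) - Oc(j, k));
      }
    }
  }
  return List::create(_["weights"] = Wc, _["output"] = Oc);
}
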
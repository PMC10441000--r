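// Skip-gram negative-sampling trainer for node embeddings.
// Sequential SGD over unique corpus pairs with (pre-damped) multiplicity
// weights, k negatives per positive drawn from a precomputed unigram
// table, and linearly decaying learning rate.  Embeddings are passed
// transposed (dim x nodes) so each node's vector is contiguous.
// Deterministic given the seed; Zt is modified in place.
#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
NumericVector cpp_sgns(NumericMatrix Zt, IntegerVector pu, IntegerVector pv,
                       NumericVector pw, IntegerVector neg_table, int k,
                       double lr, int epochs, int seed) {
  int n_pairs = pu.size(), d = Zt.nrow();
  int tab = neg_table.size();
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_int_distribution<int> pick_neg(0, tab - 1);
  std::vector<int> order(n_pairs);
  for (int i = 0; i < n_pairs; ++i) order[i] = i;
  NumericVector losses(epochs);
  double wtot = 0.0;
  for (int i = 0; i < n_pairs; ++i) wtot += pw[i];
  double *Z = REAL(Zt);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double step = lr * (1.0 - (double)ep / epochs);
    if (step < lr * 0.05) step = lr * 0.05;
    double loss = 0.0;
    for (int ii = 0; ii < n_pairs; ++ii) {
      int i = order[ii];
      double *zu = Z + (size_t)(pu[i] - 1) * d;
      double *zv = Z + (size_t)(pv[i] - 1) * d;
      double w = pw[i];
      double s = 0.0;
      for (int j = 0; j < d; ++j) s += zu[j] * zv[j];
      double p = sigmoid(s);
      loss += -w * std::log(p > 1e-12 ? p : 1e-12);
      double g = w * (1.0 - p) * step;
      for (int j = 0; j < d; ++j) {
        double zuj = zu[j];
        zu[j] += g * zv[j];
        zv[j] += g * zuj;
      }
      for (int c = 0; c < k; ++c) {
        int vn = neg_table[pick_neg(rng)] - 1;
        if (vn == pu[i] - 1) continue;
        double *zn = Z + (size_t)vn * d;
        double sn = 0.0;
        for (int j = 0; j < d; ++j) sn += zu[j] * zn[j];
        double pn = sigmoid(-sn);
        loss += -w * std::log(pn > 1e-12 ? pn : 1e-12);
        double gn = -w * (1.0 - pn) * step;
        for (int j = 0; j < d; ++j) {
          double zuj = zu[j];
          zu[j] += gn * zn[j];
          zn[j] += gn * zuj;
        }
      }
    }
    losses[ep] = loss / wtot;
  }
  return losses;
}
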
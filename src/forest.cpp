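// Compact random-forest classifier: bootstrap-bagged CART trees with Gini
// splits and per-node feature subsampling.  Probabilities are the mean of
// per-tree leaf class frequencies.  Deterministic given the seed.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Tree {
  std::vector<int> feature;            // -1 for leaf
  std::vector<double> thresh;
  std::vector<int> left, right;
  std::vector<std::vector<double>> prob;  // per-node class distribution
};

static double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += (c / n) * (c / n);
  return 1.0 - s;
}

static int grow_node(Tree& tr, const NumericMatrix& X, const IntegerVector& y,
                     int nclass, std::vector<int>& idx, int lo, int hi,
                     int depth, int max_depth, int min_node, int mtry,
                     std::mt19937& rng) {
  int n = hi - lo;
  std::vector<double> cnt(nclass, 0.0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]] += 1.0;
  int node = tr.feature.size();
  tr.feature.push_back(-1);
  tr.thresh.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  std::vector<double> p(nclass);
  for (int c = 0; c < nclass; ++c) p[c] = cnt[c] / n;
  tr.prob.push_back(p);

  double node_gini = gini_from_counts(cnt, n);
  if (n < 2 * min_node || depth >= max_depth || node_gini <= 0.0)
    return node;

  // candidate features: first mtry of a seeded shuffle
  int nfeat = X.ncol();
  std::vector<int> feats(nfeat);
  for (int f = 0; f < nfeat; ++f) feats[f] = f;
  std::shuffle(feats.begin(), feats.end(), rng);

  double best_imp = node_gini;  // must strictly improve
  int best_f = -1;
  double best_t = 0.0;
  std::vector<std::pair<double,int>> vals(n);
  for (int fi = 0; fi < mtry && fi < nfeat; ++fi) {
    int f = feats[fi];
    for (int i = 0; i < n; ++i)
      vals[i] = {X(idx[lo + i], f), y[idx[lo + i]]};
    std::sort(vals.begin(), vals.end());
    std::vector<double> lc(nclass, 0.0), rc(cnt);
    for (int i = 1; i < n; ++i) {
      int cls = vals[i - 1].second;
      lc[cls] += 1.0; rc[cls] -= 1.0;
      if (vals[i].first == vals[i - 1].first) continue;
      if (i < min_node || n - i < min_node) continue;
      double imp = (gini_from_counts(lc, i) * i +
                    gini_from_counts(rc, n - i) * (n - i)) / n;
      if (imp < best_imp - 1e-12) {
        best_imp = imp;
        best_f = f;
        best_t = 0.5 * (vals[i - 1].first + vals[i].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo:hi) on the chosen split
  std::vector<int> lidx, ridx;
  for (int i = lo; i < hi; ++i)
    (X(idx[i], best_f) <= best_t ? lidx : ridx).push_back(idx[i]);
  if (lidx.empty() || ridx.empty()) return node;
  std::copy(lidx.begin(), lidx.end(), idx.begin() + lo);
  std::copy(ridx.begin(), ridx.end(), idx.begin() + lo + lidx.size());

  tr.feature[node] = best_f;
  tr.thresh[node] = best_t;
  int mid = lo + lidx.size();
  int l = grow_node(tr, X, y, nclass, idx, lo, mid, depth + 1, max_depth,
                    min_node, mtry, rng);
  tr.left[node] = l;
  int r = grow_node(tr, X, y, nclass, idx, mid, hi, depth + 1, max_depth,
                    min_node, mtry, rng);
  tr.right[node] = r;
  return node;
}

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                     int mtry, int max_depth, int min_node, int seed) {
  int n = X.nrow();
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::mt19937 rng(static_cast<uint32_t>(seed) * 2654435761u + t);
    std::uniform_int_distribution<int> pick(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);  // bootstrap
    Tree tr;
    grow_node(tr, X, y, nclass, idx, 0, n, 0, max_depth, min_node, mtry, rng);
    int nn = tr.feature.size();
    NumericMatrix pm(nn, nclass);
    for (int i = 0; i < nn; ++i)
      for (int c = 0; c < nclass; ++c) pm(i, c) = tr.prob[i][c];
    forest[t] = List::create(
        _["feature"] = IntegerVector(tr.feature.begin(), tr.feature.end()),
        _["thresh"] = NumericVector(tr.thresh.begin(), tr.thresh.end()),
        _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
        _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
        _["prob"] = pm);
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_forest(List forest, NumericMatrix X, int nclass) {
  int n = X.nrow(), ntree = forest.size();
  NumericMatrix out(n, nclass);
  for (int t = 0; t < ntree; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"];
    NumericVector thresh = tr["thresh"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericMatrix prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= thresh[node]) ? left[node] : right[node];
      for (int c = 0; c < nclass; ++c) out(i, c) += prob(node, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nclass; ++c) out(i, c) /= ntree;
  return out;
}
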
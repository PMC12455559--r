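#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bagged CART classifier: B bootstrap trees, Gini splits over a random
// feature subset per node, probability = fraction of trees voting "active".
// Uses R's RNG so set.seed() governs reproducibility.
// Tree serialization: one matrix per tree, columns
//   feature (1-based, 0 = leaf) | threshold | left | right | leaf_prob

struct Node {
  int feature;  // 0 for leaf
  double thresh, prob;
  int left, right;
};

static void grow(const NumericMatrix& X, const IntegerVector& y,
                 std::vector<int>& idx, int lo, int hi, int depth,
                 int max_depth, int min_node, int mtry,
                 std::vector<Node>& nodes, int me) {
  int n = hi - lo;
  int pos = 0;
  for (int t = lo; t < hi; ++t) pos += y[idx[t]];
  double prob = (double)pos / n;
  nodes[me].prob = prob;
  nodes[me].feature = 0;
  nodes[me].left = nodes[me].right = -1;
  if (depth >= max_depth || n < 2 * min_node || pos == 0 || pos == n) return;

  int p = X.ncol();
  // sample mtry distinct features (partial Fisher-Yates over 0..p-1)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry; ++j) {
    int r = j + (int)std::floor(unif_rand() * (p - j));
    if (r >= p) r = p - 1;
    std::swap(feats[j], feats[r]);
  }

  double base = 1.0 - prob * prob - (1.0 - prob) * (1.0 - prob);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_t = 0.0;
  std::vector<std::pair<double, int>> vals(n);
  for (int jj = 0; jj < mtry; ++jj) {
    int f = feats[jj];
    for (int t = 0; t < n; ++t) {
      int i = idx[lo + t];
      vals[t] = std::make_pair(X(i, f), y[i]);
    }
    std::sort(vals.begin(), vals.end());
    int lpos = 0;
    for (int t = 0; t < n - 1; ++t) {
      lpos += vals[t].second;
      if (vals[t + 1].first <= vals[t].first) continue;  // no cut between ties
      int nl = t + 1, nr = n - nl;
      double pl = (double)lpos / nl, pr = (double)(pos - lpos) / nr;
      double gini = (nl * (2.0 * pl * (1.0 - pl)) +
                     nr * (2.0 * pr * (1.0 - pr))) / n;
      double gain = base - gini;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_t = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  if (best_f < 0) return;
  // partition idx[lo:hi) by the chosen split
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_f) <= best_t) std::swap(idx[mid++], idx[t]);
  if (mid == lo || mid == hi) return;
  nodes[me].feature = best_f + 1;
  nodes[me].thresh = best_t;
  nodes[me].left = (int)nodes.size();
  nodes.push_back(Node());
  grow(X, y, idx, lo, mid, depth + 1, max_depth, min_node, mtry, nodes,
       nodes[me].left);
  nodes[me].right = (int)nodes.size();
  nodes.push_back(Node());
  grow(X, y, idx, mid, hi, depth + 1, max_depth, min_node, mtry, nodes,
       nodes[me].right);
}

// [[Rcpp::export(name = ".forest_fit_cpp")]]
List forest_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                    int max_depth, int min_node) {
  RNGScope scope;
  int n = X.nrow();
  List trees(ntree);
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int r = (int)std::floor(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[i] = r;
    }
    std::vector<Node> nodes;
    nodes.push_back(Node());
    grow(X, y, idx, 0, n, 0, max_depth, min_node, mtry, nodes, 0);
    NumericMatrix tm(nodes.size(), 5);
    for (size_t k = 0; k < nodes.size(); ++k) {
      tm(k, 0) = nodes[k].feature;
      tm(k, 1) = nodes[k].feature ? nodes[k].thresh : 0.0;
      tm(k, 2) = nodes[k].left + 1;   // 1-based, 0 = none
      tm(k, 3) = nodes[k].right + 1;
      tm(k, 4) = nodes[k].prob;
    }
    trees[b] = tm;
  }
  return trees;
}

// [[Rcpp::export(name = ".forest_predict_cpp")]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    NumericMatrix tm = trees[b];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)tm(node, 0) != 0) {
        int f = (int)tm(node, 0) - 1;
        node = (X(i, f) <= tm(node, 1)) ? (int)tm(node, 2) - 1
                                        : (int)tm(node, 3) - 1;
      }
      out[i] += (tm(node, 4) >= 0.5) ? 1.0 : 0.0;  // vote of this tree
    }
  }
  return out / (double)B;
}
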
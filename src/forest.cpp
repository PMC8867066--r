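// Regression random forest: CART trees on bootstrap samples with feature
// subsampling, out-of-bag predictions and OOB permutation importance.
// Uses R's RNG throughout so results are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // child node ids
  double value;     // mean response of node samples
  int n;            // training samples reaching the node
};

struct Tree {
  std::vector<Node> nodes;
};

int ru_int(int n) {  // uniform integer in [0, n)
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// grow one node recursively; idx holds sample indices for this node
int grow(const NumericMatrix& X, const NumericVector& y,
         std::vector<int>& idx, int lo, int hi, int mtry, int min_node,
         int max_depth, int depth, Tree& tree) {
  int n = hi - lo;
  double sum = 0.0;
  for (int i = lo; i < hi; ++i) sum += y[idx[i]];
  double mean = sum / n;

  Node node;
  node.feature = -1; node.threshold = 0.0;
  node.left = node.right = -1; node.value = mean; node.n = n;

  bool stop_split = n < 2 * min_node || depth >= max_depth;
  if (!stop_split) {
    double sse = 0.0;
    for (int i = lo; i < hi; ++i) { double d = y[idx[i]] - mean; sse += d * d; }
    if (sse < 1e-12) stop_split = true;
  }
  int self = (int)tree.nodes.size();
  tree.nodes.push_back(node);
  if (stop_split) return self;

  int p = X.ncol();
  // sample mtry features without replacement (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) std::swap(feats[j], feats[j + ru_int(p - j)]);

  double best_gain = 0.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  double total_sum = sum;

  for (int jj = 0; jj < m; ++jj) {
    int f = feats[jj];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double lsum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += y[ord[i]];
      int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      if (X(ord[i + 1], f) <= X(ord[i], f) + 1e-12) continue;  // tied values
      double rsum = total_sum - lsum;
      double gain = lsum * lsum / nl + rsum * rsum / nr - total_sum * total_sum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain; best_f = f;
        best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
      }
    }
  }
  if (best_f < 0) return self;

  // partition idx[lo:hi) by the chosen split (stable)
  std::vector<int> left_v, right_v;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr) left_v.push_back(idx[i]);
    else right_v.push_back(idx[i]);
  }
  std::copy(left_v.begin(), left_v.end(), idx.begin() + lo);
  std::copy(right_v.begin(), right_v.end(), idx.begin() + lo + left_v.size());
  int mid = lo + (int)left_v.size();

  int l = grow(X, y, idx, lo, mid, mtry, min_node, max_depth, depth + 1, tree);
  int r = grow(X, y, idx, mid, hi, mtry, min_node, max_depth, depth + 1, tree);
  tree.nodes[self].feature = best_f;
  tree.nodes[self].threshold = best_thr;
  tree.nodes[self].left = l;
  tree.nodes[self].right = r;
  return self;
}

double predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0) {
    cur = X(row, tree.nodes[cur].feature) <= tree.nodes[cur].threshold
            ? tree.nodes[cur].left : tree.nodes[cur].right;
  }
  return tree.nodes[cur].value;
}

NumericMatrix tree_to_matrix(const Tree& tree) {
  int n = (int)tree.nodes.size();
  NumericMatrix m(n, 6);
  for (int i = 0; i < n; ++i) {
    const Node& nd = tree.nodes[i];
    m(i, 0) = nd.feature + 1;  // 1-based, 0 = leaf
    m(i, 1) = nd.threshold;
    m(i, 2) = nd.left + 1;     // 1-based, 0 = none
    m(i, 3) = nd.right + 1;
    m(i, 4) = nd.value;
    m(i, 5) = nd.n;
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "value", "n");
  return m;
}

}  // namespace

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node, int max_depth, bool importance) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol();
  List trees(ntree);
  List inbag_list(ntree);
  NumericVector oob_pred(n, 0.0);
  IntegerVector oob_count(n, 0);
  NumericMatrix imp_raw(ntree, p);
  std::vector<Tree> forest(ntree);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> counts(n, 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) { idx[i] = ru_int(n); counts[idx[i]]++; }
    grow(X, y, idx, 0, n, mtry, min_node, max_depth, 0, forest[t]);
    trees[t] = tree_to_matrix(forest[t]);
    IntegerVector inbag(n);
    for (int i = 0; i < n; ++i) inbag[i] = counts[i];
    inbag_list[t] = inbag;

    // OOB predictions
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) {
      if (counts[i] == 0) {
        double pr = predict_tree(forest[t], X, i);
        oob_pred[i] += pr; oob_count[i]++;
        oob.push_back(i);
      }
    }

    if (importance && !oob.empty()) {
      int no = (int)oob.size();
      double base_mse = 0.0;
      std::vector<double> base_pred(no);
      for (int k = 0; k < no; ++k) {
        base_pred[k] = predict_tree(forest[t], X, oob[k]);
        double d = base_pred[k] - y[oob[k]];
        base_mse += d * d;
      }
      base_mse /= no;
      NumericMatrix Xperm(no, p);
      for (int k = 0; k < no; ++k)
        for (int j = 0; j < p; ++j) Xperm(k, j) = X(oob[k], j);
      for (int j = 0; j < p; ++j) {
        // permute column j among OOB rows
        std::vector<double> col(no);
        for (int k = 0; k < no; ++k) col[k] = Xperm(k, j);
        for (int k = no - 1; k > 0; --k)
          std::swap(col[k], col[ru_int(k + 1)]);
        std::vector<double> saved(no);
        for (int k = 0; k < no; ++k) { saved[k] = Xperm(k, j); Xperm(k, j) = col[k]; }
        double mse = 0.0;
        for (int k = 0; k < no; ++k) {
          double d = predict_tree(forest[t], Xperm, k) - y[oob[k]];
          mse += d * d;
        }
        mse /= no;
        imp_raw(t, j) = mse - base_mse;
        for (int k = 0; k < no; ++k) Xperm(k, j) = saved[k];
      }
    }
  }

  NumericVector oob(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_count[i] > 0) oob[i] = oob_pred[i] / oob_count[i];

  NumericVector imp(p, 0.0);
  if (importance) {
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int t = 0; t < ntree; ++t) s += imp_raw(t, j);
      imp[j] = s / ntree;
    }
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag_list,
                      _["oob_prediction"] = oob, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List trees, NumericMatrix X) {
  int ntree = trees.size(), n = X.nrow();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix m = trees[t];
    for (int i = 0; i < n; ++i) {
      int cur = 0;
      while ((int)m(cur, 0) != 0) {
        int f = (int)m(cur, 0) - 1;
        cur = X(i, f) <= m(cur, 1) ? (int)m(cur, 2) - 1 : (int)m(cur, 3) - 1;
      }
      out[i] += m(cur, 4);
    }
  }
  return out / ntree;
}
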
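#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Compact regression forest with per-prediction contribution decomposition.
// Each tree is CART with variance-reduction splits, grown on a bootstrap
// sample with `mtry` candidate features per split. Trees are stored flat so
// the decomposition can walk decision paths: for a sample routed through a
// split on feature j, the change in node mean (child - parent) is credited to
// j; summing credits along the path gives prediction = root_mean + sum(contrib)
// exactly, per tree.

struct TreeNode {
  int split_var;      // -1 for leaf
  double split_val;   // go left if x <= split_val
  int left, right;    // child indices, -1 for leaf
  double node_mean;   // mean of training responses reaching the node
};

struct Tree {
  std::vector<TreeNode> nodes;
};

static int rand_int(int n) {
  // uniform on 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, min_node, max_depth;
  std::vector<TreeNode> nodes;

  Builder(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
          int min_node_, int max_depth_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_) {}

  // build node over idx[lo, hi), return node index
  int build(std::vector<int>& idx, int lo, int hi, int depth) {
    int n = hi - lo;
    double sum = 0.0, sum2 = 0.0;
    for (int i = lo; i < hi; ++i) {
      sum += y[idx[i]];
      sum2 += y[idx[i]] * y[idx[i]];
    }
    double mean = sum / n;
    double sse = sum2 - sum * sum / n;

    int me = (int)nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, mean});

    if (n < 2 * min_node || sse <= 1e-12 ||
        (max_depth > 0 && depth >= max_depth))
      return me;

    int p = X.ncol();
    // sample mtry features without replacement (partial Fisher-Yates)
    std::vector<int> feat(p);
    for (int j = 0; j < p; ++j) feat[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) std::swap(feat[j], feat[j + rand_int(p - j)]);

    double best_gain = 0.0, best_val = 0.0;
    int best_var = -1;
    std::vector<std::pair<double, double>> xv(n);  // (x, y)
    for (int f = 0; f < m; ++f) {
      int j = feat[f];
      for (int i = 0; i < n; ++i)
        xv[i] = {X(idx[lo + i], j), y[idx[lo + i]]};
      std::sort(xv.begin(), xv.end());
      double lsum = 0.0, lsum2 = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += xv[i].second;
        lsum2 += xv[i].second * xv[i].second;
        if (xv[i + 1].first <= xv[i].first) continue;  // no distinct cut here
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double rsum = sum - lsum, rsum2 = sum2 - lsum2;
        double sse_l = lsum2 - lsum * lsum / nl;
        double sse_r = rsum2 - rsum * rsum / nr;
        double gain = sse - sse_l - sse_r;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_var = j;
          best_val = 0.5 * (xv[i].first + xv[i + 1].first);
        }
      }
    }
    if (best_var < 0) return me;

    // partition idx in place
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_var) <= best_val) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return me;  // degenerate (shouldn't happen)

    nodes[me].split_var = best_var;
    nodes[me].split_val = best_val;
    int l = build(idx, lo, mid, depth + 1);
    int r = build(idx, mid, hi, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

// [[Rcpp::export]]
List forest_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                    int min_node, int max_depth, bool bootstrap) {
  int n = X.nrow();
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = rand_int(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    Builder b(X, y, mtry, min_node, max_depth);
    b.build(idx, 0, n, 0);
    int nn = (int)b.nodes.size();
    IntegerVector sv(nn), lf(nn), rt(nn);
    NumericVector spv(nn), nm(nn);
    for (int i = 0; i < nn; ++i) {
      sv[i] = b.nodes[i].split_var;
      spv[i] = b.nodes[i].split_val;
      lf[i] = b.nodes[i].left;
      rt[i] = b.nodes[i].right;
      nm[i] = b.nodes[i].node_mean;
    }
    forest[t] = List::create(_["split_var"] = sv, _["split_val"] = spv,
                             _["left"] = lf, _["right"] = rt,
                             _["node_mean"] = nm);
  }
  return forest;
}

// [[Rcpp::export]]
List forest_contrib_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol(), T = forest.size();
  NumericMatrix contrib(n, p);
  NumericVector pred(n);
  double root = 0.0;
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector sv = tr["split_var"], lf = tr["left"], rt = tr["right"];
    NumericVector spv = tr["split_val"], nm = tr["node_mean"];
    root += nm[0];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      double cur = nm[0];
      while (sv[node] >= 0) {
        int nxt = X(i, sv[node]) <= spv[node] ? lf[node] : rt[node];
        contrib(i, sv[node]) += nm[nxt] - cur;
        cur = nm[nxt];
        node = nxt;
      }
      pred[i] += cur;
    }
  }
  for (int i = 0; i < n; ++i) pred[i] /= T;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) contrib(i, j) /= T;
  return List::create(_["prediction"] = pred, _["contribution"] = contrib,
                      _["root_value"] = root / T);
}
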
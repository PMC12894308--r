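// Regression random forest with CART variance-reduction splits.
//
// Bootstrap per tree (R's RNG, so set.seed() on the R side makes the whole
// forest reproducible), mtry random candidate predictors per node, split at
// the midpoint between consecutive distinct values maximizing
// SS(parent) - SS(left) - SS(right). Importance is the total SS decrease
// credited to each predictor, averaged over trees ("increase in node
// purity"); out-of-bag predictions accumulate per sample for OOB R^2.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int var = -1;        // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double pred = 0.0;
};

struct TreeBuilder {
  const NumericMatrix& x;
  const NumericVector& y;
  int mtry, nodesize;
  std::vector<Node> nodes;
  std::vector<double>& importance;   // shared accumulator for this tree
  std::vector<int> cand;             // scratch: candidate variable ids

  TreeBuilder(const NumericMatrix& x_, const NumericVector& y_, int mtry_,
              int nodesize_, std::vector<double>& imp)
      : x(x_), y(y_), mtry(mtry_), nodesize(nodesize_), importance(imp) {}

  static double node_ss(const std::vector<int>& idx, const NumericVector& y) {
    double s = 0.0, s2 = 0.0;
    for (int i : idx) { s += y[i]; s2 += y[i] * y[i]; }
    return s2 - s * s / idx.size();
  }

  int build(std::vector<int>& idx) {
    int me = (int)nodes.size();
    nodes.push_back(Node());
    double s = 0.0;
    for (int i : idx) s += y[i];
    nodes[me].pred = s / idx.size();

    int n = (int)idx.size();
    if (n <= nodesize) return me;
    double parent_ss = node_ss(idx, y);
    if (parent_ss <= 1e-12) return me;

    // draw mtry candidate variables without replacement (partial F-Y)
    int p = x.ncol();
    cand.resize(p);
    for (int j = 0; j < p; ++j) cand[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(cand[j], cand[k]);
    }

    int best_var = -1;
    double best_dec = 0.0, best_thr = 0.0;
    std::vector<int> ord;
    for (int jj = 0; jj < m; ++jj) {
      int v = cand[jj];
      ord = idx;
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return x(a, v) < x(b, v);
      });
      double ls = 0.0, ls2 = 0.0;
      double total_s = 0.0, total_s2 = 0.0;
      for (int i : ord) { total_s += y[i]; total_s2 += y[i] * y[i]; }
      for (int c = 0; c < n - 1; ++c) {
        double yi = y[ord[c]];
        ls += yi; ls2 += yi * yi;
        if (x(ord[c + 1], v) <= x(ord[c], v)) continue;  // not a cut
        int nl = c + 1, nr = n - nl;
        double rs = total_s - ls, rs2 = total_s2 - ls2;
        double child_ss = (ls2 - ls * ls / nl) + (rs2 - rs * rs / nr);
        double dec = parent_ss - child_ss;
        if (dec > best_dec) {
          best_dec = dec;
          best_var = v;
          best_thr = 0.5 * (x(ord[c], v) + x(ord[c + 1], v));
        }
      }
    }
    if (best_var < 0) return me;

    importance[best_var] += best_dec;
    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    for (int i : idx) {
      if (x(i, best_var) <= best_thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    nodes[me].var = best_var;
    nodes[me].thr = best_thr;
    int l = build(lidx);   // may reallocate `nodes`; index after returning
    int r = build(ridx);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  double predict(int row) const {
    int cur = 0;
    while (nodes[cur].var >= 0)
      cur = (x(row, nodes[cur].var) <= nodes[cur].thr) ? nodes[cur].left
                                                       : nodes[cur].right;
    return nodes[cur].pred;
  }
};

}  // namespace

// [[Rcpp::export]]
List forest_cpp(NumericMatrix x, NumericVector y, int n_trees, int mtry,
                int nodesize) {
  int n = x.nrow(), p = x.ncol();
  std::vector<double> imp_total(p, 0.0);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_count(n, 0);
  std::vector<int> inbag(n);
  std::vector<int> idx;
  idx.reserve(n);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      inbag[k]++;
      idx.push_back(k);
    }
    std::vector<double> imp_tree(p, 0.0);
    TreeBuilder tb(x, y, mtry, nodesize, imp_tree);
    tb.build(idx);
    for (int j = 0; j < p; ++j) imp_total[j] += imp_tree[j];
    for (int i = 0; i < n; ++i) {
      if (inbag[i] == 0) {
        oob_sum[i] += tb.predict(i);
        oob_count[i]++;
      }
    }
  }

  NumericVector importance(p), oob_pred(n);
  IntegerVector oobc(n);
  for (int j = 0; j < p; ++j) importance[j] = imp_total[j] / n_trees;
  for (int i = 0; i < n; ++i) {
    oobc[i] = oob_count[i];
    oob_pred[i] = oob_count[i] > 0 ? oob_sum[i] / oob_count[i] : NA_REAL;
  }
  return List::create(_["importance"] = importance,
                      _["oob_pred"] = oob_pred,
                      _["oob_count"] = oobc);
}
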
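// Histogram-based CART regression trees (multi-output), the shared engine
// behind the random forest, AdaBoost.R2 and gradient tree boosting drivers.
// Features are pre-binned in R (bin codes 0..nb-1 per feature); split search
// scans per-node histograms, so cost per tree level is O(n_node * p).
// With a one-hot multi-output response the variance-reduction criterion
// coincides with the multiclass Gini criterion, so the same engine serves
// classification.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;     // -1 for leaf
  int split_bin = -1;   // go left if bin code <= split_bin
  int left = -1, right = -1;
  std::vector<double> value;  // per-output weighted mean
};

struct Task {
  int node_id;
  int depth;
  std::vector<int> rows;  // indices into samp (i.e., positions of samples)
};

}  // namespace

// xb: n x p integer bin codes (0-based); nb: bins per feature
// Y: n x K response matrix; w: per-row weights; samp: 0-based row indices
// (repeats allowed, e.g. bootstrap). mtry features are tried per node.
// Uses R's RNG for feature subsampling (unif_rand), so results follow
// set.seed() on the R side.
// [[Rcpp::export]]
List cart_fit_cpp(const IntegerMatrix& xb, const IntegerVector& nb,
                  const NumericMatrix& Y, const NumericVector& w,
                  const IntegerVector& samp, int max_depth, int min_leaf,
                  int mtry) {
  const int p = xb.ncol();
  const int K = Y.ncol();
  const int m = samp.size();
  std::vector<Node> nodes;
  NumericVector importance(p);

  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  std::vector<Task> stack;
  {
    Task root;
    root.node_id = 0;
    root.depth = 0;
    root.rows.resize(m);
    for (int i = 0; i < m; ++i) root.rows[i] = i;
    nodes.push_back(Node());
    stack.push_back(std::move(root));
  }

  // scratch histograms
  int max_nb = 0;
  for (int j = 0; j < p; ++j) max_nb = std::max(max_nb, (int)nb[j]);
  std::vector<double> hw(max_nb);
  std::vector<double> hs(max_nb * K);
  std::vector<int> hc(max_nb);

  while (!stack.empty()) {
    Task t = std::move(stack.back());
    stack.pop_back();
    Node& nd_init = nodes[t.node_id];
    const std::vector<int>& rows = t.rows;
    const int mn = rows.size();

    // node totals
    double W = 0.0;
    std::vector<double> S(K, 0.0);
    for (int r : rows) {
      const int i = samp[r];
      const double wi = w[i];
      W += wi;
      for (int k = 0; k < K; ++k) S[k] += wi * Y(i, k);
    }
    nd_init.value.resize(K);
    for (int k = 0; k < K; ++k) nd_init.value[k] = (W > 0) ? S[k] / W : 0.0;

    if (t.depth >= max_depth || mn < 2 * min_leaf || W <= 0.0) continue;

    double parent_score = 0.0;  // sum_k S_k^2 / W
    for (int k = 0; k < K; ++k) parent_score += S[k] * S[k] / W;

    // sample mtry features without replacement (partial Fisher-Yates)
    int ntry = std::min(mtry, p);
    for (int j = 0; j < ntry; ++j) {
      int pick = j + (int)(unif_rand() * (p - j));
      if (pick >= p) pick = p - 1;
      std::swap(feat_pool[j], feat_pool[pick]);
    }

    double best_gain = 0.0;
    int best_feat = -1, best_bin = -1;

    for (int jj = 0; jj < ntry; ++jj) {
      const int j = feat_pool[jj];
      const int nbj = nb[j];
      if (nbj < 2) continue;
      std::fill(hw.begin(), hw.begin() + nbj, 0.0);
      std::fill(hs.begin(), hs.begin() + nbj * K, 0.0);
      std::fill(hc.begin(), hc.begin() + nbj, 0);
      for (int r : rows) {
        const int i = samp[r];
        const int b = xb(i, j);
        const double wi = w[i];
        hw[b] += wi;
        hc[b] += 1;
        for (int k = 0; k < K; ++k) hs[b * K + k] += wi * Y(i, k);
      }
      double WL = 0.0;
      int CL = 0;
      std::vector<double> SL(K, 0.0);
      for (int b = 0; b < nbj - 1; ++b) {
        WL += hw[b];
        CL += hc[b];
        for (int k = 0; k < K; ++k) SL[k] += hs[b * K + k];
        if (CL < min_leaf || mn - CL < min_leaf) continue;
        const double WR = W - WL;
        if (WL <= 0.0 || WR <= 0.0) continue;
        double score = 0.0;
        for (int k = 0; k < K; ++k) {
          const double SR = S[k] - SL[k];
          score += SL[k] * SL[k] / WL + SR * SR / WR;
        }
        const double gain = score - parent_score;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = j;
          best_bin = b;
        }
      }
    }

    if (best_feat < 0) continue;

    importance[best_feat] += best_gain;
    std::vector<int> lrows, rrows;
    lrows.reserve(mn);
    rrows.reserve(mn);
    for (int r : rows) {
      if (xb(samp[r], best_feat) <= best_bin) lrows.push_back(r);
      else rrows.push_back(r);
    }
    const int li = nodes.size();
    nodes.push_back(Node());
    const int ri = nodes.size();
    nodes.push_back(Node());
    Node& nd = nodes[t.node_id];  // re-acquire: vector may have reallocated
    nd.feature = best_feat;
    nd.split_bin = best_bin;
    nd.left = li;
    nd.right = ri;

    Task tl;
    tl.node_id = li;
    tl.depth = t.depth + 1;
    tl.rows = std::move(lrows);
    Task tr;
    tr.node_id = ri;
    tr.depth = t.depth + 1;
    tr.rows = std::move(rrows);
    stack.push_back(std::move(tl));
    stack.push_back(std::move(tr));
  }

  const int nn = nodes.size();
  IntegerVector feature(nn), split_bin(nn), left(nn), right(nn);
  NumericMatrix value(nn, K);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature;
    split_bin[i] = nodes[i].split_bin;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    for (int k = 0; k < K; ++k) value(i, k) = nodes[i].value[k];
  }
  return List::create(_["feature"] = feature, _["split_bin"] = split_bin,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["importance"] = importance);
}

// [[Rcpp::export]]
NumericMatrix cart_predict_cpp(const List& tree, const IntegerMatrix& xb) {
  IntegerVector feature = tree["feature"];
  IntegerVector split_bin = tree["split_bin"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  NumericMatrix value = tree["value"];
  const int n = xb.nrow();
  const int K = value.ncol();
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (xb(i, feature[node]) <= split_bin[node]) ? left[node]
                                                       : right[node];
    }
    for (int k = 0; k < K; ++k) out(i, k) = value(node, k);
  }
  return out;
}
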
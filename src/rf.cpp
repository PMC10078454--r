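// Minimal random forest for classification: bagged CART with gini splits,
// mtry features per node, out-of-bag voting, and gini-based variable
// importance. Uses R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Node {
  int feature = -1;      // -1 => leaf
  double threshold = 0;
  int left = -1, right = -1;
  int pred = 0;
};

static double gini_from_counts(const std::vector<int> &cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : cnt) {
    double p = (double)c / n;
    g -= p * p;
  }
  return g;
}

// [[Rcpp::export]]
List rf_oob_cpp(NumericMatrix X, IntegerVector y, int n_class,
                int n_tree, int mtry, int min_node) {
  const int n = X.nrow(), p = X.ncol();
  IntegerMatrix votes(n, n_class); // OOB votes
  NumericVector importance(p);

  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  for (int t = 0; t < n_tree; ++t) {
    // bootstrap
    std::vector<int> inbag_count(n, 0);
    std::vector<int> sample_idx(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k == n) k = n - 1;
      sample_idx[i] = k;
      inbag_count[k]++;
    }
    std::vector<Node> nodes;
    nodes.reserve(2 * n);
    // stack of (node id, member list)
    std::vector<std::pair<int, std::vector<int>>> stack;
    nodes.push_back(Node());
    stack.push_back({0, sample_idx});

    while (!stack.empty()) {
      auto item = std::move(stack.back());
      stack.pop_back();
      int id = item.first;
      std::vector<int> &members = item.second;
      int m = members.size();
      std::vector<int> cnt(n_class, 0);
      for (int i : members) cnt[y[i]]++;
      int best_class = 0;
      for (int c = 1; c < n_class; ++c)
        if (cnt[c] > cnt[best_class]) best_class = c;
      nodes[id].pred = best_class;
      double node_gini = gini_from_counts(cnt, m);
      if (m <= min_node || node_gini <= 0.0) continue;

      // sample mtry features without replacement
      for (int j = 0; j < mtry; ++j) {
        int k = j + (int)(unif_rand() * (p - j));
        if (k >= p) k = p - 1;
        std::swap(feat_pool[j], feat_pool[k]);
      }

      double best_gain = 1e-12;
      int best_feat = -1;
      double best_thr = 0;
      for (int j = 0; j < mtry; ++j) {
        int f = feat_pool[j];
        std::vector<std::pair<double, int>> vals(m);
        for (int i = 0; i < m; ++i)
          vals[i] = {X(members[i], f), y[members[i]]};
        std::sort(vals.begin(), vals.end());
        if (vals.front().first == vals.back().first) continue;
        std::vector<int> lcnt(n_class, 0);
        int nl = 0;
        for (int i = 0; i + 1 < m; ++i) {
          lcnt[vals[i].second]++;
          nl++;
          if (vals[i].first == vals[i + 1].first) continue;
          std::vector<int> rcnt(n_class);
          for (int c = 0; c < n_class; ++c) rcnt[c] = cnt[c] - lcnt[c];
          int nr = m - nl;
          double gain = node_gini -
            ((double)nl / m) * gini_from_counts(lcnt, nl) -
            ((double)nr / m) * gini_from_counts(rcnt, nr);
          if (gain > best_gain) {
            best_gain = gain;
            best_feat = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
      if (best_feat < 0) continue;
      importance[best_feat] += best_gain * m;

      std::vector<int> lmem, rmem;
      lmem.reserve(m);
      rmem.reserve(m);
      for (int i : members) {
        if (X(i, best_feat) <= best_thr) lmem.push_back(i);
        else rmem.push_back(i);
      }
      if (lmem.empty() || rmem.empty()) continue;
      nodes[id].feature = best_feat;
      nodes[id].threshold = best_thr;
      int lid = nodes.size();
      nodes.push_back(Node());
      int rid = nodes.size();
      nodes.push_back(Node());
      nodes[id].left = lid;
      nodes[id].right = rid;
      stack.push_back({lid, std::move(lmem)});
      stack.push_back({rid, std::move(rmem)});
    }

    // OOB votes
    for (int i = 0; i < n; ++i) {
      if (inbag_count[i] > 0) continue;
      int id = 0;
      while (nodes[id].feature >= 0) {
        id = (X(i, nodes[id].feature) <= nodes[id].threshold)
                 ? nodes[id].left
                 : nodes[id].right;
      }
      votes(i, nodes[id].pred)++;
    }
  }
  return List::create(_["votes"] = votes,
                      _["importance"] = importance / n_tree);
}
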
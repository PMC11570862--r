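// Histogram-based Newton gradient boosting for weighted binary
// classification (log-loss).  Deterministic by construction: quantile
// binning, exact greedy splits, no row/column subsampling, first-found
// tie-breaking.  Sample weights implement scale_pos_weight.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Node {
  int feature = -1;      // split feature (column index), -1 for leaf
  double threshold = 0;  // go left iff x <= threshold
  int left = -1, right = -1;
  double value = 0;      // Newton step * learning_rate at this node
  bool leaf = true;
};

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                 int iterations, int depth, double learning_rate,
                 double lambda, double min_child_hess, int max_bins) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("gbt_fit: need >= 2 rows");
  if (max_bins < 2) max_bins = 2;

  // quantile binning per feature
  std::vector<std::vector<double>> edges(p);
  std::vector<std::vector<int>> bins(p, std::vector<int>(n));
  int nbins_max = 1;
  for (int j = 0; j < p; ++j) {
    std::vector<double> col(n);
    for (int i = 0; i < n; ++i) col[i] = X(i, j);
    std::vector<double> srt = col;
    std::sort(srt.begin(), srt.end());
    std::vector<double>& e = edges[j];
    for (int k = 1; k < max_bins; ++k) {
      double q = srt[(size_t)((double)k * (n - 1) / max_bins)];
      if (e.empty() || q > e.back()) e.push_back(q);
    }
    // drop the top edge if it equals the max (empty right bin)
    while (!e.empty() && e.back() >= srt[n - 1]) e.pop_back();
    for (int i = 0; i < n; ++i) {
      int b = (int)(std::lower_bound(e.begin(), e.end(), col[i]) - e.begin());
      bins[j][i] = b; // bin b means x <= e[b] (or last bin if b == e.size())
    }
    nbins_max = std::max(nbins_max, (int)e.size() + 1);
  }

  double sw1 = 0, sw0 = 0;
  for (int i = 0; i < n; ++i) { if (y[i] > 0.5) sw1 += w[i]; else sw0 += w[i]; }
  double p0 = std::min(std::max(sw1 / (sw1 + sw0), 1e-6), 1.0 - 1e-6);
  const double base = std::log(p0 / (1.0 - p0));

  std::vector<double> margin(n, base), g(n), h(n);
  List trees(iterations);

  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < n; ++i) {
      double pr = sigmoid(margin[i]);
      g[i] = w[i] * (pr - y[i]);
      h[i] = w[i] * pr * (1.0 - pr);
    }
    std::vector<Node> nodes(1);
    {
      double G = 0, H = 0;
      for (int i = 0; i < n; ++i) { G += g[i]; H += h[i]; }
      nodes[0].value = -G / (H + lambda) * learning_rate;
    }
    std::vector<int> row_node(n, 0);
    std::vector<int> frontier(1, 0);

    for (int level = 0; level < depth && !frontier.empty(); ++level) {
      const int nf = (int)frontier.size();
      std::vector<int> slot(nodes.size(), -1);
      for (int s = 0; s < nf; ++s) slot[frontier[s]] = s;
      // histograms: [slot][feature][bin]
      std::vector<double> HG((size_t)nf * p * nbins_max, 0.0);
      std::vector<double> HH((size_t)nf * p * nbins_max, 0.0);
      std::vector<int> HC((size_t)nf * p * nbins_max, 0);
      for (int i = 0; i < n; ++i) {
        int s = row_node[i] < (int)slot.size() ? slot[row_node[i]] : -1;
        if (s < 0) continue;
        size_t off = (size_t)s * p * nbins_max;
        for (int j = 0; j < p; ++j) {
          size_t k = off + (size_t)j * nbins_max + bins[j][i];
          HG[k] += g[i]; HH[k] += h[i]; HC[k] += 1;
        }
      }
      std::vector<int> next_frontier;
      std::vector<int> split_feat(nf, -1), split_bin(nf, -1);
      for (int s = 0; s < nf; ++s) {
        int nd = frontier[s];
        double G = 0, H = 0; int C = 0;
        size_t off = (size_t)s * p * nbins_max;
        for (int b = 0; b <= (int)edges[0].size(); ++b) {
          G += HG[off + b]; H += HH[off + b]; C += HC[off + b];
        }
        double parent_score = G * G / (H + lambda);
        double best_gain = 1e-12;
        for (int j = 0; j < p; ++j) {
          const int ne = (int)edges[j].size();
          double GL = 0, HL = 0; int CL = 0;
          for (int b = 0; b < ne; ++b) {
            size_t k = off + (size_t)j * nbins_max + b;
            GL += HG[k]; HL += HH[k]; CL += HC[k];
            double GR = G - GL, HR = H - HL;
            int CR = C - CL;
            if (CL < 1 || CR < 1) continue;
            if (HL < min_child_hess || HR < min_child_hess) continue;
            double gain = 0.5 * (GL * GL / (HL + lambda) +
                                 GR * GR / (HR + lambda) - parent_score);
            if (gain > best_gain) {
              best_gain = gain; split_feat[s] = j; split_bin[s] = b;
            }
          }
        }
        if (split_feat[s] >= 0) {
          int j = split_feat[s], b = split_bin[s];
          double GL = 0, HL = 0;
          for (int bb = 0; bb <= b; ++bb) {
            size_t k = off + (size_t)j * nbins_max + bb;
            GL += HG[k]; HL += HH[k];
          }
          double GR = G - GL, HR = H - HL;
          Node lft, rgt;
          lft.value = -GL / (HL + lambda) * learning_rate;
          rgt.value = -GR / (HR + lambda) * learning_rate;
          int li = (int)nodes.size(), ri = li + 1;
          nodes.push_back(lft); nodes.push_back(rgt);
          nodes[nd].feature = j;
          nodes[nd].threshold = edges[j][b];
          nodes[nd].left = li; nodes[nd].right = ri;
          nodes[nd].leaf = false;
          if (level + 1 < depth) { next_frontier.push_back(li);
                                   next_frontier.push_back(ri); }
        }
      }
      for (int i = 0; i < n; ++i) {
        int nd = row_node[i];
        if (nd < (int)slot.size() && slot[nd] >= 0 && !nodes[nd].leaf)
          row_node[i] = X(i, nodes[nd].feature) <= nodes[nd].threshold
                        ? nodes[nd].left : nodes[nd].right;
      }
      frontier = next_frontier;
    }
    for (int i = 0; i < n; ++i) margin[i] += nodes[row_node[i]].value;

    const int nn = (int)nodes.size();
    IntegerVector tf(nn), tl(nn), tr(nn);
    NumericVector tt(nn), tv(nn);
    LogicalVector lf(nn);
    for (int k = 0; k < nn; ++k) {
      tf[k] = nodes[k].feature; tt[k] = nodes[k].threshold;
      tl[k] = nodes[k].left; tr[k] = nodes[k].right;
      tv[k] = nodes[k].value; lf[k] = nodes[k].leaf;
    }
    trees[it] = List::create(_["feature"] = tf, _["threshold"] = tt,
                             _["left"] = tl, _["right"] = tr,
                             _["value"] = tv, _["leaf"] = lf);
  }
  return List::create(_["base_score"] = base, _["trees"] = trees,
                      _["n_features"] = p);
}

// [[Rcpp::export(name = ".gbt_margin_cpp")]]
NumericVector gbt_margin_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  double base = as<double>(model["base_score"]);
  List trees = model["trees"];
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    LogicalVector leaf = tr["leaf"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (!leaf[nd])
        nd = X(i, feature[nd]) <= threshold[nd] ? left[nd] : right[nd];
      out[i] += value[nd];
    }
  }
  return out;
}

// Saabas-style per-path attribution: contribution of the split feature at
// each traversed node is value(child) - value(node); column p holds the
// bias (base score plus root values).
// [[Rcpp::export(name = ".gbt_contrib_cpp")]]
NumericMatrix gbt_contrib_cpp(List model, NumericMatrix X) {
  const int n = X.nrow(), p = as<int>(model["n_features"]);
  double base = as<double>(model["base_score"]);
  List trees = model["trees"];
  NumericMatrix out(n, p + 1);
  for (int i = 0; i < n; ++i) out(i, p) = base;
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    LogicalVector leaf = tr["leaf"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      out(i, p) += value[0];
      while (!leaf[nd]) {
        int nxt = X(i, feature[nd]) <= threshold[nd] ? left[nd] : right[nd];
        out(i, feature[nd]) += value[nxt] - value[nd];
        nd = nxt;
      }
    }
  }
  return out;
}
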
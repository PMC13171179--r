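// Path-dependent TreeSHAP (TreeExplainer) for a single decision tree with
// vector-valued leaves. Computes, for one observation, the exact Shapley
// values of the tree's conditional-expectation value function, where the
// expectation over "missing" features follows the training-coverage split
// proportions stored in node_weight.

#include <Rcpp.h>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static inline void extend_path(PathElement *unique_path, int unique_depth,
                               double zero_fraction, double one_fraction,
                               int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; --i) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
                                  (i + 1) / static_cast<double>(unique_depth + 1);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) / static_cast<double>(unique_depth + 1);
  }
}

static inline void unwind_path(PathElement *unique_path, int unique_depth,
                               int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
                               ((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                               (unique_depth - i) /
                               static_cast<double>(unique_depth + 1);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1)) /
                               (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

static inline double unwound_path_sum(const PathElement *unique_path,
                                      int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         ((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight - tmp * zero_fraction *
                         ((unique_depth - i) /
                          static_cast<double>(unique_depth + 1));
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
               ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct TreeData {
  const int *left;
  const int *right;
  const int *feature;
  const double *threshold;
  const double *node_weight;
  const double *leaf_values;  // n_nodes x n_class, column-major
  int n_nodes;
  int n_class;
};

static void tree_shap_recursive(const TreeData &tree, const double *x,
                                double *phi, int n_features, int node,
                                int unique_depth, PathElement *parent_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *unique_path = parent_path + unique_depth + 1;
  for (int i = 0; i < unique_depth; ++i) unique_path[i] = parent_path[i];
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (tree.left[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      const double scale = w * (el.one_fraction - el.zero_fraction);
      for (int c = 0; c < tree.n_class; ++c) {
        phi[el.feature_index + c * n_features] +=
            scale * tree.leaf_values[node + c * tree.n_nodes];
      }
    }
    return;
  }

  const int split = tree.feature[node];
  const int left = tree.left[node];
  const int right = tree.right[node];
  const int hot = (x[split] <= tree.threshold[node]) ? left : right;
  const int cold = (hot == left) ? right : left;
  const double w = tree.node_weight[node];
  const double hot_zero_fraction = tree.node_weight[hot] / w;
  const double cold_zero_fraction = tree.node_weight[cold] / w;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == split) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, x, phi, n_features, hot, unique_depth + 1,
                      unique_path, hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split);
  tree_shap_recursive(tree, x, phi, n_features, cold, unique_depth + 1,
                      unique_path, cold_zero_fraction * incoming_zero_fraction,
                      0.0, split);
}

static int max_depth(const int *left, const int *right, int node) {
  if (left[node] < 0) return 1;
  int dl = max_depth(left, right, left[node]);
  int dr = max_depth(left, right, right[node]);
  return 1 + (dl > dr ? dl : dr);
}

// [[Rcpp::export]]
NumericVector tree_shap_cpp(IntegerVector left, IntegerVector right,
                            IntegerVector feature, NumericVector threshold,
                            NumericVector node_weight,
                            NumericMatrix leaf_values, NumericMatrix x) {
  const int n_nodes = left.size();
  const int n_class = leaf_values.ncol();
  const int n_samples = x.nrow();
  const int n_features = x.ncol();
  TreeData tree{left.begin(), right.begin(), feature.begin(),
                threshold.begin(), node_weight.begin(), leaf_values.begin(),
                n_nodes, n_class};

  const int maxd = max_depth(left.begin(), right.begin(), 0) + 2;
  std::vector<PathElement> path_workspace((maxd * (maxd + 1)) / 2);
  std::vector<double> xrow(n_features);
  std::vector<double> phi(n_features * n_class);

  NumericVector out(static_cast<R_xlen_t>(n_samples) * n_features * n_class);
  out.attr("dim") = IntegerVector::create(n_samples, n_features, n_class);

  for (int s = 0; s < n_samples; ++s) {
    for (int f = 0; f < n_features; ++f) xrow[f] = x(s, f);
    std::fill(phi.begin(), phi.end(), 0.0);
    tree_shap_recursive(tree, xrow.data(), phi.data(), n_features, 0, 0,
                        path_workspace.data(), 1.0, 1.0, -1);
    for (int c = 0; c < n_class; ++c) {
      for (int f = 0; f < n_features; ++f) {
        out[s + static_cast<R_xlen_t>(f) * n_samples +
            static_cast<R_xlen_t>(c) * n_samples * n_features] =
            phi[f + c * n_features];
      }
    }
  }
  return out;
}
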
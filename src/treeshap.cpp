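// Exact path-dependent Shapley attributions for binary regression trees,
// in double precision. Trees arrive flattened: per node a feature index
// (-1 for a leaf), a split threshold ("go left when x < threshold"),
// left/right child indices (-1 for none), the training cover (row count)
// of the node, and the leaf value. The recursion follows the standard
// polynomial-time algorithm: a path of unique features is maintained with
// the proportions of subsets that flow ("zero fraction": weight surviving
// when the feature is excluded; "one fraction": when it is included), and
// each leaf distributes its value over the features on its path.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(std::vector<PathElement>& path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1.0) /
                           (unique_depth + 1.0);
    path[i].pweight = zero_fraction * path[i].pweight *
                      (unique_depth - i) / (unique_depth + 1.0);
  }
}

static void unwind_path(std::vector<PathElement>& path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1.0) /
                        ((i + 1.0) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                         (unique_depth - i) / (unique_depth + 1.0);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1.0)) /
                        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const std::vector<PathElement>& path,
                               int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1.0) /
                         ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction *
                         ((unique_depth - i) / (unique_depth + 1.0));
    } else {
      total += (path[i].pweight / zero_fraction) /
               ((unique_depth - i) / (unique_depth + 1.0));
    }
  }
  return total;
}

struct Tree {
  const int* feature;
  const double* threshold;
  const int* left;
  const int* right;
  const double* cover;
  const double* value;
};

static void tree_shap_recurse(const Tree& tree, const double* x, double* phi,
                              int node, std::vector<PathElement> path,
                              int unique_depth, double parent_zero_fraction,
                              double parent_one_fraction,
                              int parent_feature_index) {
  if ((int)path.size() < unique_depth + 1) path.resize(unique_depth + 1);
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);
  const int split_feature = tree.feature[node];
  if (split_feature < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      const PathElement& el = path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) *
                               tree.value[node];
    }
    return;
  }
  // feature values compare to thresholds in float32, as the booster does
  const int hot = (float)x[split_feature] < (float)tree.threshold[node]
                      ? tree.left[node] : tree.right[node];
  const int cold = hot == tree.left[node] ? tree.right[node] : tree.left[node];
  const double w = tree.cover[node];
  const double hot_zero_fraction = tree.cover[hot] / w;
  const double cold_zero_fraction = tree.cover[cold] / w;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (path[path_index].feature_index == split_feature) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }
  tree_shap_recurse(tree, x, phi, hot, path, unique_depth + 1,
                    hot_zero_fraction * incoming_zero_fraction,
                    incoming_one_fraction, split_feature);
  tree_shap_recurse(tree, x, phi, cold, path, unique_depth + 1,
                    cold_zero_fraction * incoming_zero_fraction, 0.0,
                    split_feature);
}

// Cover-weighted expected value of one tree (the path-dependent baseline).
static double tree_expected_value(const Tree& tree, int node) {
  if (tree.feature[node] < 0) return tree.value[node];
  const int l = tree.left[node], r = tree.right[node];
  return (tree.cover[l] * tree_expected_value(tree, l) +
          tree.cover[r] * tree_expected_value(tree, r)) / tree.cover[node];
}

static double tree_predict(const Tree& tree, const double* x, int node) {
  while (tree.feature[node] >= 0)
    node = (float)x[tree.feature[node]] < (float)tree.threshold[node]
               ? tree.left[node] : tree.right[node];
  return tree.value[node];
}

// X: n x p (feature columns in model order). Tree arrays are concatenated
// over trees; tree_offset gives each tree's first node. Returns a list:
// phi (n x p), base_value (scalar, sum of tree expectations), prediction
// (n, double-precision tree traversal; excludes any global bias).
// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(NumericMatrix X, IntegerVector tree_offset,
                  IntegerVector feature, NumericVector threshold,
                  IntegerVector left, IntegerVector right,
                  NumericVector cover, NumericVector value) {
  const int n = X.nrow(), p = X.ncol(), T = tree_offset.size();
  NumericMatrix phi(n, p);
  NumericVector pred(n);
  double base = 0.0;

  std::vector<Tree> trees(T);
  for (int t = 0; t < T; ++t) {
    const int off = tree_offset[t];
    trees[t].feature = &feature[off];
    trees[t].threshold = &threshold[off];
    trees[t].left = &left[off];
    trees[t].right = &right[off];
    trees[t].cover = &cover[off];
    trees[t].value = &value[off];
    base += tree_expected_value(trees[t], 0);
  }

  std::vector<double> xrow(p), phirow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    std::fill(phirow.begin(), phirow.end(), 0.0);
    double pr = 0.0;
    for (int t = 0; t < T; ++t) {
      std::vector<PathElement> path(2);
      tree_shap_recurse(trees[t], xrow.data(), phirow.data(), 0, path, 0,
                        1.0, 1.0, -1);
      pr += tree_predict(trees[t], xrow.data(), 0);
    }
    pred[i] = pr;
    for (int j = 0; j < p; ++j) phi(i, j) = phirow[j];
  }
  return List::create(_["phi"] = phi, _["base_value"] = base,
                      _["prediction"] = pred);
}
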
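#include <Rcpp.h>
using namespace Rcpp;

// Exact Shapley additive explanations for tree ensembles in double
// precision (polynomial-time path algorithm of Lundberg et al.), computed
// from parsed tree structures rather than through the boosting backend so
// that the additivity identity base + sum(phi) == margin holds to machine
// precision. Conditional expectations marginalise absent features with
// cover-weighted averaging, the same weighting the backend uses.

struct PathElem {
  int feature;
  double zero_frac;
  double one_frac;
  double pweight;
};

static void extend_path(std::vector<PathElem> &path, int depth,
                        double zero_frac, double one_frac, int feature) {
  path[depth].feature = feature;
  path[depth].zero_frac = zero_frac;
  path[depth].one_frac = one_frac;
  path[depth].pweight = depth == 0 ? 1.0 : 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_frac * path[i].pweight * (i + 1) /
      (double) (depth + 1);
    path[i].pweight = zero_frac * path[i].pweight * (depth - i) /
      (double) (depth + 1);
  }
}

static void unwind_path(std::vector<PathElem> &path, int depth, int idx) {
  const double one_frac = path[idx].one_frac;
  const double zero_frac = path[idx].zero_frac;
  double next_one = path[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_frac != 0.0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one * (depth + 1) / (double) ((i + 1) * one_frac);
      next_one = tmp - path[i].pweight * zero_frac * (depth - i) /
        (double) (depth + 1);
    } else {
      path[i].pweight = path[i].pweight * (depth + 1) /
        (double) (zero_frac * (depth - i));
    }
  }
  for (int i = idx; i < depth; ++i) {
    path[i].feature = path[i + 1].feature;
    path[i].zero_frac = path[i + 1].zero_frac;
    path[i].one_frac = path[i + 1].one_frac;
  }
}

static double unwound_sum(const std::vector<PathElem> &path, int depth,
                          int idx) {
  const double one_frac = path[idx].one_frac;
  const double zero_frac = path[idx].zero_frac;
  double next_one = path[depth].pweight;
  double total = 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_frac != 0.0) {
      const double tmp = next_one * (depth + 1) /
        (double) ((i + 1) * one_frac);
      total += tmp;
      next_one = path[i].pweight - tmp * zero_frac * (depth - i) /
        (double) (depth + 1);
    } else {
      total += path[i].pweight /
        (zero_frac * (depth - i) / (double) (depth + 1));
    }
  }
  return total;
}

struct Tree {
  IntegerVector left, right, feature;  // feature < 0 => leaf
  NumericVector threshold, value, cover;
};

static void tree_recurse(const Tree &t, const NumericVector::const_iterator x,
                         std::vector<double> &phi, int node,
                         std::vector<PathElem> path, int depth,
                         double parent_zero, double parent_one,
                         int parent_feature) {
  extend_path(path, depth, parent_zero, parent_one, parent_feature);
  if (t.feature[node] < 0) {
    for (int i = 1; i <= depth; ++i) {
      const double w = unwound_sum(path, depth, i);
      phi[path[i].feature] += w *
        (path[i].one_frac - path[i].zero_frac) * t.value[node];
    }
    return;
  }
  const int split = t.feature[node];
  const int hot = x[split] < t.threshold[node] ? t.left[node] : t.right[node];
  const int cold = hot == t.left[node] ? t.right[node] : t.left[node];
  double inc_zero = 1.0, inc_one = 1.0;
  int found = -1;
  for (int i = 1; i <= depth; ++i)
    if (path[i].feature == split) { found = i; break; }
  if (found >= 0) {
    inc_zero = path[found].zero_frac;
    inc_one = path[found].one_frac;
    unwind_path(path, depth, found);
    --depth;
  }
  // Normalise by the children's sum, not the stored parent cover: per-node
  // covers are individually rounded by the backend, and exact additivity
  // needs the two branch fractions to sum to exactly one.
  const double denom = t.cover[hot] + t.cover[cold];
  const double hot_zero = t.cover[hot] / denom;
  const double cold_zero = t.cover[cold] / denom;
  tree_recurse(t, x, phi, hot, path, depth + 1, inc_zero * hot_zero,
               inc_one, split);
  tree_recurse(t, x, phi, cold, path, depth + 1, inc_zero * cold_zero,
               0.0, split);
}

static double leaf_expectation(const Tree &t, int node) {
  if (t.feature[node] < 0) return t.value[node];
  const double wl = t.cover[t.left[node]], wr = t.cover[t.right[node]];
  return (wl * leaf_expectation(t, t.left[node]) +
          wr * leaf_expectation(t, t.right[node])) / (wl + wr);
}

static Tree unpack_tree(List tl) {
  Tree t;
  t.left = tl["left"]; t.right = tl["right"]; t.feature = tl["feature"];
  t.threshold = tl["threshold"]; t.value = tl["value"]; t.cover = tl["cover"];
  return t;
}

// Returns an n x (p + 1) matrix: per-feature contributions plus the base
// value (ensemble expectation) in the last column.
// [[Rcpp::export]]
NumericMatrix tree_shap_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), m = trees.size();
  NumericMatrix out(n, p + 1);
  std::vector<Tree> ts(m);
  double base = 0.0;
  for (int k = 0; k < m; ++k) {
    ts[k] = unpack_tree(trees[k]);
    base += leaf_expectation(ts[k], 0);
  }
  NumericMatrix Xt = transpose(X);  // column-major access per sample
  const int max_depth = 64;
  for (int s = 0; s < n; ++s) {
    std::vector<double> phi(p, 0.0);
    NumericVector::const_iterator x = Xt.begin() + (R_xlen_t) s * p;
    for (int k = 0; k < m; ++k) {
      if (ts[k].feature[0] < 0) continue;  // stump collapsed to a leaf
      std::vector<PathElem> path(max_depth);
      tree_recurse(ts[k], x, phi, 0, path, 0, 1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) out(s, j) = phi[j];
    out(s, p) = base;
  }
  return out;
}

// Double-precision ensemble margin by plain tree traversal.
// [[Rcpp::export]]
NumericVector tree_margin_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), m = trees.size();
  NumericVector out(n);
  std::vector<Tree> ts(m);
  for (int k = 0; k < m; ++k) ts[k] = unpack_tree(trees[k]);
  NumericMatrix Xt = transpose(X);
  for (int s = 0; s < n; ++s) {
    NumericVector::const_iterator x = Xt.begin() + (R_xlen_t) s * p;
    double acc = 0.0;
    for (int k = 0; k < m; ++k) {
      int node = 0;
      while (ts[k].feature[node] >= 0)
        node = x[ts[k].feature[node]] < ts[k].threshold[node] ?
          ts[k].left[node] : ts[k].right[node];
      acc += ts[k].value[node];
    }
    out[s] = acc;
  }
  return out;
}
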
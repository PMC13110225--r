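// Path-dependent TreeSHAP for binary CART-style trees, plus the routing
// pass that derives per-node sample covers from a background data set.
//
// Trees are encoded as parallel arrays (0-based node ids): left/right child
// (-1 for a leaf), split feature (0-based), split threshold ("value <=
// threshold" goes left), leaf value, and node cover (background sample
// count). Attributions satisfy local accuracy exactly: for every row,
// base + sum(phi) equals the tree-ensemble prediction.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct PathElem {
  int d;       // feature index, -1 for the root dummy
  double z;    // zero fraction (proportion of cover flowing through)
  double o;    // one fraction (1 if the feature path matches x)
  double w;    // permutation weight
};

void extend_path(std::vector<PathElem> &m, double pz, double po, int pi) {
  int l = static_cast<int>(m.size());
  PathElem e;
  e.d = pi; e.z = pz; e.o = po; e.w = (l == 0) ? 1.0 : 0.0;
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(l + 1);
    m[i].w = pz * m[i].w * (l - i) / static_cast<double>(l + 1);
  }
}

double unwound_sum(const std::vector<PathElem> &m, int idx) {
  int ud = static_cast<int>(m.size()) - 1;
  double o = m[idx].o, z = m[idx].z;
  double next = m[ud].w, total = 0.0;
  if (o != 0.0) {
    for (int i = ud - 1; i >= 0; --i) {
      double tmp = next / ((i + 1) * o);
      total += tmp;
      next = m[i].w - tmp * z * (ud - i);
    }
  } else {
    for (int i = ud - 1; i >= 0; --i) {
      total += m[i].w / (z * (ud - i));
    }
  }
  return total * (ud + 1);
}

void unwind_path(std::vector<PathElem> &m, int idx) {
  int ud = static_cast<int>(m.size()) - 1;
  double o = m[idx].o, z = m[idx].z;
  double next = m[ud].w;
  for (int i = ud - 1; i >= 0; --i) {
    if (o != 0.0) {
      double tmp = m[i].w;
      m[i].w = next * (ud + 1) / ((i + 1) * o);
      next = tmp - m[i].w * z * (ud - i) / static_cast<double>(ud + 1);
    } else {
      m[i].w = m[i].w * (ud + 1) / (z * (ud - i));
    }
  }
  for (int i = idx; i < ud; ++i) {
    m[i].d = m[i + 1].d;
    m[i].z = m[i + 1].z;
    m[i].o = m[i + 1].o;
  }
  m.pop_back();
}

struct Tree {
  IntegerVector left, right, feat;
  NumericVector thr, value, cover;
};

void tree_shap_recurse(const Tree &tr, const double *x, double *phi,
                       int node, std::vector<PathElem> m,
                       double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  if (tr.left[node] < 0) {
    int ud = static_cast<int>(m.size()) - 1;
    for (int i = 1; i <= ud; ++i) {
      double w = unwound_sum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * tr.value[node];
    }
    return;
  }
  int f = tr.feat[node];
  int hot = (x[f] <= tr.thr[node]) ? tr.left[node] : tr.right[node];
  int cold = (hot == tr.left[node]) ? tr.right[node] : tr.left[node];
  double w = tr.cover[node];
  double hzf = tr.cover[hot] / w;
  double czf = tr.cover[cold] / w;
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 0; i < static_cast<int>(m.size()); ++i) {
    if (m[i].d == f) { k = i; break; }
  }
  if (k >= 0) {
    iz = m[k].z;
    io = m[k].o;
    unwind_path(m, k);
  }
  tree_shap_recurse(tr, x, phi, hot, m, hzf * iz, io, f);
  tree_shap_recurse(tr, x, phi, cold, m, czf * iz, 0.0, f);
}

Tree as_tree(const List &tl) {
  Tree tr;
  tr.left = tl["left"];
  tr.right = tl["right"];
  tr.feat = tl["feature"];
  tr.thr = tl["threshold"];
  tr.value = tl["value"];
  tr.cover = tl["cover"];
  return tr;
}

} // namespace

// SHAP attributions for a forest: returns an n x p matrix of per-feature
// attributions plus the (common) base value as an attribute. Leaf values
// are expected pre-scaled by 1/n_trees so that the ensemble prediction is
// the sum over trees.
// [[Rcpp::export]]
List treeshap_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol(), T = forest.size();
  NumericMatrix phi(n, p);
  double base = 0.0;
  std::vector<Tree> trees(T);
  for (int t = 0; t < T; ++t) trees[t] = as_tree(forest[t]);
  for (int t = 0; t < T; ++t) {
    const Tree &tr = trees[t];
    double root_cover = tr.cover[0];
    for (int j = 0; j < tr.left.size(); ++j) {
      if (tr.left[j] < 0) base += tr.value[j] * tr.cover[j] / root_cover;
    }
  }
  std::vector<double> xrow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    std::vector<double> ph(p, 0.0);
    for (int t = 0; t < T; ++t) {
      std::vector<PathElem> m;
      tree_shap_recurse(trees[t], xrow.data(), ph.data(), 0, m, 1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = ph[j];
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}

// Route each row of X through a tree and count arrivals per node.
// [[Rcpp::export]]
IntegerVector route_counts_cpp(IntegerVector left, IntegerVector right,
                               IntegerVector feat, NumericVector thr,
                               NumericMatrix X) {
  int n = X.nrow();
  IntegerVector counts(left.size());
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (true) {
      counts[node] += 1;
      if (left[node] < 0) break;
      node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
    }
  }
  return counts;
}

// Per-tree prediction for each row of X (leaf value lookup).
// [[Rcpp::export]]
NumericMatrix route_predict_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), T = forest.size();
  NumericMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    Tree tr = as_tree(forest[t]);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr.left[node] >= 0) {
        node = (X(i, tr.feat[node]) <= tr.thr[node]) ? tr.left[node]
                                                     : tr.right[node];
      }
      out(i, t) = tr.value[node];
    }
  }
  return out;
}
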
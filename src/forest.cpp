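// Bagged CART ensemble on binary feature matrices with out-of-bag
// permutation importance.  This is the importance scorer behind the
// shadow-feature selection step; it is deliberately minimal: features are
// {0,1} indicators, splits are "x == 0 vs x == 1", impurity is Gini.
// Randomness comes from R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;  // -1 for leaf
  std::vector<int> left, right, pred;
};

int add_node(Tree &t) {
  t.feature.push_back(-1);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(-1);
  return static_cast<int>(t.feature.size()) - 1;
}

double gini(const std::vector<int> &counts, int total) {
  if (total == 0) return 0.0;
  double g = 1.0;
  for (int c : counts) {
    double p = static_cast<double>(c) / total;
    g -= p * p;
  }
  return g;
}

int majority(const std::vector<int> &counts) {
  int best = 0;
  for (size_t k = 1; k < counts.size(); ++k)
    if (counts[k] > counts[best]) best = static_cast<int>(k);
  return best;  // ties break toward the smallest class index
}

int rand_int(int n) {  // uniform on 0..n-1 via R's RNG
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

void grow(Tree &t, int node, std::vector<int> &rows, const IntegerMatrix &X,
          const IntegerVector &y, int nclass, int mtry, int min_node,
          std::vector<int> &feat_pool, std::vector<bool> &used) {
  std::vector<int> counts(nclass, 0);
  for (int r : rows) counts[y[r]]++;
  int total = static_cast<int>(rows.size());
  int maj = majority(counts);
  bool pure = counts[maj] == total;
  if (pure || total < min_node) {
    t.pred[node] = maj;
    return;
  }
  // sample mtry candidate features (partial Fisher-Yates on the pool)
  int p = static_cast<int>(feat_pool.size());
  int m = mtry < p ? mtry : p;
  for (int i = 0; i < m; ++i) {
    int j = i + rand_int(p - i);
    std::swap(feat_pool[i], feat_pool[j]);
  }
  int best_f = -1;
  double best_imp = gini(counts, total);
  std::vector<int> cl(nclass), cr(nclass);
  for (int i = 0; i < m; ++i) {
    int f = feat_pool[i];
    std::fill(cl.begin(), cl.end(), 0);
    std::fill(cr.begin(), cr.end(), 0);
    int nl = 0;
    for (int r : rows) {
      if (X(r, f) == 0) { cl[y[r]]++; nl++; } else cr[y[r]]++;
    }
    int nr = total - nl;
    if (nl == 0 || nr == 0) continue;
    double imp = (nl * gini(cl, nl) + nr * gini(cr, nr)) / total;
    if (imp < best_imp - 1e-12) {
      best_imp = imp;
      best_f = f;
    }
  }
  if (best_f < 0) {
    t.pred[node] = maj;
    return;
  }
  std::vector<int> lrows, rrows;
  for (int r : rows) (X(r, best_f) == 0 ? lrows : rrows).push_back(r);
  t.feature[node] = best_f;
  used[best_f] = true;
  int ln = add_node(t), rn = add_node(t);
  t.left[node] = ln;
  t.right[node] = rn;
  rows.clear();
  rows.shrink_to_fit();
  grow(t, ln, lrows, X, y, nclass, mtry, min_node, feat_pool, used);
  grow(t, rn, rrows, X, y, nclass, mtry, min_node, feat_pool, used);
}

int predict_row(const Tree &t, const IntegerMatrix &X, int r, int perm_f,
                int perm_val) {
  int node = 0;
  while (t.feature[node] >= 0) {
    int f = t.feature[node];
    int v = (f == perm_f) ? perm_val : X(r, f);
    node = (v == 0) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

}  // namespace

// Per-tree OOB permutation importance: returns an ntree x p matrix whose
// (t, f) entry is (OOB accuracy - OOB accuracy with feature f permuted)
// for tree t.  Features unused by a tree score exactly 0.
// [[Rcpp::export]]
NumericMatrix forest_importance_cpp(IntegerMatrix X, IntegerVector y,
                                    int nclass, int ntree, int mtry,
                                    int min_node) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix imp(ntree, p);
  std::vector<int> feat_pool(p);
  for (int tr = 0; tr < ntree; ++tr) {
    std::vector<bool> inbag(n, false);
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      int r = rand_int(n);
      rows[i] = r;
      inbag[r] = true;
    }
    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    Tree t;
    add_node(t);
    for (int f = 0; f < p; ++f) feat_pool[f] = f;
    std::vector<bool> used(p, false);
    grow(t, 0, rows, X, y, nclass, mtry, min_node, feat_pool, used);
    if (oob.empty()) continue;
    int n_oob = static_cast<int>(oob.size());
    int base = 0;
    for (int r : oob)
      if (predict_row(t, X, r, -1, 0) == y[r]) base++;
    std::vector<int> perm(n_oob);
    for (int f = 0; f < p; ++f) {
      if (!used[f]) continue;
      // permuted copy of feature f over the OOB rows (Fisher-Yates)
      for (int i = 0; i < n_oob; ++i) perm[i] = X(oob[i], f);
      for (int i = n_oob - 1; i > 0; --i) {
        int j = rand_int(i + 1);
        std::swap(perm[i], perm[j]);
      }
      int correct = 0;
      for (int i = 0; i < n_oob; ++i)
        if (predict_row(t, X, oob[i], f, perm[i]) == y[oob[i]]) correct++;
      imp(tr, f) = static_cast<double>(base - correct) / n_oob;
    }
  }
  return imp;
}
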
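// Conditional-inference-style regression forest.
//
// Each node selects its split variable by the smallest per-variable
// association p-value (two-sided t test on the Pearson correlation within
// the node, Bonferroni-corrected over the candidates actually tested, as an
// analytic stand-in for the permutation correlation test), and stops when
// the adjusted p-value exceeds alpha. Trees are grown on subsamples drawn
// without replacement; variable importance is the mean increase in
// out-of-bag MSE when one feature's OOB values are permuted.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct TreeData {
  std::vector<int> var;        // split variable, -1 for leaf
  std::vector<double> split;   // split threshold (go left if x <= split)
  std::vector<double> pred;    // node mean of y
  std::vector<int> left, right;
};

static int build_node(const NumericMatrix& X, const NumericVector& y,
                      std::vector<int>& rows, int lo, int hi,
                      int mtry, int min_node, double alpha,
                      int depth, int max_depth,
                      std::mt19937& gen, TreeData& tree) {
  const int node = static_cast<int>(tree.var.size());
  const int m = hi - lo;
  double sum = 0.0;
  for (int i = lo; i < hi; ++i) sum += y[rows[i]];
  const double mean = sum / m;
  tree.var.push_back(-1);
  tree.split.push_back(0.0);
  tree.pred.push_back(mean);
  tree.left.push_back(-1);
  tree.right.push_back(-1);

  if (m < 2 * min_node || depth >= max_depth) return node;
  double ssy = 0.0;
  for (int i = lo; i < hi; ++i) {
    const double d = y[rows[i]] - mean;
    ssy += d * d;
  }
  if (ssy <= 1e-12) return node;

  // candidate variables: partial Fisher-Yates draw of mtry indices
  const int p = X.ncol();
  std::vector<int> cand(p);
  for (int j = 0; j < p; ++j) cand[j] = j;
  const int ncand = std::min(mtry, p);
  for (int j = 0; j < ncand; ++j) {
    std::uniform_int_distribution<int> pick(j, p - 1);
    std::swap(cand[j], cand[pick(gen)]);
  }

  double best_p = 2.0;
  int best_var = -1, tested = 0;
  for (int j = 0; j < ncand; ++j) {
    const int v = cand[j];
    double sx = 0.0, sxx = 0.0, sxy = 0.0;
    for (int i = lo; i < hi; ++i) {
      const double xv = X(rows[i], v);
      sx += xv;
      sxx += xv * xv;
      sxy += xv * y[rows[i]];
    }
    const double varx = sxx - sx * sx / m;
    if (varx <= 1e-12) continue;
    ++tested;
    const double cov = sxy - sx * sum / m;
    double r2 = cov * cov / (varx * ssy);
    if (r2 > 1.0 - 1e-12) r2 = 1.0 - 1e-12;
    const double tstat = std::sqrt(r2 * (m - 2) / (1.0 - r2));
    const double pval = 2.0 * R::pt(-tstat, m - 2, 1, 0);
    if (pval < best_p) { best_p = pval; best_var = v; }
  }
  if (best_var < 0) return node;
  const double p_adj = std::min(1.0, best_p * tested);
  if (p_adj > alpha) return node;

  // best SSE-reducing split point on the selected variable
  std::sort(rows.begin() + lo, rows.begin() + hi,
            [&](int a, int b) { return X(a, best_var) < X(b, best_var); });
  std::vector<double> cumy(m + 1, 0.0);
  for (int i = 0; i < m; ++i) cumy[i + 1] = cumy[i] + y[rows[lo + i]];
  double best_score = -1.0;
  int best_i = -1;
  for (int i = min_node; i <= m - min_node; ++i) {
    const double xl = X(rows[lo + i - 1], best_var);
    const double xr = X(rows[lo + i], best_var);
    if (xr - xl <= 0.0) continue;
    const double sl = cumy[i], sr = sum - sl;
    const double score = sl * sl / i + sr * sr / (m - i);
    if (score > best_score) { best_score = score; best_i = i; }
  }
  if (best_i < 0) return node;

  const double split_val = 0.5 * (X(rows[lo + best_i - 1], best_var) +
                                  X(rows[lo + best_i], best_var));
  tree.var[node] = best_var;
  tree.split[node] = split_val;
  const int lchild = build_node(X, y, rows, lo, lo + best_i, mtry, min_node,
                                alpha, depth + 1, max_depth, gen, tree);
  const int rchild = build_node(X, y, rows, lo + best_i, hi, mtry, min_node,
                                alpha, depth + 1, max_depth, gen, tree);
  tree.left[node] = lchild;
  tree.right[node] = rchild;
  return node;
}

static double predict_row(const TreeData& tree, const NumericMatrix& X,
                          int row, int override_var, double override_val) {
  int node = 0;
  while (tree.var[node] >= 0) {
    const int v = tree.var[node];
    const double xv = (v == override_var) ? override_val : X(row, v);
    node = (xv <= tree.split[node]) ? tree.left[node] : tree.right[node];
  }
  return tree.pred[node];
}

// [[Rcpp::export]]
List cif_fit_cpp(NumericMatrix X, NumericVector y, int num_trees, int mtry,
                 int min_node, double alpha, double subsample, int max_depth,
                 int seed, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 gen(static_cast<unsigned int>(seed));
  int n_sub = static_cast<int>(std::lround(subsample * n));
  if (n_sub < 2) n_sub = 2;
  if (n_sub > n) n_sub = n;

  List trees(num_trees);
  NumericVector imp(p);
  std::vector<int> perm_all(n);

  for (int t = 0; t < num_trees; ++t) {
    for (int i = 0; i < n; ++i) perm_all[i] = i;
    for (int i = 0; i < n_sub; ++i) {
      std::uniform_int_distribution<int> pick(i, n - 1);
      std::swap(perm_all[i], perm_all[pick(gen)]);
    }
    std::vector<int> inbag(perm_all.begin(), perm_all.begin() + n_sub);
    std::vector<int> oob(perm_all.begin() + n_sub, perm_all.end());

    TreeData tree;
    build_node(X, y, inbag, 0, n_sub, mtry, min_node, alpha, 0, max_depth,
               gen, tree);
    trees[t] = List::create(
      Named("var") = IntegerVector(tree.var.begin(), tree.var.end()),
      Named("split") = NumericVector(tree.split.begin(), tree.split.end()),
      Named("pred") = NumericVector(tree.pred.begin(), tree.pred.end()),
      Named("left") = IntegerVector(tree.left.begin(), tree.left.end()),
      Named("right") = IntegerVector(tree.right.begin(), tree.right.end()));

    if (importance && !oob.empty()) {
      const int no = static_cast<int>(oob.size());
      double mse0 = 0.0;
      for (int i = 0; i < no; ++i) {
        const double d = predict_row(tree, X, oob[i], -1, 0.0) - y[oob[i]];
        mse0 += d * d;
      }
      mse0 /= no;

      std::vector<bool> used(p, false);
      for (size_t k = 0; k < tree.var.size(); ++k)
        if (tree.var[k] >= 0) used[tree.var[k]] = true;

      std::vector<int> shuf(no);
      for (int v = 0; v < p; ++v) {
        if (!used[v]) continue;
        for (int i = 0; i < no; ++i) shuf[i] = i;
        for (int i = no - 1; i > 0; --i) {
          std::uniform_int_distribution<int> pick(0, i);
          std::swap(shuf[i], shuf[pick(gen)]);
        }
        double mse_perm = 0.0;
        for (int i = 0; i < no; ++i) {
          const double xv = X(oob[shuf[i]], v);
          const double d = predict_row(tree, X, oob[i], v, xv) - y[oob[i]];
          mse_perm += d * d;
        }
        mse_perm /= no;
        imp[v] += mse_perm - mse0;
      }
    }
  }
  for (int v = 0; v < p; ++v) imp[v] /= num_trees;
  return List::create(Named("trees") = trees,
                      Named("importance") = imp,
                      Named("n_features") = p);
}

// [[Rcpp::export]]
NumericVector cif_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    TreeData tree;
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
    NumericVector split = tr["split"], pred = tr["pred"];
    tree.var.assign(var.begin(), var.end());
    tree.split.assign(split.begin(), split.end());
    tree.pred.assign(pred.begin(), pred.end());
    tree.left.assign(left.begin(), left.end());
    tree.right.assign(right.begin(), right.end());
    for (int i = 0; i < n; ++i)
      out[i] += predict_row(tree, X, i, -1, 0.0);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
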
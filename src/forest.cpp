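#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bagged regression trees (CART with variance-reduction splits).
//
// Tree storage: one matrix per tree, one row per node, columns
//   0 var   (1-based split covariate; 0 = terminal node)
//   1 split (numeric cutpoint; rows with x <= split go left)
//   2 left  (1-based row of left child; 0 for leaves)
//   3 right (1-based row of right child)
//   4 value (in-bag mean response at the node)
//   5 n     (in-bag sample size at the node)
//
// All randomness (bootstrap draws, covariate subsampling, permutation)
// comes from R's RNG stream, so a single set.seed() in the caller makes
// the whole forest bit-reproducible.

namespace {

struct NodeTask {
  int node_row;                // row in the output matrix
  std::vector<int> rows;       // in-bag row indices (0-based, with multiplicity)
};

inline int rand_int(int n) {
  // uniform integer in [0, n), via R's RNG
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// sample m distinct values from 0..(p-1), returned sorted ascending so the
// split search visits covariates in index order (deterministic tie-break)
void sample_vars(int p, int m, std::vector<int>& out, std::vector<int>& pool) {
  pool.resize(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < m; ++i) {
    int j = i + rand_int(p - i);
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
  std::sort(out.begin(), out.end());
}

struct BestSplit {
  int var;            // -1 if none
  double split;
  long double gain;
};

// best SSE-reduction split at a node; ties broken by lowest covariate index
// then smallest cutpoint (guaranteed by scan order and strict improvement)
BestSplit find_split(const NumericMatrix& X, const NumericVector& y,
                     const std::vector<int>& rows,
                     const std::vector<int>& vars) {
  const int n = (int)rows.size();
  BestSplit best{-1, 0.0, 0.0L};

  long double ytot = 0.0L;
  for (int i = 0; i < n; ++i) ytot += y[rows[i]];
  const long double base = (ytot * ytot) / n;

  std::vector<std::pair<double, double> > xy(n);
  for (size_t v = 0; v < vars.size(); ++v) {
    const int j = vars[v];
    for (int i = 0; i < n; ++i)
      xy[i] = std::make_pair(X(rows[i], j), y[rows[i]]);
    std::sort(xy.begin(), xy.end());
    if (xy[0].first == xy[n - 1].first) continue;  // constant covariate

    long double sl = 0.0L;
    for (int i = 0; i < n - 1; ++i) {
      sl += xy[i].second;
      if (xy[i].first == xy[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      const long double sr = ytot - sl;
      const long double gain = (sl * sl) / nl + (sr * sr) / nr - base;
      if (gain > best.gain) {
        best.gain = gain;
        best.var = j;
        best.split = (xy[i].first + xy[i + 1].first) / 2.0;
      }
    }
  }
  return best;
}

NumericMatrix grow_tree_impl(const NumericMatrix& X, const NumericVector& y,
                             const std::vector<int>& inbag_rows,
                             int mtry, int min_node_size) {
  const int p = X.ncol();
  std::vector<std::array<double, 6> > nodes;
  std::vector<NodeTask> stack;
  std::vector<int> vars, pool;

  nodes.push_back({0, 0, 0, 0, 0, 0});
  stack.push_back(NodeTask{0, inbag_rows});

  while (!stack.empty()) {
    NodeTask task = std::move(stack.back());
    stack.pop_back();
    const std::vector<int>& rows = task.rows;
    const int n = (int)rows.size();

    long double s = 0.0L;
    double ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double yi = y[rows[i]];
      s += yi;
      if (yi < ymin) ymin = yi;
      if (yi > ymax) ymax = yi;
    }
    const double mean = (double)(s / n);

    std::array<double, 6>& nd = nodes[task.node_row];
    nd[4] = mean;
    nd[5] = n;

    if (n <= min_node_size || n < 2 || ymin == ymax) continue;  // leaf

    sample_vars(p, mtry, vars, pool);
    BestSplit bs = find_split(X, y, rows, vars);
    if (bs.var < 0) continue;  // no valid split among sampled covariates

    std::vector<int> left, right;
    left.reserve(n);
    right.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(rows[i], bs.var) <= bs.split) left.push_back(rows[i]);
      else right.push_back(rows[i]);
    }
    if (left.empty() || right.empty()) continue;  // numeric safeguard

    const int li = (int)nodes.size();
    nodes.push_back({0, 0, 0, 0, 0, 0});
    const int ri = (int)nodes.size();
    nodes.push_back({0, 0, 0, 0, 0, 0});

    std::array<double, 6>& nd2 = nodes[task.node_row];  // may have moved
    nd2[0] = bs.var + 1;
    nd2[1] = bs.split;
    nd2[2] = li + 1;
    nd2[3] = ri + 1;

    stack.push_back(NodeTask{ri, std::move(right)});
    stack.push_back(NodeTask{li, std::move(left)});
  }

  NumericMatrix out((int)nodes.size(), 6);
  for (size_t i = 0; i < nodes.size(); ++i)
    for (int j = 0; j < 6; ++j) out((int)i, j) = nodes[i][j];
  colnames(out) = CharacterVector::create("var", "split", "left", "right",
                                          "value", "n");
  return out;
}

inline double predict_row(const NumericMatrix& tree, const NumericMatrix& X,
                          int row) {
  int node = 0;
  while (tree(node, 0) != 0) {
    const int j = (int)tree(node, 0) - 1;
    node = (X(row, j) <= tree(node, 1)) ? (int)tree(node, 2) - 1
                                        : (int)tree(node, 3) - 1;
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export(name = ".grow_tree_cpp")]]
NumericMatrix grow_tree_cpp(NumericMatrix X, NumericVector y,
                            IntegerVector inbag, int mtry, int min_node_size) {
  std::vector<int> rows(inbag.size());
  for (int i = 0; i < inbag.size(); ++i) rows[i] = inbag[i] - 1;
  return grow_tree_impl(X, y, rows, mtry, min_node_size);
}

// [[Rcpp::export(name = ".grow_forest_cpp")]]
List grow_forest_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                     int min_node_size) {
  const int n = X.nrow();
  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees);
  std::vector<int> rows(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      const int k = rand_int(n);
      rows[i] = k;
      inbag(k, t)++;
    }
    trees[t] = grow_tree_impl(X, y, rows, mtry, min_node_size);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export(name = ".predict_forest_cpp")]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// [[Rcpp::export(name = ".oob_predict_cpp")]]
NumericVector oob_predict_cpp(List trees, IntegerMatrix inbag,
                              NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector sum(n);
  IntegerVector cnt(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) == 0) {
        sum[i] += predict_row(tree, X, i);
        cnt[i]++;
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (cnt[i] > 0) ? sum[i] / cnt[i] : NA_REAL;
  return out;
}

// Per-tree OOB permutation importance: the increase in a tree's OOB MSE
// when one covariate's OOB values are shuffled, averaged over trees.
// [[Rcpp::export(name = ".perm_importance_cpp")]]
List perm_importance_cpp(List trees, IntegerMatrix inbag, NumericMatrix X,
                         NumericVector y) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericVector imp(p), imp_sq(p);
  IntegerVector used(p);  // trees with >=2 OOB rows contributing

  NumericMatrix Xw(clone(X));
  std::vector<int> oob;
  std::vector<double> saved;

  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    const int m = (int)oob.size();
    if (m < 2) continue;

    long double base = 0.0L;
    for (int k = 0; k < m; ++k) {
      const double e = y[oob[k]] - predict_row(tree, X, oob[k]);
      base += e * e;
    }
    const double mse0 = (double)(base / m);

    for (int j = 0; j < p; ++j) {
      saved.resize(m);
      for (int k = 0; k < m; ++k) saved[k] = Xw(oob[k], j);
      // Fisher-Yates shuffle of the OOB values of covariate j
      for (int k = m - 1; k > 0; --k) {
        const int l = rand_int(k + 1);
        std::swap(saved[k], saved[l]);
      }
      for (int k = 0; k < m; ++k) Xw(oob[k], j) = saved[k];
      long double perm = 0.0L;
      for (int k = 0; k < m; ++k) {
        const double e = y[oob[k]] - predict_row(tree, Xw, oob[k]);
        perm += e * e;
      }
      for (int k = 0; k < m; ++k) Xw(oob[k], j) = X(oob[k], j);
      const double d = (double)(perm / m) - mse0;
      imp[j] += d;
      imp_sq[j] += d * d;
    }
    for (int j = 0; j < p; ++j) used[j]++;
  }

  NumericVector mean_imp(p), se_imp(p);
  for (int j = 0; j < p; ++j) {
    if (used[j] > 0) {
      mean_imp[j] = imp[j] / used[j];
      if (used[j] > 1) {
        const double var =
            (imp_sq[j] - imp[j] * imp[j] / used[j]) / (used[j] - 1);
        se_imp[j] = std::sqrt(std::max(var, 0.0) / used[j]);
      } else {
        se_imp[j] = NA_REAL;
      }
    } else {
      mean_imp[j] = NA_REAL;
      se_imp[j] = NA_REAL;
    }
  }
  return List::create(_["importance"] = mean_imp, _["se"] = se_imp,
                      _["n_trees_used"] = used);
}
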
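// Bagged CART regression trees with leaf-weight conditional quantiles
// (Meinshausen-style) and out-of-bag permutation importance.
//
// Trees are grown on bootstrap resamples passed in as an inbag count
// matrix so that all randomness flows through R's RNG on the R side;
// the only RNG use here (mtry feature sampling, OOB permutation) goes
// through R's RNG via Rcpp, keeping fits reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuild {
  std::vector<int> split_var;   // -1 for leaf
  std::vector<double> split_val;
  std::vector<int> left, right;
  std::vector<double> pred;     // node mean of bootstrap responses
  std::vector<int> node_n;      // bootstrap count in node
};

int new_node(TreeBuild &t) {
  t.split_var.push_back(-1);
  t.split_val.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(0.0);
  t.node_n.push_back(0);
  return (int)t.split_var.size() - 1;
}

// terminal node of row i under tree t (flat-vector representation)
inline int drop_row(const IntegerVector &sv, const NumericVector &spl,
                    const IntegerVector &lf, const IntegerVector &rg,
                    const NumericMatrix &X, int i) {
  int node = 0;
  while (sv[node] >= 0) {
    node = (X(i, sv[node]) <= spl[node]) ? lf[node] : rg[node];
  }
  return node;
}

} // namespace

// [[Rcpp::export]]
List grow_forest_cpp(NumericMatrix X, NumericVector y, IntegerMatrix inbag,
                     int mtry, int min_node_size) {
  const int n = X.nrow(), p = X.ncol(), n_trees = inbag.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  if (min_node_size < 1) min_node_size = 1;

  List trees(n_trees);
  IntegerMatrix train_nodes(n, n_trees);
  NumericVector purity(p);

  std::vector<int> ids;            // bootstrap row ids, node = segment
  ids.reserve(n);
  std::vector<std::pair<double, int> > vals; // (x value, position) scratch
  vals.reserve(n);

  for (int t = 0; t < n_trees; ++t) {
    ids.clear();
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < inbag(i, t); ++c) ids.push_back(i);
    const int nb = (int)ids.size();

    TreeBuild tr;
    // stack of (lo, hi, node_id)
    std::vector<std::array<int, 3> > stack;
    int root = new_node(tr);
    stack.push_back({0, nb, root});

    while (!stack.empty()) {
      int lo = stack.back()[0], hi = stack.back()[1], node = stack.back()[2];
      stack.pop_back();
      const int m = hi - lo;
      double sum = 0.0, sumsq = 0.0;
      for (int k = lo; k < hi; ++k) {
        double v = y[ids[k]];
        sum += v; sumsq += v * v;
      }
      const double mean = sum / m;
      const double ss = sumsq - sum * sum / m;
      tr.pred[node] = mean;
      tr.node_n[node] = m;
      // min_node_size is a minimum leaf size: a node can only split if
      // both children can reach it, so leaves hold min_node_size to
      // 2*min_node_size - 1 bootstrap observations
      if (m < 2 * min_node_size || ss <= 1e-12) continue; // leaf

      // candidate features: mtry sampled without replacement, scanned in
      // increasing index order so ties resolve to the lowest feature index
      IntegerVector cand = Rcpp::sample(p, mtry, false); // 1-based
      std::vector<int> feat(cand.begin(), cand.end());
      for (size_t f = 0; f < feat.size(); ++f) feat[f] -= 1;
      std::sort(feat.begin(), feat.end());

      double best_gain = 0.0, best_split = 0.0;
      int best_f = -1, best_nl = 0;
      for (size_t fi = 0; fi < feat.size(); ++fi) {
        const int f = feat[fi];
        vals.clear();
        for (int k = lo; k < hi; ++k)
          vals.push_back(std::make_pair(X(ids[k], f), ids[k]));
        std::sort(vals.begin(), vals.end());
        if (vals.front().first == vals.back().first) continue; // constant
        double sl = 0.0;
        for (int k = 0; k < m - 1; ++k) {
          sl += y[vals[k].second];
          if (k + 1 < min_node_size || m - k - 1 < min_node_size) continue;
          if (vals[k + 1].first > vals[k].first) {
            const int nl = k + 1, nr = m - nl;
            const double sr = sum - sl;
            // maximizing nl*meanl^2 + nr*meanr^2 minimizes child SS
            const double gain = sl * sl / nl + sr * sr / nr - sum * sum / m;
            if (gain > best_gain + 1e-12) {
              best_gain = gain;
              best_f = f;
              best_split = (vals[k].first + vals[k + 1].first) / 2.0;
              best_nl = nl;
            }
          }
        }
      }
      if (best_f < 0) continue; // no valid split among sampled features

      purity[best_f] += best_gain;
      // in-place stable partition of the segment
      std::vector<int> lbuf, rbuf;
      lbuf.reserve(best_nl); rbuf.reserve(m - best_nl);
      for (int k = lo; k < hi; ++k) {
        if (X(ids[k], best_f) <= best_split) lbuf.push_back(ids[k]);
        else rbuf.push_back(ids[k]);
      }
      std::copy(lbuf.begin(), lbuf.end(), ids.begin() + lo);
      std::copy(rbuf.begin(), rbuf.end(), ids.begin() + lo + (int)lbuf.size());

      int lnode = new_node(tr), rnode = new_node(tr);
      tr.split_var[node] = best_f;
      tr.split_val[node] = best_split;
      tr.left[node] = lnode;
      tr.right[node] = rnode;
      stack.push_back({lo + (int)lbuf.size(), hi, rnode});
      stack.push_back({lo, lo + (int)lbuf.size(), lnode});
    }

    IntegerVector sv(tr.split_var.begin(), tr.split_var.end());
    NumericVector spl(tr.split_val.begin(), tr.split_val.end());
    IntegerVector lf(tr.left.begin(), tr.left.end());
    IntegerVector rg(tr.right.begin(), tr.right.end());
    NumericVector pr(tr.pred.begin(), tr.pred.end());
    IntegerVector nn(tr.node_n.begin(), tr.node_n.end());
    trees[t] = List::create(_["split_var"] = sv, _["split_val"] = spl,
                            _["left"] = lf, _["right"] = rg,
                            _["pred"] = pr, _["node_n"] = nn);
    for (int i = 0; i < n; ++i)
      train_nodes(i, t) = drop_row(sv, spl, lf, rg, X, i);
  }
  for (int j = 0; j < p; ++j) purity[j] /= n_trees;
  return List::create(_["trees"] = trees, _["train_nodes"] = train_nodes,
                      _["node_purity"] = purity);
}

// [[Rcpp::export]]
IntegerMatrix forest_nodes_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), n_trees = trees.size();
  IntegerMatrix out(n, n_trees);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector sv = tr["split_var"];
    NumericVector spl = tr["split_val"];
    IntegerVector lf = tr["left"], rg = tr["right"];
    for (int i = 0; i < n; ++i) out(i, t) = drop_row(sv, spl, lf, rg, X, i);
  }
  return out;
}

namespace {

// per-tree bucketing of in-bag training rows by terminal node
struct LeafIndex {
  std::vector<int> offset;   // n_nodes + 1
  std::vector<int> item_row; // original row ids (each once)
  std::vector<int> item_cnt; // bootstrap multiplicity
  std::vector<double> node_tot;
};

void build_leaf_index(const IntegerMatrix &train_nodes,
                      const IntegerMatrix &inbag, int t, int n_nodes,
                      LeafIndex &L) {
  const int n = train_nodes.nrow();
  std::vector<int> cnt(n_nodes, 0);
  for (int i = 0; i < n; ++i)
    if (inbag(i, t) > 0) cnt[train_nodes(i, t)]++;
  L.offset.assign(n_nodes + 1, 0);
  for (int k = 0; k < n_nodes; ++k) L.offset[k + 1] = L.offset[k] + cnt[k];
  L.item_row.assign(L.offset[n_nodes], 0);
  L.item_cnt.assign(L.offset[n_nodes], 0);
  L.node_tot.assign(n_nodes, 0.0);
  std::vector<int> pos(L.offset.begin(), L.offset.end() - 1);
  for (int i = 0; i < n; ++i) {
    const int c = inbag(i, t);
    if (c > 0) {
      const int nd = train_nodes(i, t);
      L.item_row[pos[nd]] = i;
      L.item_cnt[pos[nd]] = c;
      pos[nd]++;
      L.node_tot[nd] += c;
    }
  }
}

} // namespace

// Conditional quantiles: weight w_i(x) = mean over trees of
// multiplicity_i / leaf_total for the leaf containing x; quantile is the
// inf-type inverse of the weighted empirical CDF over training responses.
// [[Rcpp::export]]
NumericMatrix qrf_quantiles_cpp(List trees, IntegerMatrix train_nodes,
                                IntegerMatrix inbag, NumericVector y,
                                IntegerMatrix test_nodes, NumericVector taus) {
  const int n = y.size(), n_trees = trees.size(), n_test = test_nodes.nrow();
  const int n_tau = taus.size();

  std::vector<LeafIndex> idx(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector sv = tr["split_var"];
    build_leaf_index(train_nodes, inbag, t, sv.size(), idx[t]);
  }
  // ascending order of y
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return y[a] < y[b]; });
  // taus scanned in ascending order
  std::vector<int> tord(n_tau);
  for (int k = 0; k < n_tau; ++k) tord[k] = k;
  std::sort(tord.begin(), tord.end(),
            [&](int a, int b) { return taus[a] < taus[b]; });

  NumericMatrix out(n_test, n_tau);
  std::vector<double> w(n);
  for (int i = 0; i < n_test; ++i) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int t = 0; t < n_trees; ++t) {
      const LeafIndex &L = idx[t];
      const int nd = test_nodes(i, t);
      const double tot = L.node_tot[nd];
      if (tot <= 0) continue;
      for (int k = L.offset[nd]; k < L.offset[nd + 1]; ++k)
        w[L.item_row[k]] += L.item_cnt[k] / tot;
    }
    double wsum = 0.0;
    for (int j = 0; j < n; ++j) wsum += w[j];
    double cum = 0.0;
    int k = 0, j = 0;
    for (; j < n && k < n_tau; ++j) {
      cum += w[ord[j]] / wsum;
      while (k < n_tau && cum >= taus[tord[k]] - 1e-10) {
        out(i, tord[k]) = y[ord[j]];
        ++k;
      }
    }
    for (; k < n_tau; ++k) out(i, tord[k]) = y[ord[n - 1]];
  }
  return out;
}

// Dense weight matrix; intended for small fixtures in tests.
// [[Rcpp::export]]
NumericMatrix qrf_weights_cpp(List trees, IntegerMatrix train_nodes,
                              IntegerMatrix inbag, IntegerMatrix test_nodes) {
  const int n = train_nodes.nrow(), n_trees = trees.size();
  const int n_test = test_nodes.nrow();
  std::vector<LeafIndex> idx(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector sv = tr["split_var"];
    build_leaf_index(train_nodes, inbag, t, sv.size(), idx[t]);
  }
  NumericMatrix out(n_test, n);
  for (int i = 0; i < n_test; ++i) {
    for (int t = 0; t < n_trees; ++t) {
      const LeafIndex &L = idx[t];
      const int nd = test_nodes(i, t);
      const double tot = L.node_tot[nd];
      if (tot <= 0) continue;
      for (int k = L.offset[nd]; k < L.offset[nd + 1]; ++k)
        out(i, L.item_row[k]) += L.item_cnt[k] / tot;
    }
    for (int j = 0; j < n; ++j) out(i, j) /= n_trees;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector qrf_mean_cpp(List trees, IntegerMatrix test_nodes) {
  const int n_test = test_nodes.nrow(), n_trees = trees.size();
  NumericVector out(n_test);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    NumericVector pr = tr["pred"];
    for (int i = 0; i < n_test; ++i) out[i] += pr[test_nodes(i, t)];
  }
  for (int i = 0; i < n_test; ++i) out[i] /= n_trees;
  return out;
}

// %IncMSE: per tree, relative increase in OOB MSE after permuting one
// feature among the OOB rows, averaged over trees, times 100.
// [[Rcpp::export]]
NumericVector qrf_perm_importance_cpp(List trees, NumericMatrix X,
                                      NumericVector y, IntegerMatrix inbag) {
  const int n = X.nrow(), p = X.ncol(), n_trees = trees.size();
  NumericVector inc(p);
  std::vector<int> used(p, 0);
  std::vector<int> oob;
  std::vector<double> xsave;
  NumericMatrix Xw(clone(X));
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector sv = tr["split_var"];
    NumericVector spl = tr["split_val"];
    IntegerVector lf = tr["left"], rg = tr["right"];
    NumericVector pr = tr["pred"];
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    const int m = (int)oob.size();
    if (m < 2) continue;
    double mse0 = 0.0;
    for (int k = 0; k < m; ++k) {
      const double e = y[oob[k]] - pr[drop_row(sv, spl, lf, rg, Xw, oob[k])];
      mse0 += e * e;
    }
    mse0 /= m;
    if (mse0 <= 0) continue;
    for (int j = 0; j < p; ++j) {
      // permutation of the OOB rows via R's RNG
      IntegerVector perm = Rcpp::sample(m, m, false); // 1-based
      xsave.assign(m, 0.0);
      for (int k = 0; k < m; ++k) xsave[k] = Xw(oob[k], j);
      for (int k = 0; k < m; ++k) Xw(oob[k], j) = xsave[perm[k] - 1];
      double mse1 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double e = y[oob[k]] - pr[drop_row(sv, spl, lf, rg, Xw, oob[k])];
        mse1 += e * e;
      }
      mse1 /= m;
      for (int k = 0; k < m; ++k) Xw(oob[k], j) = xsave[k];
      inc[j] += (mse1 - mse0) / mse0;
      used[j]++;
    }
  }
  for (int j = 0; j < p; ++j)
    inc[j] = used[j] > 0 ? 100.0 * inc[j] / used[j] : 0.0;
  return inc;
}
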
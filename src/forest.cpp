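#include <Rcpp.h>
using namespace Rcpp;

// Binary-classification forest for per-bird-day ARS habitat models.
// Each tree is grown on an independent random two-thirds subsample of the
// locations drawn WITHOUT replacement; the held-out third is that tree's
// validation set. Splits minimise Gini impurity over `mtry` predictors
// drawn at random at every node; trees grow to purity or to nodes of
// `min_node` locations. Variable importance is the impurity decrease
// (weighted by node size) summed over splits and averaged over trees.
// Uses R's RNG so results are reproducible under set.seed().

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<int> pred;      // leaf majority class (0/1)
};

static inline double gini(int n0, int n1) {
  double n = n0 + n1;
  if (n <= 0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

// draw k distinct integers from 0..n-1 (partial Fisher-Yates, R RNG)
static void sample_k(std::vector<int>& pool, int k) {
  int n = pool.size();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
}

static int grow_node(const NumericMatrix& X, const IntegerVector& y,
                     std::vector<int>& idx, int lo, int hi, int mtry,
                     int min_node, Tree& tree, std::vector<double>& imp,
                     std::vector<int>& featpool,
                     std::vector<std::pair<double, int>>& buf) {
  int nn = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  int n0 = nn - n1;
  int node = tree.feat.size();
  tree.feat.push_back(-1);
  tree.thr.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.pred.push_back(n1 * 2 > nn ? 1 : 0);
  if (n0 == 0 || n1 == 0 || nn <= min_node) return node;

  double gp = gini(n0, n1);
  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;
  sample_k(featpool, mtry);
  for (int f = 0; f < mtry; ++f) {
    int j = featpool[f];
    buf.clear();
    for (int i = lo; i < hi; ++i)
      buf.push_back(std::make_pair(X(idx[i], j), y[idx[i]]));
    std::sort(buf.begin(), buf.end());
    int l0 = 0, l1 = 0;
    for (int i = 0; i + 1 < nn; ++i) {
      if (buf[i].second) ++l1; else ++l0;
      if (buf[i + 1].first <= buf[i].first) continue;
      double gain = gp * nn - (l0 + l1) * gini(l0, l1) -
        (n0 - l0 + n1 - l1) * gini(n0 - l0, n1 - l1);
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (buf[i].first + buf[i + 1].first);
      }
    }
  }
  if (best_feat < 0) return node;

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  }
  if (mid == lo || mid == hi) return node;  // degenerate, keep as leaf

  imp[best_feat] += best_gain;
  tree.feat[node] = best_feat;
  tree.thr[node] = best_thr;
  int lchild = grow_node(X, y, idx, lo, mid, mtry, min_node, tree, imp,
                         featpool, buf);
  tree.left[node] = lchild;
  int rchild = grow_node(X, y, idx, mid, hi, mtry, min_node, tree, imp,
                         featpool, buf);
  tree.right[node] = rchild;
  return node;
}

static int predict_one(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.feat[node] >= 0) {
    node = (X(row, tree.feat[node]) <= tree.thr[node]) ? tree.left[node]
                                                       : tree.right[node];
  }
  return tree.pred[node];
}

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, double train_frac, bool keep_train_idx) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry must be in 1..ncol(X)");
  int ntrain = (int)std::floor(train_frac * n + 1e-9);
  if (ntrain < 2 || ntrain >= n)
    stop("train_frac leaves too few training or validation rows");

  std::vector<double> imp(p, 0.0);
  // held-out validation by vote aggregation: each row is predicted by the
  // majority vote of the trees that did NOT train on it
  std::vector<int> oob_votes1(n, 0), oob_total(n, 0);
  List trees(ntree);
  List train_sets(keep_train_idx ? ntree : 0);
  std::vector<int> rows(n), featpool(p);
  std::vector<std::pair<double, int>> buf;
  buf.reserve(n);

  for (int b = 0; b < ntree; ++b) {
    for (int i = 0; i < n; ++i) rows[i] = i;
    for (int i = 0; i < p; ++i) featpool[i] = i;
    sample_k(rows, ntrain);
    std::vector<int> train(rows.begin(), rows.begin() + ntrain);
    Tree tree;
    std::vector<int> idx(train);
    grow_node(X, y, idx, 0, idx.size(), mtry, min_node, tree, imp,
              featpool, buf);
    // held-out votes
    for (int i = ntrain; i < n; ++i) {
      oob_votes1[rows[i]] += predict_one(tree, X, rows[i]);
      oob_total[rows[i]] += 1;
    }
    trees[b] = List::create(
      _["feat"] = IntegerVector(tree.feat.begin(), tree.feat.end()),
      _["thr"] = NumericVector(tree.thr.begin(), tree.thr.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["pred"] = IntegerVector(tree.pred.begin(), tree.pred.end()));
    if (keep_train_idx) {
      train_sets[b] = IntegerVector(train.begin(), train.end());
    }
  }
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / ntree;
  int tp = 0, fn = 0, tn = 0, fp = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_total[i] == 0) continue;
    int pred = (2 * oob_votes1[i] > oob_total[i]) ? 1 : 0;
    if (y[i] == 1) { if (pred == 1) ++tp; else ++fn; }
    else { if (pred == 0) ++tn; else ++fp; }
  }
  return List::create(
    _["trees"] = trees,
    _["importance"] = importance,
    _["sensitivity"] = (tp + fn) ? (double)tp / (tp + fn) : NA_REAL,
    _["specificity"] = (tn + fp) ? (double)tn / (tn + fp) : NA_REAL,
    _["accuracy"] = (tp + fn + tn + fp)
        ? (double)(tp + tn) / (tp + fn + tn + fp) : NA_REAL,
    _["train_idx"] = train_sets);
}

// Ensemble vote fraction for class 1 at each row of X.
// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List tl = trees[b];
    Tree tree;
    IntegerVector feat = tl["feat"];
    NumericVector thr = tl["thr"];
    IntegerVector left = tl["left"], right = tl["right"], pred = tl["pred"];
    tree.feat.assign(feat.begin(), feat.end());
    tree.thr.assign(thr.begin(), thr.end());
    tree.left.assign(left.begin(), left.end());
    tree.right.assign(right.begin(), right.end());
    tree.pred.assign(pred.begin(), pred.end());
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  return out / (double)B;
}
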
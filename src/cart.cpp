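#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// A decision tree is a flat node table (one row per node, row 1 = root):
//   feature   column index in X (1-based); 0 marks a leaf
//   threshold split value; samples with x <= threshold go left; NA at leaves
//   left, right  child row indices (1-based); 0 at leaves
//   label     -1/+1 at leaves; 0 at internal nodes
// Growth is deterministic given (X, y, pool): greedy Gini minimisation,
// candidate thresholds are midpoints between consecutive distinct sorted
// values, ties broken by lower feature index then lower threshold.

namespace {

struct Node {
  int feature;      // 1-based column in X, 0 = leaf
  double threshold;
  int left, right;  // 1-based node ids, 0 = leaf
  int label;        // -1/+1 at leaves
};

struct Split {
  bool found;
  int feature;      // 1-based
  double threshold;
  double impurity;  // weighted Gini of the two children
};

int majority_label(const IntegerVector& y, const std::vector<int>& idx) {
  int pos = 0;
  for (int i : idx) if (y[i] > 0) ++pos;
  int neg = (int)idx.size() - pos;
  return pos >= neg ? 1 : -1;  // tie -> +1 (HC)
}

bool is_pure(const IntegerVector& y, const std::vector<int>& idx) {
  for (size_t i = 1; i < idx.size(); ++i)
    if (y[idx[i]] != y[idx[0]]) return false;
  return true;
}

// Best split over the feature pool for the samples in idx.
Split best_split(const NumericMatrix& X, const IntegerVector& y,
                 const std::vector<int>& pool, const std::vector<int>& idx,
                 int min_leaf) {
  Split best;
  best.found = false;
  best.impurity = R_PosInf;
  const int n = (int)idx.size();
  std::vector<double> xv(n);
  std::vector<int> ord(n), yv(n);

  for (int f : pool) {  // pool is sorted ascending: ties -> lower feature wins
    for (int i = 0; i < n; ++i) {
      xv[i] = X(idx[i], f);
      yv[i] = y[idx[i]];
      ord[i] = i;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    // prefix counts of +1 over the sorted order
    int total_pos = 0;
    for (int i = 0; i < n; ++i) if (yv[i] > 0) ++total_pos;
    int left_pos = 0;
    for (int t = 0; t < n - 1; ++t) {
      if (yv[ord[t]] > 0) ++left_pos;
      double lo = xv[ord[t]], hi = xv[ord[t + 1]];
      if (lo >= hi) continue;  // not a boundary between distinct values
      int nl = t + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double plp = (double)left_pos / nl;
      double prp = (double)(total_pos - left_pos) / nr;
      double gini = nl * (1.0 - plp * plp - (1.0 - plp) * (1.0 - plp)) +
                    nr * (1.0 - prp * prp - (1.0 - prp) * (1.0 - prp));
      // strict < keeps the first optimum: lowest feature, lowest threshold
      if (gini < best.impurity) {
        best.found = true;
        best.impurity = gini;
        best.feature = f + 1;
        best.threshold = (lo + hi) / 2.0;
      }
    }
  }
  return best;
}

int grow(std::vector<Node>& nodes, const NumericMatrix& X,
         const IntegerVector& y, const std::vector<int>& pool,
         const std::vector<int>& idx, int depth, int max_depth, int min_leaf) {
  nodes.push_back(Node());
  int self = (int)nodes.size();  // 1-based id
  if (depth >= max_depth || (int)idx.size() < 2 * min_leaf ||
      is_pure(y, idx)) {
    nodes[self - 1] = {0, NA_REAL, 0, 0, majority_label(y, idx)};
    return self;
  }
  Split s = best_split(X, y, pool, idx, min_leaf);
  if (!s.found) {  // all pooled features constant on idx
    nodes[self - 1] = {0, NA_REAL, 0, 0, majority_label(y, idx)};
    return self;
  }
  std::vector<int> lidx, ridx;
  for (int i : idx) {
    if (X(i, s.feature - 1) <= s.threshold) lidx.push_back(i);
    else ridx.push_back(i);
  }
  int l = grow(nodes, X, y, pool, lidx, depth + 1, max_depth, min_leaf);
  int r = grow(nodes, X, y, pool, ridx, depth + 1, max_depth, min_leaf);
  nodes[self - 1] = {s.feature, s.threshold, l, r, 0};
  return self;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_grow_tree(NumericMatrix X, IntegerVector y,
                            IntegerVector pool, int max_depth, int min_leaf) {
  if (X.nrow() == 0) stop("empty training data");
  if (X.nrow() != y.size()) stop("X rows and y length differ");
  std::vector<int> pool0(pool.begin(), pool.end());
  for (int& p : pool0) {
    if (p < 1 || p > X.ncol()) stop("feature pool index out of range");
    --p;  // to 0-based
  }
  std::sort(pool0.begin(), pool0.end());
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;

  std::vector<Node> nodes;
  grow(nodes, X, y, pool0, idx, 0, max_depth, min_leaf);

  NumericMatrix out((int)nodes.size(), 5);
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "label");
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].feature;
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left;
    out(i, 3) = nodes[i].right;
    out(i, 4) = nodes[i].label;
  }
  return out;
}

// Route each row of X to its leaf; returns the 1-based leaf node id.
// [[Rcpp::export]]
IntegerVector cpp_route(NumericMatrix nodes, NumericMatrix X) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    int cur = 1, guard = 0;
    while (nodes(cur - 1, 0) != 0) {
      int f = (int)nodes(cur - 1, 0);
      double thr = nodes(cur - 1, 1);
      cur = X(r, f - 1) <= thr ? (int)nodes(cur - 1, 2)
                               : (int)nodes(cur - 1, 3);
      if (cur < 1 || cur > nodes.nrow() || ++guard > nodes.nrow())
        stop("malformed node table");
    }
    out[r] = cur;
  }
  return out;
}
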
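// Nearest-centre assignment of descriptors to a visual dictionary:
// exhaustive vector quantization and a k-d tree that recursively splits on
// the dimension of maximum variance.  Both use squared Euclidean distance
// with ties broken towards the lowest centre index; with unlimited
// backtracking the tree is exact and must agree with the exhaustive scan.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

namespace {

inline double sqdist(const double* a, const double* b, int p) {
  double s = 0.0;
  for (int j = 0; j < p; ++j) { double d = a[j] - b[j]; s += d * d; }
  return s;
}

struct KdNode {
  int dim;        // split dimension (internal nodes)
  double split;   // split value
  int left, right;
  int start, end; // leaf: index range into `order`
};

struct KdTree {
  std::vector<KdNode> nodes;
  std::vector<int> order;
  const double* pts;
  int p;
  int leaf_size;

  int build(int start, int end) {
    KdNode nd;
    nd.left = nd.right = -1;
    nd.start = start;
    nd.end = end;
    nd.dim = -1;
    nd.split = 0.0;
    int n = end - start;
    if (n <= leaf_size) {
      // keep leaf points in ascending index order so tie scans are tidy
      std::sort(order.begin() + start, order.begin() + end);
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    // dimension of maximum variance over this subset
    int bd = 0;
    double bv = -1.0;
    for (int j = 0; j < p; ++j) {
      double m = 0.0, m2 = 0.0;
      for (int i = start; i < end; ++i) {
        double v = pts[(size_t)order[i] * p + j];
        m += v; m2 += v * v;
      }
      m /= n;
      double var = m2 / n - m * m;
      if (var > bv) { bv = var; bd = j; }
    }
    if (bv <= 0.0) { // all points identical: make a leaf
      std::sort(order.begin() + start, order.begin() + end);
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    int mid = start + n / 2;
    const double* P = pts;
    int pp = p, dd = bd;
    std::nth_element(order.begin() + start, order.begin() + mid, order.begin() + end,
                     [P, pp, dd](int a, int b) {
                       return P[(size_t)a * pp + dd] < P[(size_t)b * pp + dd];
                     });
    nd.dim = bd;
    nd.split = pts[(size_t)order[mid] * p + bd];
    int self = (int)nodes.size();
    nodes.push_back(nd);
    int l = build(start, mid);
    int r = build(mid, end);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  void search(int node, const double* q, double& best_d, int& best_i,
              long& comparisons, long budget) const {
    const KdNode& nd = nodes[node];
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.end; ++i) {
        int idx = order[i];
        double d = sqdist(q, pts + (size_t)idx * p, p);
        ++comparisons;
        if (d < best_d || (d == best_d && idx < best_i)) { best_d = d; best_i = idx; }
      }
      return;
    }
    double diff = q[nd.dim] - nd.split;
    int near = diff < 0.0 ? nd.left : nd.right;
    int far = diff < 0.0 ? nd.right : nd.left;
    search(near, q, best_d, best_i, comparisons, budget);
    // <= so equidistant branches are still explored (exact tie handling)
    if (comparisons < budget && diff * diff <= best_d)
      search(far, q, best_d, best_i, comparisons, budget);
  }
};

} // namespace

// Exhaustive nearest-centre assignment; 1-based indices.
// [[Rcpp::export]]
IntegerVector vq_assign_cpp(NumericMatrix desc, NumericMatrix centres) {
  int n = desc.nrow(), k = centres.nrow(), p = desc.ncol();
  if (centres.ncol() != p) stop("descriptor/centre dimension mismatch");
  // row-major copies for cache-friendly scans
  std::vector<double> D((size_t)n * p), C((size_t)k * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) D[(size_t)i * p + j] = desc(i, j);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < p; ++j) C[(size_t)i * p + j] = centres(i, j);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bi = -1;
    const double* q = D.data() + (size_t)i * p;
    for (int c = 0; c < k; ++c) {
      double d = sqdist(q, C.data() + (size_t)c * p, p);
      if (d < best || (d == best && c < bi)) { best = d; bi = c; }
    }
    out[i] = bi + 1;
  }
  return out;
}

// k-d tree nearest-centre assignment.  max_comparisons <= 0 means unlimited
// backtracking (exact search).  Returns 1-based assignments plus the number
// of point comparisons spent per descriptor.
// [[Rcpp::export]]
List kdtree_assign_cpp(NumericMatrix desc, NumericMatrix centres,
                       int max_comparisons, int leaf_size) {
  int n = desc.nrow(), k = centres.nrow(), p = desc.ncol();
  if (centres.ncol() != p) stop("descriptor/centre dimension mismatch");
  std::vector<double> D((size_t)n * p), C((size_t)k * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) D[(size_t)i * p + j] = desc(i, j);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < p; ++j) C[(size_t)i * p + j] = centres(i, j);

  KdTree tree;
  tree.pts = C.data();
  tree.p = p;
  tree.leaf_size = leaf_size < 1 ? 1 : leaf_size;
  tree.order.resize(k);
  for (int i = 0; i < k; ++i) tree.order[i] = i;
  int root = tree.build(0, k);

  long budget = max_comparisons <= 0 ? std::numeric_limits<long>::max() : (long)max_comparisons;
  IntegerVector out(n);
  IntegerVector ncmp(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bi = -1;
    long comparisons = 0;
    tree.search(root, D.data() + (size_t)i * p, best, bi, comparisons, budget);
    out[i] = bi + 1;
    ncmp[i] = (int)std::min<long>(comparisons, std::numeric_limits<int>::max());
  }
  return List::create(_["assignments"] = out, _["comparisons"] = ncmp);
}
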
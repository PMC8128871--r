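// One-vs-rest linear SVM trained by stochastic gradient descent on the
// primal hinge-loss + L2 objective (Pegasos: eta_t = 1/(lambda t) with
// projection onto the ball of radius 1/sqrt(lambda)).  The bias is
// unregularized and follows its own 1/t step so the solver is exactly
// equivariant under input scaling with matched lambda.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// X: n x p feature matrix; y: 1-based class ids (1..K);
// order: n x epochs matrix of 1-based visit orders (the shuffles).
// Returns weights (K x p), biases (K), and the full primal objective
// (summed over the K binary problems) evaluated at each epoch end.
// [[Rcpp::export]]
List svm_sgd_cpp(NumericMatrix X, IntegerVector y, int K, double lambda,
                 IntegerMatrix order, double eta_bias) {
  int n = X.nrow(), p = X.ncol(), epochs = order.ncol();
  if (order.nrow() != n) stop("order matrix must have one row per sample");
  std::vector<double> W((size_t)K * p, 0.0), b(K, 0.0);
  std::vector<double> xs(p);
  NumericVector objective(epochs);
  const double radius = 1.0 / std::sqrt(lambda);
  double t = 0.0;

  for (int e = 0; e < epochs; ++e) {
    for (int ii = 0; ii < n; ++ii) {
      int i = order(ii, e) - 1;
      t += 1.0;
      double eta = 1.0 / (lambda * t);
      double shrink = 1.0 - eta * lambda; // = 1 - 1/t
      for (int j = 0; j < p; ++j) xs[j] = X(i, j);
      for (int k = 0; k < K; ++k) {
        double yy = (y[i] == k + 1) ? 1.0 : -1.0;
        double* w = W.data() + (size_t)k * p;
        double m = b[k];
        for (int j = 0; j < p; ++j) m += w[j] * xs[j];
        m *= yy;
        for (int j = 0; j < p; ++j) w[j] *= shrink;
        if (m < 1.0) {
          double step = eta * yy;
          for (int j = 0; j < p; ++j) w[j] += step * xs[j];
          b[k] += eta_bias / t * yy;
        }
        double nrm = 0.0;
        for (int j = 0; j < p; ++j) nrm += w[j] * w[j];
        nrm = std::sqrt(nrm);
        if (nrm > radius) {
          double sc = radius / nrm;
          for (int j = 0; j < p; ++j) w[j] *= sc;
        }
      }
    }
    // primal objective at epoch end, summed over binary problems
    double obj = 0.0;
    for (int k = 0; k < K; ++k) {
      const double* w = W.data() + (size_t)k * p;
      double reg = 0.0;
      for (int j = 0; j < p; ++j) reg += w[j] * w[j];
      double hinge = 0.0;
      for (int i = 0; i < n; ++i) {
        double yy = (y[i] == k + 1) ? 1.0 : -1.0;
        double m = b[k];
        for (int j = 0; j < p; ++j) m += w[j] * X(i, j);
        double l = 1.0 - yy * m;
        if (l > 0.0) hinge += l;
      }
      obj += 0.5 * lambda * reg + hinge / n;
    }
    objective[e] = obj;
  }

  NumericMatrix Wm(K, p);
  NumericVector bv(K);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < p; ++j) Wm(k, j) = W[(size_t)k * p + j];
    bv[k] = b[k];
  }
  return List::create(_["weights"] = Wm, _["biases"] = bv,
                      _["objective"] = objective);
}
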
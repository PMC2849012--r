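#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Linear soft-margin SVM trained by dual coordinate descent on the L1-loss
// dual. Sweeps visit samples in a deterministically seeded pseudo-random
// permutation (fresh xorshift stream per fit), so results are bit-
// reproducible while converging much faster than cyclic order. The bias is
// handled by augmenting each sample with a constant feature of 1, so it is
// weakly regularized together with w (liblinear's -B 1 convention).
//
// Primal objective: 0.5 * ||w||^2 + C * sum_i max(0, 1 - y_i * w . x_i)

namespace {

struct XorShift32 {
  uint32_t state;
  explicit XorShift32(uint32_t seed) : state(seed ? seed : 1u) {}
  uint32_t next() {
    uint32_t x = state;
    x ^= x << 13; x ^= x >> 17; x ^= x << 5;
    return state = x;
  }
  // uniform on [0, n)
  uint32_t below(uint32_t n) { return next() % n; }
};

struct DcdFit {
  std::vector<double> w;  // length d (bias is the last augmented column)
  bool converged;
  int iterations;
};

// X: row-major n x d (bias column included), y in {-1, +1}
DcdFit dcd_train(const double* X, int n, int d, const double* y,
                 double C, double tol, int max_iter) {
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = X + (size_t)i * d;
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qii[i] = s;
    order[i] = i;
  }
  XorShift32 rng(2463534242u);
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.below(i + 1)]);
    double max_pg = 0.0;
    for (int k = 0; k < n; ++k) {
      const int i = order[k];
      if (qii[i] <= 0.0) continue;  // all-zero sample carries no constraint
      const double* xi = X + (size_t)i * d;
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * xi[j];
      g = y[i] * g - 1.0;
      double pg;
      if (alpha[i] <= 0.0)      pg = std::min(g, 0.0);
      else if (alpha[i] >= C)   pg = std::max(g, 0.0);
      else                      pg = g;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C)   a_new = C;
        alpha[i] = a_new;
        const double delta = (a_new - a_old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
      }
    }
    if (max_pg < tol) { converged = true; ++iter; break; }
  }
  DcdFit fit;
  fit.w = w;
  fit.converged = converged;
  fit.iterations = iter;
  return fit;
}

// Gather rows/columns of an R matrix into a flat row-major buffer with a
// trailing bias column, optionally standardizing by center/scale.
void gather_rows(const NumericMatrix& X,
                 const std::vector<int>& row_idx,
                 const std::vector<int>& col_idx,
                 const std::vector<double>& center,
                 const std::vector<double>& scale,
                 std::vector<double>& out) {
  const int p = col_idx.size();
  const int d = p + 1;
  out.assign(row_idx.size() * d, 1.0);
  for (size_t r = 0; r < row_idx.size(); ++r) {
    double* dst = &out[r * d];
    for (int j = 0; j < p; ++j)
      dst[j] = (X(row_idx[r], col_idx[j]) - center[j]) / scale[j];
  }
}

void train_stats(const NumericMatrix& X,
                 const std::vector<int>& row_idx,
                 const std::vector<int>& col_idx,
                 bool zscore,
                 std::vector<double>& center,
                 std::vector<double>& scale) {
  const int p = col_idx.size();
  center.assign(p, 0.0);
  scale.assign(p, 1.0);
  if (!zscore || row_idx.size() < 2) return;
  const double n = row_idx.size();
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (size_t r = 0; r < row_idx.size(); ++r) m += X(row_idx[r], col_idx[j]);
    m /= n;
    double v = 0.0;
    for (size_t r = 0; r < row_idx.size(); ++r) {
      double dx = X(row_idx[r], col_idx[j]) - m;
      v += dx * dx;
    }
    v /= (n - 1.0);
    center[j] = m;
    scale[j] = (v > 1e-24) ? std::sqrt(v) : 1.0;
  }
}

// One-vs-one multiclass prediction. classes are the distinct training
// labels in increasing order. Vote ties are broken by the largest summed
// signed pairwise margin, then by the lowest class id.
void ovo_fit_predict(const NumericMatrix& X,
                     const IntegerVector& y,
                     const std::vector<int>& train_idx,
                     const std::vector<int>& test_idx,
                     const std::vector<int>& col_idx,
                     double C, double tol, int max_iter, bool zscore,
                     std::vector<int>& pred) {
  std::vector<int> classes;
  for (size_t r = 0; r < train_idx.size(); ++r) {
    int lab = y[train_idx[r]];
    if (std::find(classes.begin(), classes.end(), lab) == classes.end())
      classes.push_back(lab);
  }
  std::sort(classes.begin(), classes.end());
  const int K = classes.size();
  if (K < 2) stop("training fold contains a single class");

  const int d = col_idx.size() + 1;
  std::vector<double> center, scale, test_rows, pair_rows, pair_y;
  train_stats(X, train_idx, col_idx, zscore, center, scale);
  gather_rows(X, test_idx, col_idx, center, scale, test_rows);

  const int n_test = test_idx.size();
  std::vector<std::vector<int> > votes(n_test, std::vector<int>(K, 0));
  std::vector<std::vector<double> > margin(n_test, std::vector<double>(K, 0.0));
  std::vector<int> pair_idx;

  for (int a = 0; a < K; ++a) {
    for (int b = a + 1; b < K; ++b) {
      pair_idx.clear();
      pair_y.clear();
      for (size_t r = 0; r < train_idx.size(); ++r) {
        int lab = y[train_idx[r]];
        if (lab == classes[a]) { pair_idx.push_back(train_idx[r]); pair_y.push_back(1.0); }
        else if (lab == classes[b]) { pair_idx.push_back(train_idx[r]); pair_y.push_back(-1.0); }
      }
      gather_rows(X, pair_idx, col_idx, center, scale, pair_rows);
      DcdFit fit = dcd_train(pair_rows.data(), pair_idx.size(), d,
                             pair_y.data(), C, tol, max_iter);
      for (int t = 0; t < n_test; ++t) {
        const double* xt = &test_rows[(size_t)t * d];
        double f = 0.0;
        for (int j = 0; j < d; ++j) f += fit.w[j] * xt[j];
        if (f >= 0.0) votes[t][a] += 1; else votes[t][b] += 1;
        margin[t][a] += f;
        margin[t][b] -= f;
      }
    }
  }
  pred.assign(n_test, classes[0]);
  for (int t = 0; t < n_test; ++t) {
    int best = 0;
    for (int k = 1; k < K; ++k) {
      if (votes[t][k] > votes[t][best] ||
          (votes[t][k] == votes[t][best] && margin[t][k] > margin[t][best])) {
        best = k;  // equal votes and equal margin keep the lower class id
      }
    }
    pred[t] = classes[best];
  }
}

std::vector<int> as_cols(const IntegerVector& cols1) {
  std::vector<int> out(cols1.size());
  for (int j = 0; j < cols1.size(); ++j) out[j] = cols1[j] - 1;
  return out;
}

double cv_accuracy(const NumericMatrix& X, const IntegerVector& y,
                   const IntegerVector& fold, const std::vector<int>& col_idx,
                   double C, double tol, int max_iter, bool zscore) {
  const int n = X.nrow();
  int n_folds = 0;
  for (int i = 0; i < n; ++i) if (fold[i] > n_folds) n_folds = fold[i];
  int correct = 0;
  std::vector<int> train_idx, test_idx, pred;
  for (int f = 1; f <= n_folds; ++f) {
    train_idx.clear();
    test_idx.clear();
    for (int i = 0; i < n; ++i)
      (fold[i] == f ? test_idx : train_idx).push_back(i);
    if (test_idx.empty()) continue;
    ovo_fit_predict(X, y, train_idx, test_idx, col_idx, C, tol, max_iter,
                    zscore, pred);
    for (size_t t = 0; t < pred.size(); ++t)
      if (pred[t] == y[test_idx[t]]) ++correct;
  }
  return static_cast<double>(correct) / n;
}

}  // namespace

// [[Rcpp::export]]
List cpp_svm_train(NumericMatrix X, NumericVector y,
                   double C, double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> rows((size_t)n * (p + 1), 1.0), yy(n);
  for (int i = 0; i < n; ++i) {
    yy[i] = y[i];
    for (int j = 0; j < p; ++j) rows[(size_t)i * (p + 1) + j] = X(i, j);
  }
  DcdFit fit = dcd_train(rows.data(), n, p + 1, yy.data(), C, tol, max_iter);
  NumericVector w(p);
  for (int j = 0; j < p; ++j) w[j] = fit.w[j];
  return List::create(_["w"] = w,
                      _["bias"] = fit.w[p],
                      _["converged"] = fit.converged,
                      _["iterations"] = fit.iterations);
}

// Predict labels of rows `test` (1-based) using a one-vs-one model trained
// on rows `train` (1-based), restricted to columns `cols` (1-based).
// [[Rcpp::export]]
IntegerVector cpp_ovo_predict(NumericMatrix X, IntegerVector y,
                              IntegerVector train, IntegerVector test,
                              IntegerVector cols,
                              double C, double tol, int max_iter,
                              bool zscore) {
  std::vector<int> train_idx(train.size()), test_idx(test.size());
  for (int i = 0; i < train.size(); ++i) train_idx[i] = train[i] - 1;
  for (int i = 0; i < test.size(); ++i) test_idx[i] = test[i] - 1;
  std::vector<int> col_idx = as_cols(cols);
  std::vector<int> pred;
  ovo_fit_predict(X, y, train_idx, test_idx, col_idx, C, tol, max_iter,
                  zscore, pred);
  return wrap(pred);
}

// Cross-validated one-vs-one accuracy over a fold assignment (1-based fold
// ids; every fold is tested once against the remaining folds).
// [[Rcpp::export]]
double cpp_ovo_cv_accuracy(NumericMatrix X, IntegerVector y,
                           IntegerVector fold, IntegerVector cols,
                           double C, double tol, int max_iter, bool zscore) {
  return cv_accuracy(X, y, fold, as_cols(cols), C, tol, max_iter, zscore);
}

// Searchlight scoring: for each neighborhood (list of 1-based column index
// vectors) compute the inner cross-validated one-vs-one accuracy.
// Neighborhoods smaller than min_neighborhood score 0.
// [[Rcpp::export]]
NumericVector cpp_searchlight_scores(NumericMatrix X, IntegerVector y,
                                     List neighborhoods, IntegerVector fold,
                                     double C, double tol, int max_iter,
                                     bool zscore, int min_neighborhood) {
  const int V = neighborhoods.size();
  NumericVector scores(V);
  for (int v = 0; v < V; ++v) {
    IntegerVector cols = neighborhoods[v];
    if (cols.size() < min_neighborhood) { scores[v] = 0.0; continue; }
    scores[v] = cv_accuracy(X, y, fold, as_cols(cols), C, tol, max_iter,
                            zscore);
  }
  return scores;
}
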
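#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted L1 distance matrix: D[i,j] = sum_k w_k^2 |X[i,k] - X[j,k]|.
static void weighted_l1(const NumericMatrix& X, const NumericVector& w,
                        NumericMatrix& D) {
  int n = X.nrow(), p = X.ncol();
  std::fill(D.begin(), D.end(), 0.0);
  for (int k = 0; k < p; ++k) {
    double wk2 = w[k] * w[k];
    if (wk2 == 0.0) continue;
    const double* xk = &X(0, k);
    for (int j = 0; j < n; ++j) {
      double xjk = xk[j];
      double* dj = &D(0, j);
      for (int i = j + 1; i < n; ++i) {
        double a = wk2 * std::fabs(xk[i] - xjk);
        dj[i] += a;
      }
    }
  }
  for (int j = 0; j < n; ++j)
    for (int i = j + 1; i < n; ++i)
      D(j, i) = D(i, j);
}

// Reference-point probabilities gamma[i,j] = k(D_ij)/sum_{l!=i} k(D_il),
// kernel k(z) = exp(-z/sigma), computed stably via per-row min subtraction.
static void gamma_rows(const NumericMatrix& D, double sigma,
                       NumericMatrix& G) {
  int n = D.nrow();
  for (int i = 0; i < n; ++i) {
    double dmin = R_PosInf;
    for (int j = 0; j < n; ++j)
      if (j != i && D(i, j) < dmin) dmin = D(i, j);
    double tot = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) { G(i, j) = 0.0; continue; }
      double e = std::exp(-(D(i, j) - dmin) / sigma);
      G(i, j) = e;
      tot += e;
    }
    for (int j = 0; j < n; ++j)
      if (j != i) G(i, j) /= tot;
  }
}

// Leave-one-out NCA regression loss. Lmat[i,j] = loss(y_i, y_j) precomputed
// in R. Returns per-sample losses L_i and the gamma matrix.
// [[Rcpp::export]]
List nca_loss_cpp(NumericMatrix X, NumericVector w, NumericMatrix Lmat,
                  double sigma) {
  int n = X.nrow();
  NumericMatrix D(n, n), G(n, n);
  weighted_l1(X, w, D);
  gamma_rows(D, sigma, G);
  NumericVector Li(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += G(i, j) * Lmat(i, j);
    Li[i] = s;
  }
  return List::create(_["Li"] = Li, _["gamma"] = G);
}

// Objective F(w) = mean_i L_i + lambda * sum w^2 and its exact gradient.
// dF/dw_k = -(2 w_k / (n sigma)) * sum_{i,j} gamma_ij (Lmat_ij - L_i)
//           |x_ik - x_jk|  + 2 lambda w_k
// [[Rcpp::export]]
List nca_obj_grad_cpp(NumericMatrix X, NumericVector w, NumericMatrix Lmat,
                      double sigma, double lambda) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix D(n, n), G(n, n);
  weighted_l1(X, w, D);
  gamma_rows(D, sigma, G);

  NumericVector Li(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += G(i, j) * Lmat(i, j);
    Li[i] = s;
  }
  double obj = 0.0;
  for (int i = 0; i < n; ++i) obj += Li[i];
  obj /= n;
  double pen = 0.0;
  for (int k = 0; k < p; ++k) pen += w[k] * w[k];
  obj += lambda * pen;

  // S = B + B^T with B_ij = gamma_ij (Lmat_ij - L_i); |x diff| is symmetric
  NumericMatrix S(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double b = G(i, j) * (Lmat(i, j) - Li[i]);
      S(i, j) += b;
      S(j, i) += b;
    }

  NumericVector grad(p);
  for (int k = 0; k < p; ++k) {
    const double* xk = &X(0, k);
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      double xjk = xk[j];
      const double* sj = &S(0, j);
      for (int i = j + 1; i < n; ++i)
        acc += sj[i] * std::fabs(xk[i] - xjk);
    }
    grad[k] = -(2.0 * w[k] / (n * sigma)) * acc + 2.0 * lambda * w[k];
  }
  return List::create(_["objective"] = obj, _["gradient"] = grad,
                      _["Li"] = Li);
}

// Validation loss of a fitted weight vector: for each validation row v,
// gamma over the training rows, L_v = sum_j gamma_vj loss(yv_v, ytr_j).
// [[Rcpp::export]]
NumericVector nca_predict_loss_cpp(NumericMatrix Xtr, NumericMatrix Xva,
                                   NumericMatrix Lva, NumericVector w,
                                   double sigma) {
  int ntr = Xtr.nrow(), nva = Xva.nrow(), p = Xtr.ncol();
  NumericVector out(nva);
  std::vector<double> d(ntr);
  for (int v = 0; v < nva; ++v) {
    std::fill(d.begin(), d.end(), 0.0);
    for (int k = 0; k < p; ++k) {
      double wk2 = w[k] * w[k];
      if (wk2 == 0.0) continue;
      double xv = Xva(v, k);
      const double* xk = &Xtr(0, k);
      for (int j = 0; j < ntr; ++j)
        d[j] += wk2 * std::fabs(xk[j] - xv);
    }
    double dmin = *std::min_element(d.begin(), d.end());
    double tot = 0.0, acc = 0.0;
    for (int j = 0; j < ntr; ++j) {
      double e = std::exp(-(d[j] - dmin) / sigma);
      tot += e;
      acc += e * Lva(v, j);
    }
    out[v] = acc / tot;
  }
  return out;
}

// Soft-neighbor prediction for validation rows: yhat_v = sum_j gamma_vj y_j.
// [[Rcpp::export]]
NumericVector nca_predict_cpp(NumericMatrix Xtr, NumericMatrix Xva,
                              NumericVector ytr, NumericVector w,
                              double sigma) {
  int ntr = Xtr.nrow(), nva = Xva.nrow(), p = Xtr.ncol();
  NumericVector out(nva);
  std::vector<double> d(ntr);
  for (int v = 0; v < nva; ++v) {
    std::fill(d.begin(), d.end(), 0.0);
    for (int k = 0; k < p; ++k) {
      double wk2 = w[k] * w[k];
      if (wk2 == 0.0) continue;
      double xv = Xva(v, k);
      const double* xk = &Xtr(0, k);
      for (int j = 0; j < ntr; ++j)
        d[j] += wk2 * std::fabs(xk[j] - xv);
    }
    double dmin = *std::min_element(d.begin(), d.end());
    double tot = 0.0, acc = 0.0;
    for (int j = 0; j < ntr; ++j) {
      double e = std::exp(-(d[j] - dmin) / sigma);
      tot += e;
      acc += e * ytr[j];
    }
    out[v] = acc / tot;
  }
  return out;
}
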
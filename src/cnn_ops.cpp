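// Hot layer primitives of the window classifier. Activations are column-major
// arrays of shape (M, L, C): M = electrode-rows folded into the batch, L =
// temporal length, C = feature channels. Convolution kernels are (k, C, F)
// and slide along time only with "same"-style padding.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int out_len(int L, int stride) { return (L + stride - 1) / stride; }

// im2col: A is (M*Lo) x (k*C), column (j + k*c) holds x[m, t*stride+j-pl, c]
// (zero where the padded input position falls outside the signal).
static void im2col(const double *xp, double *A, int M, int L, int C,
                   int k, int Lo, int stride, int pl) {
  const R_xlen_t rows = (R_xlen_t)M * Lo;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      double *col = A + rows * (j + (R_xlen_t)k * c);
      for (int t = 0; t < Lo; ++t) {
        int p = t * stride + j - pl;
        double *dst = col + (R_xlen_t)M * t;
        if (p < 0 || p >= L) {
          std::fill(dst, dst + M, 0.0);
        } else {
          const double *src = xp + (R_xlen_t)M * (p + (R_xlen_t)L * c);
          std::copy(src, src + M, dst);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv1d_fwd_cpp(NumericVector x, NumericVector W,
                             NumericVector b, int stride) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  int M = xd[0], L = xd[1], C = xd[2];
  int k = wd[0], F = wd[2];
  int Lo = out_len(L, stride);
  int pad = std::max((Lo - 1) * stride + k - L, 0);
  int pl = pad / 2;
  const int rows = M * Lo, kc = k * C;
  std::vector<double> A((R_xlen_t)rows * kc);
  im2col(REAL(x), A.data(), M, L, C, k, Lo, stride, pl);
  NumericVector out((R_xlen_t)rows * F);
  out.attr("dim") = IntegerVector::create(M, Lo, F);
  const double one = 1.0, zero = 0.0;
  // out = A %*% Wmat, Wmat is W reshaped (k*C) x F (layouts coincide)
  F77_CALL(dgemm)("N", "N", &rows, &F, &kc, &one, A.data(), &rows,
                  REAL(W), &kc, &zero, REAL(out), &rows FCONE FCONE);
  double *op = REAL(out);
  for (int f = 0; f < F; ++f) {
    double bf = b[f];
    double *o = op + (R_xlen_t)rows * f;
    for (int i = 0; i < rows; ++i) o[i] += bf;
  }
  return out;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(NumericVector x, NumericVector W, NumericVector dy,
                    int stride) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  int M = xd[0], L = xd[1], C = xd[2];
  int k = wd[0], F = wd[2];
  int Lo = out_len(L, stride);
  int pad = std::max((Lo - 1) * stride + k - L, 0);
  int pl = pad / 2;
  const int rows = M * Lo, kc = k * C;
  std::vector<double> A((R_xlen_t)rows * kc), dA((R_xlen_t)rows * kc);
  im2col(REAL(x), A.data(), M, L, C, k, Lo, stride, pl);
  NumericVector dx((R_xlen_t)M * L * C), dW(W.size()), db(F);
  dx.attr("dim") = xd;
  dW.attr("dim") = wd;
  const double one = 1.0, zero = 0.0;
  double *dyp = REAL(dy);
  // dW = A^T %*% dy ; dA = dy %*% W^T
  F77_CALL(dgemm)("T", "N", &kc, &F, &rows, &one, A.data(), &rows,
                  dyp, &rows, &zero, REAL(dW), &kc FCONE FCONE);
  F77_CALL(dgemm)("N", "T", &rows, &kc, &F, &one, dyp, &rows,
                  REAL(W), &kc, &zero, dA.data(), &rows FCONE FCONE);
  for (int f = 0; f < F; ++f) {
    double acc = 0.0;
    const double *d = dyp + (R_xlen_t)rows * f;
    for (int i = 0; i < rows; ++i) acc += d[i];
    db[f] = acc;
  }
  // col2im scatter-add
  double *dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      const double *col = dA.data() + (R_xlen_t)rows * (j + (R_xlen_t)k * c);
      for (int t = 0; t < Lo; ++t) {
        int p = t * stride + j - pl;
        if (p < 0 || p >= L) continue;
        double *dst = dxp + (R_xlen_t)M * (p + (R_xlen_t)L * c);
        const double *src = col + (R_xlen_t)M * t;
        for (int m = 0; m < M; ++m) dst[m] += src[m];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// batch norm over the first two axes of (M, L, C), training mode:
// returns normalized output, xhat, batch mean/var and 1/sqrt(var + eps)
// [[Rcpp::export]]
List bn_train_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                  double eps) {
  IntegerVector xd = x.attr("dim");
  R_xlen_t n = (R_xlen_t)xd[0] * xd[1];
  int C = xd[2];
  NumericVector out(x.size()), xhat(x.size()), mu(C), var(C), ivar(C);
  out.attr("dim") = xd;
  xhat.attr("dim") = xd;
  double *xp = REAL(x), *op = REAL(out), *hp = REAL(xhat);
  for (int c = 0; c < C; ++c) {
    double *xc = xp + n * c;
    double s = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) s += xc[i];
    double m = s / n;
    double v = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) { double d = xc[i] - m; v += d * d; }
    v /= n;
    double iv = 1.0 / std::sqrt(v + eps);
    double g = gamma[c], b = beta[c];
    double *oc = op + n * c, *hc = hp + n * c;
    for (R_xlen_t i = 0; i < n; ++i) {
      double h = (xc[i] - m) * iv;
      hc[i] = h;
      oc[i] = g * h + b;
    }
    mu[c] = m; var[c] = v; ivar[c] = iv;
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["ivar"] = ivar);
}

// [[Rcpp::export]]
NumericVector bn_infer_cpp(NumericVector x, NumericVector gamma,
                           NumericVector beta, NumericVector mean,
                           NumericVector var, double eps) {
  IntegerVector xd = x.attr("dim");
  R_xlen_t n = (R_xlen_t)xd[0] * xd[1];
  int C = xd[2];
  NumericVector out(x.size());
  out.attr("dim") = xd;
  double *xp = REAL(x), *op = REAL(out);
  for (int c = 0; c < C; ++c) {
    double iv = 1.0 / std::sqrt(var[c] + eps);
    double g = gamma[c], b = beta[c], m = mean[c];
    double *xc = xp + n * c, *oc = op + n * c;
    for (R_xlen_t i = 0; i < n; ++i) oc[i] = g * (xc[i] - m) * iv + b;
  }
  return out;
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector xhat, NumericVector gamma,
                NumericVector ivar) {
  IntegerVector xd = xhat.attr("dim");
  R_xlen_t n = (R_xlen_t)xd[0] * xd[1];
  int C = xd[2];
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  double *dyp = REAL(dy), *hp = REAL(xhat), *dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    double *dc = dyp + n * c, *hc = hp + n * c, *xc = dxp + n * c;
    double s1 = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      s1 += dc[i];
      s2 += dc[i] * hc[i];
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    double g = gamma[c], iv = ivar[c];
    double gs1 = g * s1, gs2 = g * s2;
    double scale = iv / n;
    for (R_xlen_t i = 0; i < n; ++i)
      xc[i] = scale * (n * g * dc[i] - gs1 - hc[i] * gs2);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  double *xp = REAL(x), *op = REAL(out);
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector out) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  double *dyp = REAL(dy), *op = REAL(out), *dxp = REAL(dx);
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dxp[i] = op[i] > 0 ? dyp[i] : 0.0;
  return dx;
}

// non-overlapping temporal max-pool with truncation; records argmax offsets
// [[Rcpp::export]]
List pool_fwd_cpp(NumericVector x, int p) {
  IntegerVector xd = x.attr("dim");
  int M = xd[0], L = xd[1], C = xd[2];
  int Lp = L / p;
  NumericVector out((R_xlen_t)M * Lp * C);
  IntegerVector which((R_xlen_t)M * Lp * C);
  out.attr("dim") = IntegerVector::create(M, Lp, C);
  which.attr("dim") = IntegerVector::create(M, Lp, C);
  double *xp = REAL(x), *op = REAL(out);
  int *wp = INTEGER(which);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Lp; ++t) {
      double *o = op + (R_xlen_t)M * (t + (R_xlen_t)Lp * c);
      int *w = wp + (R_xlen_t)M * (t + (R_xlen_t)Lp * c);
      for (int j = 0; j < p; ++j) {
        double *xi = xp + (R_xlen_t)M * (t * p + j + (R_xlen_t)L * c);
        if (j == 0) {
          for (int m = 0; m < M; ++m) { o[m] = xi[m]; w[m] = 0; }
        } else {
          for (int m = 0; m < M; ++m)
            if (xi[m] > o[m]) { o[m] = xi[m]; w[m] = j; }
        }
      }
    }
  }
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector pool_bwd_cpp(NumericVector dy, IntegerVector which,
                           int p, int L) {
  IntegerVector yd = dy.attr("dim");
  int M = yd[0], Lp = yd[1], C = yd[2];
  NumericVector dx((R_xlen_t)M * L * C);
  dx.attr("dim") = IntegerVector::create(M, L, C);
  double *dyp = REAL(dy), *dxp = REAL(dx);
  int *wp = INTEGER(which);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Lp; ++t) {
      double *d = dyp + (R_xlen_t)M * (t + (R_xlen_t)Lp * c);
      int *w = wp + (R_xlen_t)M * (t + (R_xlen_t)Lp * c);
      for (int m = 0; m < M; ++m) {
        dxp[m + (R_xlen_t)M * (t * p + w[m] + (R_xlen_t)L * c)] = d[m];
      }
    }
  }
  return dx;
}
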
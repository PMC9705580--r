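// Low-level numerical kernels for the 2D characterization network:
// same-padded 3x3 convolution (im2col + GEMM), 2x2 max pooling and
// batch normalization, each with an explicit backward pass.
//
// Array layout follows R: dimensions (H, W, C, B), column-major,
// H fastest. Kernel weights are (K, K, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Fill the im2col matrix for one sample: cols is (H*W) x (K*K*Cin).
// Column q = cin*K*K + (dx+hk)*K + (dy+hk) holds channel cin shifted by
// (dy, dx), zero outside the image (zero padding, stride 1).
void im2col_sample(const double* x, int H, int W, int Cin, int K,
                   arma::mat& cols) {
  const int hk = K / 2;
  cols.zeros();
  for (int cin = 0; cin < Cin; ++cin) {
    const arma::mat Xc(const_cast<double*>(x) + (size_t)cin * H * W, H, W,
                       false, true);
    for (int dx = -hk; dx <= hk; ++dx) {
      for (int dy = -hk; dy <= hk; ++dy) {
        const int q = cin * K * K + (dx + hk) * K + (dy + hk);
        arma::mat Cc(cols.colptr(q), H, W, false, true);
        // destination pixel (i, j) reads source (i + dy, j + dx)
        const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        const int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        if (i1 > i0 && j1 > j0) {
          Cc.submat(i0, j0, i1 - 1, j1 - 1) =
              Xc.submat(i0 + dy, j0 + dx, i1 - 1 + dy, j1 - 1 + dx);
        }
      }
    }
  }
}

arma::mat weights_as_matrix(const NumericVector& w, int K, int Cin, int Cout) {
  // (K, K, Cin, Cout) -> (K*K*Cin, Cout); row index matches im2col column q.
  arma::mat Wm(K * K * Cin, Cout);
  for (int cout = 0; cout < Cout; ++cout)
    for (int cin = 0; cin < Cin; ++cin)
      for (int kx = 0; kx < K; ++kx)
        for (int ky = 0; ky < K; ++ky)
          Wm(cin * K * K + kx * K + ky, cout) =
              w[ky + K * (kx + K * (cin + Cin * cout))];
  return Wm;
}

} // namespace

// [[Rcpp::export(name = ".cfConv2dForward")]]
NumericVector cf_conv2d_forward(NumericVector x, NumericVector w,
                                NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int K = wd[0], Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch between input and kernel");
  NumericVector y((size_t)H * W * Cout * B);
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  arma::mat Wm = weights_as_matrix(w, K, Cin, Cout);
  arma::rowvec bv(Cout);
  for (int c = 0; c < Cout; ++c) bv(c) = bias[c];
  arma::mat cols(H * W, K * K * Cin);
  for (int b = 0; b < B; ++b) {
    im2col_sample(&x[0] + (size_t)b * H * W * Cin, H, W, Cin, K, cols);
    arma::mat Ym(&y[0] + (size_t)b * H * W * Cout, H * W, Cout, false, true);
    Ym = cols * Wm;
    Ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".cfConv2dBackward")]]
List cf_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int hk = K / 2;
  arma::mat Wm = weights_as_matrix(w, K, Cin, Cout);

  NumericVector dx((size_t)H * W * Cin * B);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  arma::mat dWm(K * K * Cin, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);

  arma::mat cols(H * W, K * K * Cin);
  for (int b = 0; b < B; ++b) {
    const double* xb = &x[0] + (size_t)b * H * W * Cin;
    arma::mat dYm(const_cast<double*>(&dy[0]) + (size_t)b * H * W * Cout,
                  H * W, Cout, false, true);
    im2col_sample(xb, H, W, Cin, K, cols);
    dWm += cols.t() * dYm;
    db += arma::sum(dYm, 0);
    arma::mat dcols = dYm * Wm.t(); // (H*W) x (K*K*Cin)
    // col2im: scatter shifted blocks back, accumulating
    double* dxb = &dx[0] + (size_t)b * H * W * Cin;
    for (int cin = 0; cin < Cin; ++cin) {
      arma::mat dXc(dxb + (size_t)cin * H * W, H, W, false, true);
      for (int dxo = -hk; dxo <= hk; ++dxo) {
        for (int dyo = -hk; dyo <= hk; ++dyo) {
          const int q = cin * K * K + (dxo + hk) * K + (dyo + hk);
          arma::mat Dc(dcols.colptr(q), H, W, false, true);
          const int i0 = std::max(0, -dyo), i1 = std::min(H, H - dyo);
          const int j0 = std::max(0, -dxo), j1 = std::min(W, W - dxo);
          if (i1 > i0 && j1 > j0) {
            dXc.submat(i0 + dyo, j0 + dxo, i1 - 1 + dyo, j1 - 1 + dxo) +=
                Dc.submat(i0, j0, i1 - 1, j1 - 1);
          }
        }
      }
    }
  }
  // repack dW to (K, K, Cin, Cout)
  NumericVector dw((size_t)K * K * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(K, K, Cin, Cout);
  for (int cout = 0; cout < Cout; ++cout)
    for (int cin = 0; cin < Cin; ++cin)
      for (int kx = 0; kx < K; ++kx)
        for (int ky = 0; ky < K; ++ky)
          dw[ky + K * (kx + K * (cin + Cin * cout))] =
              dWm(cin * K * K + kx * K + ky, cout);
  NumericVector dbv(Cout);
  for (int c = 0; c < Cout; ++c) dbv[c] = db(c);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = dbv);
}

// 2x2 max pooling, stride 2, floor rule (odd trailing row/col dropped).
// [[Rcpp::export(name = ".cfMaxPool2Forward")]]
List cf_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y((size_t)H2 * W2 * C * B);
  y.attr("dim") = IntegerVector::create(H2, W2, C, B);
  IntegerVector idx((size_t)H2 * W2 * C * B); // argmax as offset in (H, W) plane
  idx.attr("dim") = IntegerVector::create(H2, W2, C, B);
  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xp = &x[0] + (size_t)(b * C + c) * H * W;
      for (int j = 0; j < W2; ++j) {
        for (int i = 0; i < H2; ++i, ++o) {
          int bi = 2 * i, bj = 2 * j;
          int best = bi + bj * H;
          double bv = xp[best];
          const int cand[3] = {bi + 1 + bj * H, bi + (bj + 1) * H,
                               bi + 1 + (bj + 1) * H};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          y[o] = bv;
          idx[o] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cfMaxPool2Backward")]]
NumericVector cf_maxpool2_backward(IntegerVector idx, NumericVector dy,
                                   int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2], B = yd[3];
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  size_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double* dxp = &dx[0] + (size_t)(b * C + c) * H * W;
      for (int k = 0; k < H2 * W2; ++k, ++o) dxp[idx[o]] += dy[o];
    }
  return dx;
}

// Batch normalization over (H, W, B) per channel, population variance.
// [[Rcpp::export(name = ".cfBatchNormForward")]]
List cf_batchnorm_forward(NumericVector x, NumericVector gamma,
                          NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector mu(C), var(C);
  const double n = (double)plane * B;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double* xp = &x[0] + ((size_t)b * C + c) * plane;
      for (size_t k = 0; k < plane; ++k) { s += xp[k]; s2 += xp[k] * xp[k]; }
    }
    const double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    mu[c] = m; var[c] = v;
    const double inv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], bb = beta[c];
    for (int b = 0; b < B; ++b) {
      const double* xp = &x[0] + ((size_t)b * C + c) * plane;
      double* yp = &y[0] + ((size_t)b * C + c) * plane;
      for (size_t k = 0; k < plane; ++k) yp[k] = g * (xp[k] - m) * inv + bb;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export(name = ".cfBatchNormBackward")]]
List cf_batchnorm_backward(NumericVector x, NumericVector dy, NumericVector mu,
                           NumericVector var, NumericVector gamma, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t plane = (size_t)H * W;
  const double n = (double)plane * B;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c];
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    double sdy = 0, sdyx = 0;
    for (int b = 0; b < B; ++b) {
      const double* xp = &x[0] + ((size_t)b * C + c) * plane;
      const double* dp = &dy[0] + ((size_t)b * C + c) * plane;
      for (size_t k = 0; k < plane; ++k) {
        sdy += dp[k];
        sdyx += dp[k] * (xp[k] - m) * inv;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double g = gamma[c];
    for (int b = 0; b < B; ++b) {
      const double* xp = &x[0] + ((size_t)b * C + c) * plane;
      const double* dp = &dy[0] + ((size_t)b * C + c) * plane;
      double* dxp = &dx[0] + ((size_t)b * C + c) * plane;
      for (size_t k = 0; k < plane; ++k) {
        const double xhat = (xp[k] - m) * inv;
        dxp[k] = g * inv / n * (n * dp[k] - sdy - xhat * sdyx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// kernel-3 1D convolution over (positions x channels) matrices with zero
// padding and dilation; w is (3, Cin, Cout).
namespace {
arma::mat w1d_slice(const NumericVector& w, int j, int Cin, int Cout) {
  arma::mat W(Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      W(ci, co) = w[j + 3 * (ci + Cin * co)];
  return W;
}
} // namespace

// [[Rcpp::export(name = ".cfConv1dForward")]]
NumericMatrix cf_conv1d_forward(NumericMatrix x, NumericVector w,
                                NumericVector b, int dil) {
  IntegerVector wd = w.attr("dim");
  const int S = x.nrow(), Cin = wd[1], Cout = wd[2];
  const arma::mat X(x.begin(), S, Cin, false, true);
  arma::mat W1 = w1d_slice(w, 0, Cin, Cout), W2 = w1d_slice(w, 1, Cin, Cout),
            W3 = w1d_slice(w, 2, Cin, Cout);
  NumericMatrix y(S, Cout);
  arma::mat Y(y.begin(), S, Cout, false, true);
  Y = X * W2;
  if (dil < S) {
    Y.rows(dil, S - 1) += X.rows(0, S - 1 - dil) * W1;
    Y.rows(0, S - 1 - dil) += X.rows(dil, S - 1) * W3;
  }
  for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  return y;
}

// [[Rcpp::export(name = ".cfConv1dBackward")]]
List cf_conv1d_backward(NumericMatrix x, NumericVector w, NumericMatrix dy,
                        int dil) {
  IntegerVector wd = w.attr("dim");
  const int S = x.nrow(), Cin = wd[1], Cout = wd[2];
  const arma::mat X(x.begin(), S, Cin, false, true);
  const arma::mat dY(dy.begin(), S, Cout, false, true);
  arma::mat W1 = w1d_slice(w, 0, Cin, Cout), W2 = w1d_slice(w, 1, Cin, Cout),
            W3 = w1d_slice(w, 2, Cin, Cout);
  arma::mat dW1(Cin, Cout, arma::fill::zeros), dW2 = X.t() * dY,
            dW3(Cin, Cout, arma::fill::zeros);
  NumericMatrix dx(S, Cin);
  arma::mat dX(dx.begin(), S, Cin, false, true);
  dX = dY * W2.t();
  if (dil < S) {
    dW1 = X.rows(0, S - 1 - dil).t() * dY.rows(dil, S - 1);
    dW3 = X.rows(dil, S - 1).t() * dY.rows(0, S - 1 - dil);
    dX.rows(0, S - 1 - dil) += dY.rows(dil, S - 1) * W1.t();
    dX.rows(dil, S - 1) += dY.rows(0, S - 1 - dil) * W3.t();
  }
  NumericVector dw(3 * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(3, Cin, Cout);
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    db[co] = arma::accu(dY.col(co));
    for (int ci = 0; ci < Cin; ++ci) {
      dw[0 + 3 * (ci + Cin * co)] = dW1(ci, co);
      dw[1 + 3 * (ci + Cin * co)] = dW2(ci, co);
      dw[2 + 3 * (ci + Cin * co)] = dW3(ci, co);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Fused batch-norm + ReLU: forward returns the rectified output plus the
// batch statistics; backward recomputes the pre-ReLU sign internally.
// [[Rcpp::export(name = ".cfBNReluForward")]]
List cf_bnrelu_forward(NumericVector x, NumericVector gamma,
                       NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector mu(C), var(C);
  const double n = (double)plane * B;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double* xp = &x[0] + ((size_t)b * C + c) * plane;
      for (size_t k = 0; k < plane; ++k) { s += xp[k]; s2 += xp[k] * xp[k]; }
    }
    const double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    mu[c] = m; var[c] = v;
    const double inv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], bb = beta[c];
    for (int b = 0; b < B; ++b) {
      const double* xp = &x[0] + ((size_t)b * C + c) * plane;
      double* yp = &y[0] + ((size_t)b * C + c) * plane;
      for (size_t k = 0; k < plane; ++k) {
        const double t = g * (xp[k] - m) * inv + bb;
        yp[k] = t > 0 ? t : 0.0;
      }
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export(name = ".cfBNReluBackward")]]
List cf_bnrelu_backward(NumericVector x, NumericVector dy, NumericVector mu,
                        NumericVector var, NumericVector gamma,
                        NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t plane = (size_t)H * W;
  const double n = (double)plane * B;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c];
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], bb = beta[c];
    double sdy = 0, sdyx = 0;
    for (int b = 0; b < B; ++b) {
      const double* xp = &x[0] + ((size_t)b * C + c) * plane;
      const double* dp = &dy[0] + ((size_t)b * C + c) * plane;
      for (size_t k = 0; k < plane; ++k) {
        const double xhat = (xp[k] - m) * inv;
        if (g * xhat + bb > 0) {           // ReLU pass-through
          sdy += dp[k];
          sdyx += dp[k] * xhat;
        }
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    for (int b = 0; b < B; ++b) {
      const double* xp = &x[0] + ((size_t)b * C + c) * plane;
      const double* dp = &dy[0] + ((size_t)b * C + c) * plane;
      double* dxp = &dx[0] + ((size_t)b * C + c) * plane;
      for (size_t k = 0; k < plane; ++k) {
        const double xhat = (xp[k] - m) * inv;
        const double dpass = (g * xhat + bb > 0) ? dp[k] : 0.0;
        dxp[k] = g * inv / n * (n * dpass - sdy - xhat * sdyx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Inference-mode batch norm + ReLU with running statistics.
// [[Rcpp::export(name = ".cfBNReluEval")]]
NumericVector cf_bnrelu_eval(NumericVector x, NumericVector gamma,
                             NumericVector beta, NumericVector rmean,
                             NumericVector rvar, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c], bb = beta[c], m = rmean[c];
    for (int b = 0; b < B; ++b) {
      const double* xp = &x[0] + ((size_t)b * C + c) * plane;
      double* yp = &y[0] + ((size_t)b * C + c) * plane;
      for (size_t k = 0; k < plane; ++k) {
        const double t = g * (xp[k] - m) * inv + bb;
        yp[k] = t > 0 ? t : 0.0;
      }
    }
  }
  return y;
}
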
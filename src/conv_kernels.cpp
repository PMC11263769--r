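// Convolution and pooling kernels for the U-net trainer.
// Layout: image batches are column-major R arrays [H, W, C, N];
// conv weights are [k, k, Cin, Cout]. "Same" padding, stride 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill colT (H*W x k*k*C) with shifted copies of the input planes so that
// y = colT * Wmat computes a same-padded correlation.
static void im2colT(const double* xs, int H, int W, int C, int k,
                    arma::mat& colT) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* plane = xs + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * (kj + k * c);
        const int di = ki - pad, dj = kj - pad;
        double* dst = colT.colptr(r);
        for (int j = 0; j < W; ++j) {
          double* d = dst + (R_xlen_t)j * H;
          const int sj = j + dj;
          if (sj < 0 || sj >= W) { std::fill(d, d + H, 0.0); continue; }
          const double* src = plane + (R_xlen_t)sj * H;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          if (i0 > 0) std::fill(d, d + i0, 0.0);
          if (i1 < H) std::fill(d + i1, d + H, 0.0);
          if (i1 > i0) std::copy(src + i0 + di, src + i1 + di, d + i0);
        }
      }
    }
  }
}

// Adjoint of im2colT: scatter-add dcolT back onto the input gradient.
static void col2imT(const arma::mat& dcolT, int H, int W, int C, int k,
                    double* dxs) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    double* plane = dxs + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * (kj + k * c);
        const int di = ki - pad, dj = kj - pad;
        const double* src = dcolT.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          double* d = plane + (R_xlen_t)sj * H;
          const double* s = src + (R_xlen_t)j * H;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) d[i + di] += s[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch in conv2d_fwd");
  const int HW = H * W, K = k * k * C;
  NumericVector y((R_xlen_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat colT(HW, K);
  const arma::mat Wm((double*)w.begin(), K, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    im2colT(x.begin() + (R_xlen_t)n * HW * C, H, W, C, k, colT);
    arma::mat Y(y.begin() + (R_xlen_t)n * HW * Cout, HW, Cout, false, true);
    Y = colT * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int HW = H * W, K = k * k * C;
  NumericVector dx((R_xlen_t)HW * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat colT(HW, K);
  arma::mat dW((double*)dw.begin(), K, Cout, false, true);
  const arma::mat Wm((double*)w.begin(), K, Cout, false, true);
  arma::mat dcolT(HW, K);
  for (int n = 0; n < N; ++n) {
    im2colT(x.begin() + (R_xlen_t)n * HW * C, H, W, C, k, colT);
    const arma::mat dY((double*)dy.begin() + (R_xlen_t)n * HW * Cout,
                       HW, Cout, false, true);
    dW += colT.t() * dY;
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dY.col(co));
    dcolT = dY * Wm.t();
    col2imT(dcolT, H, W, C, k, dx.begin() + (R_xlen_t)n * HW * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector which(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* wp = which.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + ((R_xlen_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          const R_xlen_t base = (R_xlen_t)(2 * j) * H + 2 * i;
          double best = plane[base];
          int arg = 0;
          const R_xlen_t cand[3] = {base + 1, base + H, base + H + 1};
          for (int q = 0; q < 3; ++q)
            if (plane[cand[q]] > best) { best = plane[cand[q]]; arg = q + 1; }
          yp[o] = best;
          wp[o] = arg;
        }
    }
  return List::create(_["out"] = y, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector which,
                           IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* wp = which.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* plane = dxp + ((R_xlen_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          R_xlen_t base = (R_xlen_t)(2 * j) * H + 2 * i;
          switch (wp[o]) {
            case 1: base += 1; break;
            case 2: base += H; break;
            case 3: base += H + 1; break;
          }
          plane[base] += dyp[o];
        }
    }
  return dx;
}
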
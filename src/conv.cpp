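// Valid 2-D convolution (with optional zero padding) over batches stored as
// (batch, height, width, channel) column-major arrays: im2col buffers filled
// with contiguous batch-sized copies feed BLAS-backed matrix products.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// fill col (B*oh*ow) x (kh*kw*Cin) from padded input xp of dims (B,H,W,C)
static void im2col(const double* xp, int B, int H, int W, int C,
                   int kh, int kw, int sh, int sw, int oh, int ow,
                   arma::mat& col) {
  for (int ci = 0; ci < C; ++ci) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int cc = i + kh * (j + kw * ci);
        double* dst = col.colptr(cc);
        for (int oj = 0; oj < ow; ++oj) {
          for (int oi = 0; oi < oh; ++oi) {
            const double* src = xp + (size_t)B *
              ((size_t)(i + oi * sh) + (size_t)H *
               ((size_t)(j + oj * sw) + (size_t)W * ci));
            std::memcpy(dst + (size_t)B * (oi + (size_t)oh * oj), src,
                        B * sizeof(double));
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& col, double* xp, int B, int H, int W,
                   int C, int kh, int kw, int sh, int sw, int oh, int ow) {
  for (int ci = 0; ci < C; ++ci) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int cc = i + kh * (j + kw * ci);
        const double* src = col.colptr(cc);
        for (int oj = 0; oj < ow; ++oj) {
          for (int oi = 0; oi < oh; ++oi) {
            double* dst = xp + (size_t)B *
              ((size_t)(i + oi * sh) + (size_t)H *
               ((size_t)(j + oj * sw) + (size_t)W * ci));
            const double* s = src + (size_t)B * (oi + (size_t)oh * oj);
            for (int b = 0; b < B; ++b) dst[b] += s[b];
          }
        }
      }
    }
  }
}

static std::vector<double> pad_input(const double* x, int B, int H, int W,
                                     int C, int ph, int pw) {
  const int Hp = H + 2 * ph, Wp = W + 2 * pw;
  std::vector<double> xp((size_t)B * Hp * Wp * C, 0.0);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        std::memcpy(xp.data() + (size_t)B *
                      ((size_t)(h + ph) + (size_t)Hp *
                       ((size_t)(w + pw) + (size_t)Wp * c)),
                    x + (size_t)B * ((size_t)h + (size_t)H *
                                     ((size_t)w + (size_t)W * c)),
                    B * sizeof(double));
      }
    }
  }
  return xp;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector Wt,
                            NumericVector bias, IntegerVector stride,
                            IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim");
  const int B = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but kernel expects %d", C, Cin);
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int Hp = H + 2 * ph, Wp = W + 2 * pw;
  if (Hp < kh || Wp < kw) {
    stop("conv2d: spatial size (%dx%d) smaller than kernel (%dx%d)", Hp, Wp, kh, kw);
  }
  const int oh = (Hp - kh) / sh + 1, ow = (Wp - kw) / sw + 1;
  const double* xptr = x.begin();
  std::vector<double> padded;
  if (ph > 0 || pw > 0) {
    padded = pad_input(xptr, B, H, W, C, ph, pw);
    xptr = padded.data();
  }
  arma::mat col((size_t)B * oh * ow, (size_t)kh * kw * Cin);
  im2col(xptr, B, Hp, Wp, C, kh, kw, sh, sw, oh, ow, col);
  const arma::mat Wm(const_cast<double*>(Wt.begin()), (size_t)kh * kw * Cin,
                     Cout, false, true);
  arma::mat y = col * Wm;
  for (int co = 0; co < Cout; ++co) y.col(co) += bias[co];
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(B, oh, ow, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector Wt, IntegerVector stride,
                   IntegerVector pad, NumericVector dy, bool want_dx,
                   bool want_dw) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim"), yd = dy.attr("dim");
  const int B = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int Hp = H + 2 * ph, Wp = W + 2 * pw;
  const int oh = yd[1], ow = yd[2];
  const arma::mat dYm(const_cast<double*>(dy.begin()), (size_t)B * oh * ow,
                      Cout, false, true);
  const arma::mat Wm(const_cast<double*>(Wt.begin()), (size_t)kh * kw * C,
                     Cout, false, true);
  List res;
  if (want_dw) {
    const double* xptr = x.begin();
    std::vector<double> padded;
    if (ph > 0 || pw > 0) {
      padded = pad_input(xptr, B, H, W, C, ph, pw);
      xptr = padded.data();
    }
    arma::mat col((size_t)B * oh * ow, (size_t)kh * kw * C);
    im2col(xptr, B, Hp, Wp, C, kh, kw, sh, sw, oh, ow, col);
    arma::mat dW = col.t() * dYm;
    NumericVector dWout(dW.begin(), dW.end());
    dWout.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
    res["dW"] = dWout;
    arma::rowvec db = arma::sum(dYm, 0);
    res["db"] = NumericVector(db.begin(), db.end());
  }
  if (want_dx) {
    arma::mat dcol = dYm * Wm.t();
    std::vector<double> dxp((size_t)B * Hp * Wp * C, 0.0);
    col2im(dcol, dxp.data(), B, Hp, Wp, C, kh, kw, sh, sw, oh, ow);
    NumericVector dx((size_t)B * H * W * C);
    if (ph > 0 || pw > 0) {
      for (int c = 0; c < C; ++c) {
        for (int w = 0; w < W; ++w) {
          for (int h = 0; h < H; ++h) {
            std::memcpy(dx.begin() + (size_t)B *
                          ((size_t)h + (size_t)H * ((size_t)w + (size_t)W * c)),
                        dxp.data() + (size_t)B *
                          ((size_t)(h + ph) + (size_t)Hp *
                           ((size_t)(w + pw) + (size_t)Wp * c)),
                        B * sizeof(double));
          }
        }
      }
    } else {
      std::memcpy(dx.begin(), dxp.data(), dxp.size() * sizeof(double));
    }
    dx.attr("dim") = IntegerVector::create(B, H, W, C);
    res["dx"] = dx;
  }
  return res;
}
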
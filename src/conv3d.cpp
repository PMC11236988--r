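// 3D convolution primitives for the classification backbones.
//
// Volumes are R arrays with dim (D, H, W, C), i.e. column-major with the
// first spatial axis fastest and channels slowest.  Kernels are fixed at
// 3x3x3 with padding 1 (the only kernel the backbones use); weights are
// (C_out) x (C_in * 27) matrices whose column index is ci * 27 + ko with
// ko enumerating the kernel offsets, first axis fastest.
//
// The implementation is im2col + BLAS GEMM via Armadillo, which keeps a
// 1-CPU desk-scale training run within minutes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int n, int stride) {
  // kernel 3, pad 1
  return (n + 2 - 3) / stride + 1;
}

static arma::mat im2col3(const double* x, int D, int H, int W, int C,
                         int stride) {
  const int OD = conv_out_dim(D, stride);
  const int OH = conv_out_dim(H, stride);
  const int OW = conv_out_dim(W, stride);
  const int nout = OD * OH * OW;
  arma::mat cols(27 * C, nout, arma::fill::zeros);
  const int R = 27 * C;
  double* cp = cols.memptr();
  // valid output range for kernel offset k along an axis of size n:
  // index = o*stride - 1 + k must lie in [0, n)
  auto lo = [stride](int k) { return k >= 1 ? 0 : (stride == 1 ? 1 : 1); };
  auto hi = [stride](int n, int no, int k) {
    int h = (n - k) / stride;
    return h > no - 1 ? no - 1 : h;
  };
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * D * H * W;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        for (int kd = 0; kd < 3; ++kd) {
          const int r = ci * 27 + kd + 3 * (kh + 3 * kw);
          const int od_lo = lo(kd), od_hi = hi(D, OD, kd);
          for (int ow = lo(kw); ow <= hi(W, OW, kw); ++ow) {
            const int iw = ow * stride - 1 + kw;
            for (int oh = lo(kh); oh <= hi(H, OH, kh); ++oh) {
              const int ih = oh * stride - 1 + kh;
              const double* xcol = xc + (size_t)(ih + H * iw) * D;
              double* crow = cp + r;
              const size_t cbase = (size_t)(oh + OH * ow) * OD;
              for (int od = od_lo; od <= od_hi; ++od) {
                crow[(cbase + od) * R] = xcol[od * stride - 1 + kd];
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

static void col2im3(const arma::mat& cols, double* dx, int D, int H, int W,
                    int C, int stride) {
  const int OD = conv_out_dim(D, stride);
  const int OH = conv_out_dim(H, stride);
  const int OW = conv_out_dim(W, stride);
  std::fill(dx, dx + (size_t)D * H * W * C, 0.0);
  const int R = cols.n_rows;
  const double* cp = cols.memptr();
  auto lo = [stride](int k) { return k >= 1 ? 0 : 1; };
  auto hi = [stride](int n, int no, int k) {
    int h = (n - k) / stride;
    return h > no - 1 ? no - 1 : h;
  };
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (size_t)ci * D * H * W;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        for (int kd = 0; kd < 3; ++kd) {
          const int r = ci * 27 + kd + 3 * (kh + 3 * kw);
          const int od_lo = lo(kd), od_hi = hi(D, OD, kd);
          for (int ow = lo(kw); ow <= hi(W, OW, kw); ++ow) {
            const int iw = ow * stride - 1 + kw;
            for (int oh = lo(kh); oh <= hi(H, OH, kh); ++oh) {
              const int ih = oh * stride - 1 + kh;
              double* xcol = xc + (size_t)(ih + H * iw) * D;
              const double* crow = cp + r;
              const size_t cbase = (size_t)(oh + OH * ow) * OD;
              for (int od = od_lo; od <= od_hi; ++od) {
                xcol[od * stride - 1 + kd] += crow[(cbase + od) * R];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
List conv3d_fwd(NumericVector x, IntegerVector xdim, NumericMatrix weight,
                NumericVector bias, int stride, bool keep_cols) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int Cout = weight.nrow();
  if (weight.ncol() != 27 * C)
    stop("weight has %d columns; expected %d for %d input channels",
         weight.ncol(), 27 * C, C);
  const int OD = conv_out_dim(D, stride);
  const int OH = conv_out_dim(H, stride);
  const int OW = conv_out_dim(W, stride);
  const int nout = OD * OH * OW;

  arma::mat cols = im2col3(x.begin(), D, H, W, C, stride);
  arma::mat Wm(weight.begin(), Cout, 27 * C, false, true);
  arma::mat out = Wm * cols;               // Cout x nout
  out.each_col() += arma::vec(bias.begin(), Cout);

  NumericVector y((size_t)nout * Cout);
  arma::mat ymat(y.begin(), nout, Cout, false, true);
  ymat = out.t();
  y.attr("dim") = IntegerVector::create(OD, OH, OW, Cout);

  List res = List::create(_["y"] = y);
  if (keep_cols) res["cols"] = wrap(cols);
  return res;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector dy, IntegerVector xdim, NumericMatrix weight,
                NumericMatrix cols_in, int stride, bool need_dx) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int Cout = weight.nrow();
  const int OD = conv_out_dim(D, stride);
  const int OH = conv_out_dim(H, stride);
  const int OW = conv_out_dim(W, stride);
  const int nout = OD * OH * OW;
  if ((int)dy.size() != nout * Cout) stop("dy size mismatch");

  arma::mat dy_nc(dy.begin(), nout, Cout, false, true);
  arma::mat dy_cm = dy_nc.t();             // Cout x nout
  arma::mat cols(cols_in.begin(), 27 * C, nout, false, true);

  arma::mat dW = dy_cm * cols.t();         // Cout x 27C
  arma::vec db = arma::sum(dy_cm, 1);

  List res = List::create(_["dW"] = wrap(dW), _["db"] = wrap(db));
  if (need_dx) {
    arma::mat Wm(weight.begin(), Cout, 27 * C, false, true);
    arma::mat dcols = Wm.t() * dy_cm;      // 27C x nout
    NumericVector dx((size_t)D * H * W * C);
    col2im3(dcols, dx.begin(), D, H, W, C, stride);
    dx.attr("dim") = IntegerVector::create(D, H, W, C);
    res["dx"] = dx;
  }
  return res;
}
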
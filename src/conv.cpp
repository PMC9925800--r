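// Direct 2-D convolution (cross-correlation) kernels for the small-CNN engine.
// Layout follows R column-major arrays: x is H x W x Cin x N, the weight matrix
// has (k*k*Cin) rows indexed r = ki + k*(kj + k*c) (0-based kernel offsets) and
// Cout columns. "Same" padding (k-1)/2, stride 1.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_one(const double* x, int H, int W, int C, int k, int pad,
                       arma::mat& cols) {
  // cols: (H*W) x (k*k*C), row p = i + H*j
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int q = ki + k * (kj + k * c);
        double* col = cols.colptr(q);
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - pad;
          if (jj < 0 || jj >= W) {
            for (int i = 0; i < H; ++i) col[i + H * j] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * jj;
          for (int i = 0; i < H; ++i) {
            int ii = i + ki - pad;
            col[i + H * j] = (ii < 0 || ii >= H) ? 0.0 : src[ii];
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& dcols, int H, int W, int C, int k,
                       int pad, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int q = ki + k * (kj + k * c);
        const double* col = dcols.colptr(q);
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          double* dst = dxc + (size_t)H * jj;
          for (int i = 0; i < H; ++i) {
            int ii = i + ki - pad;
            if (ii >= 0 && ii < H) dst[ii] += col[i + H * j];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, IntegerVector dims,
                           NumericMatrix Wm, NumericVector b, int k) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int pad = (k - 1) / 2;
  const int Cout = Wm.ncol();
  if (Wm.nrow() != k * k * C) stop("weight matrix rows != k*k*Cin");
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector out((size_t)H * W * Cout * N);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, pad, cols);
    arma::mat z = cols * Wa;  // (H*W) x Cout
    double* o = out.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* zc = z.colptr(co);
      double bc = b[co];
      double* oc = o + (size_t)co * H * W;
      for (int p = 0; p < H * W; ++p) oc[p] = zc[p] + bc;
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return out;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, IntegerVector dims, NumericVector dz,
                  NumericMatrix Wm, int k, bool need_dx) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int pad = (k - 1) / 2;
  const int Cout = Wm.ncol();
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  arma::mat dW(k * k * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  arma::mat cols(H * W, k * k * C);
  arma::mat dz_mat(H * W, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, pad, cols);
    const double* d = dz.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* dc = dz_mat.colptr(co);
      const double* src = d + (size_t)co * H * W;
      double s = 0.0;
      for (int p = 0; p < H * W; ++p) { dc[p] = src[p]; s += src[p]; }
      db[co] += s;
    }
    dW += cols.t() * dz_mat;
    if (need_dx) {
      arma::mat dcols = dz_mat * Wa.t();
      col2im_one(dcols, H, W, C, k, pad, dx.begin() + (size_t)n * H * W * C);
    }
  }
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dx"] = dx);
}
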
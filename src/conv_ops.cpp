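// Convolution kernels for the CNN branches. Layouts mirror the R arrays:
// 1-D signals N x L x C, 2-D maps N x H x W x C, kernels k x Cin x Cout and
// kh x kw x Cin x Cout, all column-major. 'same' zero padding with left pad
// floor((k-1)/2). The offset-loop formulation (one GEMM per kernel offset)
// keeps memory at one padded copy of the input.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Build the padded design matrix Xp ((N*Lp) x Cin) for a 1-D batch.
static arma::mat pad1d(const arma::mat &X, int N, int L, int Cin, int pad_l,
                       int k) {
  const int Lp = L + k - 1;
  arma::mat Xp(N * Lp, Cin, arma::fill::zeros);
  Xp.rows(N * pad_l, N * pad_l + N * L - 1) = X;
  return Xp;
}

// [[Rcpp::export]]
NumericVector conv1d_fw_cpp(NumericVector x, NumericVector W,
                            NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  const int N = xd[0], L = xd[1], Cin = xd[2];
  const int k = wd[0], Cout = wd[2];
  const int pad_l = (k - 1) / 2;
  arma::mat X(x.begin(), N * L, Cin, false);
  arma::mat Xp = pad1d(X, N, L, Cin, pad_l, k);
  arma::mat out(N * L, Cout);
  for (int o = 0; o < Cout; ++o) out.col(o).fill(b[o]);
  arma::mat Wj(Cin, Cout);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < Cin; ++c)
      for (int o = 0; o < Cout; ++o) Wj(c, o) = W[j + k * c + k * Cin * o];
    out += Xp.rows(N * j, N * j + N * L - 1) * Wj;
  }
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(N, L, Cout);
  return res;
}

// [[Rcpp::export]]
List conv1d_bw_cpp(NumericVector x, NumericVector W, NumericVector dout) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  const int N = xd[0], L = xd[1], Cin = xd[2];
  const int k = wd[0], Cout = wd[2];
  const int pad_l = (k - 1) / 2;
  arma::mat X(x.begin(), N * L, Cin, false);
  arma::mat D(dout.begin(), N * L, Cout, false);
  arma::mat Xp = pad1d(X, N, L, Cin, pad_l, k);
  arma::mat dXp(N * (L + k - 1), Cin, arma::fill::zeros);
  NumericVector dW(k * Cin * Cout);
  arma::mat Wj(Cin, Cout);
  for (int j = 0; j < k; ++j) {
    arma::mat dWj = Xp.rows(N * j, N * j + N * L - 1).t() * D;
    for (int c = 0; c < Cin; ++c)
      for (int o = 0; o < Cout; ++o) {
        dW[j + k * c + k * Cin * o] = dWj(c, o);
        Wj(c, o) = W[j + k * c + k * Cin * o];
      }
    dXp.rows(N * j, N * j + N * L - 1) += D * Wj.t();
  }
  arma::mat dX = dXp.rows(N * pad_l, N * pad_l + N * L - 1);
  NumericVector dx(dX.begin(), dX.end());
  dx.attr("dim") = IntegerVector::create(N, L, Cin);
  dW.attr("dim") = IntegerVector::create(k, Cin, Cout);
  NumericVector db(Cout);
  for (int o = 0; o < Cout; ++o) db[o] = arma::accu(D.col(o));
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2-D convolutions work entirely in padded (n, h', w') coordinates, where
// rows of the padded design matrix are indexed n + N*h' + N*Hp*w'. Every
// kernel offset (a, b) is then a *contiguous* row range of the padded
// matrix (shift N*a + N*Hp*b), so GEMMs run on views with no gathering.
// Outputs computed in padded coordinates are cropped once at the end; the
// extra rows (padded h positions) are simply discarded.

static arma::mat pad2d(const double *x, int N, int H, int Wd, int Cin,
                       int ph, int pw, int Hp, int Wp, int kh) {
  // N*(kh-1) slack rows so every offset view stays in bounds
  arma::mat Xp((size_t)N * Hp * Wp + (size_t)N * (kh - 1), Cin,
               arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    double *dst = Xp.colptr(c);
    const double *src = x + (size_t)N * H * Wd * c;
    for (int w = 0; w < Wd; ++w)
      std::memcpy(dst + (size_t)N * ph + (size_t)N * Hp * (w + pw),
                  src + (size_t)N * H * w, sizeof(double) * (size_t)N * H);
  }
  return Xp;
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector W,
                            NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  const int N = xd[0], H = xd[1], Wd = xd[2], Cin = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int Hp = H + kh - 1, Wp = Wd + kw - 1;
  const size_t nrow_p = (size_t)N * Hp * Wd;  // padded-h rows, true w range
  arma::mat Xp = pad2d(x.begin(), N, H, Wd, Cin, ph, pw, Hp, Wp, kh);
  arma::mat outP(nrow_p, Cout, arma::fill::zeros);
  arma::mat Wab(Cin, Cout);
  for (int a = 0; a < kh; ++a)
    for (int bb = 0; bb < kw; ++bb) {
      for (int c = 0; c < Cin; ++c)
        for (int o = 0; o < Cout; ++o)
          Wab(c, o) = W[a + kh * bb + kh * kw * c + kh * kw * Cin * o];
      const size_t off = (size_t)N * a + (size_t)N * Hp * bb;
      outP += Xp.rows(off, off + nrow_p - 1) * Wab;
    }
  NumericVector res((size_t)N * H * Wd * Cout);
  for (int o = 0; o < Cout; ++o) {
    const double *src = outP.colptr(o);
    double *dst = res.begin() + (size_t)N * H * Wd * o;
    for (int w = 0; w < Wd; ++w)
      for (int h = 0; h < H; ++h)
        std::memcpy(dst + (size_t)N * (h + (size_t)H * w),
                    src + (size_t)N * h + (size_t)N * Hp * w,
                    sizeof(double) * (size_t)N);
  }
  for (size_t i = 0; i < (size_t)N * H * Wd; ++i)
    for (int o = 0; o < Cout; ++o)
      res[i + (size_t)N * H * Wd * o] += b[o];
  res.attr("dim") = IntegerVector::create(N, H, Wd, Cout);
  return res;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector W, NumericVector dout) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  const int N = xd[0], H = xd[1], Wd = xd[2], Cin = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int Hp = H + kh - 1, Wp = Wd + kw - 1;
  const size_t nrow_p = (size_t)N * Hp * Wd;
  arma::mat Xp = pad2d(x.begin(), N, H, Wd, Cin, ph, pw, Hp, Wp, kh);
  // expand dout into padded-h coordinates once (rows with h' >= H are 0)
  arma::mat Dp(nrow_p, Cout, arma::fill::zeros);
  for (int o = 0; o < Cout; ++o) {
    double *dst = Dp.colptr(o);
    const double *src = dout.begin() + (size_t)N * H * Wd * o;
    for (int w = 0; w < Wd; ++w)
      for (int h = 0; h < H; ++h)
        std::memcpy(dst + (size_t)N * h + (size_t)N * Hp * w,
                    src + (size_t)N * (h + (size_t)H * w),
                    sizeof(double) * (size_t)N);
  }
  arma::mat dXp((size_t)N * Hp * Wp + (size_t)N * (kh - 1), Cin,
                arma::fill::zeros);
  NumericVector dW(kh * kw * Cin * Cout);
  arma::mat Wab(Cin, Cout);
  for (int a = 0; a < kh; ++a)
    for (int bb = 0; bb < kw; ++bb) {
      const size_t off = (size_t)N * a + (size_t)N * Hp * bb;
      arma::mat dWab = Xp.rows(off, off + nrow_p - 1).t() * Dp;
      for (int c = 0; c < Cin; ++c)
        for (int o = 0; o < Cout; ++o) {
          dW[a + kh * bb + kh * kw * c + kh * kw * Cin * o] = dWab(c, o);
          Wab(c, o) = W[a + kh * bb + kh * kw * c + kh * kw * Cin * o];
        }
      dXp.rows(off, off + nrow_p - 1) += Dp * Wab.t();
    }
  NumericVector dx((size_t)N * H * Wd * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double *src = dXp.colptr(c);
    double *dst = dx.begin() + (size_t)N * H * Wd * c;
    for (int w = 0; w < Wd; ++w)
      std::memcpy(dst + (size_t)N * H * w,
                  src + (size_t)N * ph + (size_t)N * Hp * (w + pw),
                  sizeof(double) * (size_t)N * H);
  }
  dx.attr("dim") = IntegerVector::create(N, H, Wd, Cin);
  dW.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector db(Cout);
  for (int o = 0; o < Cout; ++o) {
    double s = 0;
    const double *src = dout.begin() + (size_t)N * H * Wd * o;
    for (size_t i = 0; i < (size_t)N * H * Wd; ++i) s += src[i];
    db[o] = s;
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
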
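// Compact CNN kernels: im2col convolution forward/backward, 2x2 max pooling,
// 2x nearest upsampling. Batches are R arrays in H x W x C x N layout
// (column-major, H fastest), weights kh x kw x Cin x Cout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(arma::uword h, arma::uword w, arma::uword c,
                               arma::uword n, arma::uword H, arma::uword W,
                               arma::uword C) {
  return h + H * (w + W * (c + C * n));
}

// Build the (Hout*Wout) x (kh*kw*Cin) patch matrix for one sample.
// Inner spans are contiguous in both source and destination, so bulk
// copies do the work.
static void im2col(const double* x, arma::uword H, arma::uword W,
                   arma::uword C, arma::uword n, int kh, int kw, int pad,
                   arma::mat& M) {
  const int Hout = (int)H + 2 * pad - kh + 1;
  const int Wout = (int)W + 2 * pad - kw + 1;
  M.zeros((arma::uword)(Hout * Wout), (arma::uword)(kh * kw * C));
  for (arma::uword c = 0; c < C; ++c) {
    const double* xc = x + (R_xlen_t)H * W * (c + C * n);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const arma::uword q = (arma::uword)(ki + kh * (kj + kw * (int)c));
        double* col = M.colptr(q);
        // valid output-row range for this kernel row offset
        const int i_lo = std::max(0, pad - ki);
        const int i_hi = std::min(Hout, (int)H + pad - ki);  // exclusive
        if (i_lo >= i_hi) continue;
        for (int j = 0; j < Wout; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= (int)W) continue;
          const double* src = xc + (R_xlen_t)H * sj + (i_lo + ki - pad);
          std::copy(src, src + (i_hi - i_lo), col + (R_xlen_t)Hout * j + i_lo);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                       int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const arma::uword Cout = wd[3];
  if ((arma::uword)wd[2] != C) stop("channel mismatch in conv_fwd");
  const int Hout = (int)H + 2 * pad - kh + 1;
  const int Wout = (int)W + 2 * pad - kw + 1;
  if (Hout < 1 || Wout < 1) stop("kernel larger than padded input");
  NumericVector y((R_xlen_t)Hout * Wout * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, (int)Cout, (int)N);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)(kh * kw * C),
               Cout, false, true);
  arma::mat M;
  for (arma::uword n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, kh, kw, pad, M);
    arma::mat Y = M * Wm;  // (Hout*Wout) x Cout
    double* yp = y.begin() + (R_xlen_t)Hout * Wout * Cout * n;
    for (arma::uword co = 0; co < Cout; ++co) {
      const double bc = b[co];
      double* dst = yp + (R_xlen_t)Hout * Wout * co;
      const double* src = Y.colptr(co);
      for (int k = 0; k < Hout * Wout; ++k) dst[k] = src[k] + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericVector w, NumericVector dy, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const arma::uword Cout = wd[3];
  const int Hout = yd[0], Wout = yd[1];
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)(kh * kw * C),
               Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xd;
  arma::mat dWm((arma::uword)(kh * kw * C), Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat M;
  for (arma::uword n = 0; n < N; ++n) {
    arma::mat dY((arma::uword)(Hout * Wout), Cout);
    const double* dyp = dy.begin() + (R_xlen_t)Hout * Wout * Cout * n;
    for (arma::uword co = 0; co < Cout; ++co)
      std::copy(dyp + (R_xlen_t)Hout * Wout * co,
                dyp + (R_xlen_t)Hout * Wout * (co + 1), dY.colptr(co));
    im2col(x.begin(), H, W, C, n, kh, kw, pad, M);
    dWm += M.t() * dY;
    db += arma::sum(dY, 0).t();
    arma::mat dM = dY * Wm.t();  // (Hout*Wout) x (kh*kw*C)
    // col2im: add contiguous spans back
    double* dxp = dx.begin();
    for (arma::uword c = 0; c < C; ++c) {
      double* dxc = dxp + (R_xlen_t)H * W * (c + C * n);
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const arma::uword q = (arma::uword)(ki + kh * (kj + kw * (int)c));
          const double* col = dM.colptr(q);
          const int i_lo = std::max(0, pad - ki);
          const int i_hi = std::min(Hout, (int)H + pad - ki);
          if (i_lo >= i_hi) continue;
          for (int j = 0; j < Wout; ++j) {
            const int sj = j + kj - pad;
            if (sj < 0 || sj >= (int)W) continue;
            double* dst = dxc + (R_xlen_t)H * sj + (i_lo + ki - pad);
            const double* src = col + (R_xlen_t)Hout * j + i_lo;
            for (int i = 0; i < i_hi - i_lo; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  NumericVector dwOut(w.size());
  dwOut.attr("dim") = wd;
  std::copy(dWm.begin(), dWm.end(), dwOut.begin());
  NumericVector dbOut(Cout);
  std::copy(db.begin(), db.end(), dbOut.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwOut, _["db"] = dbOut);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector which((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  which.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double best = -1e308;
          R_xlen_t bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const R_xlen_t ii = base + (2 * i + di) + (R_xlen_t)H * (2 * j + dj);
              if (xp[ii] > best) { best = xp[ii]; bi = ii; }
            }
          // column-major output order is i fastest, then j, c, n — matches o
          R_xlen_t oo = (R_xlen_t)i + Ho * ((R_xlen_t)j + Wo * ((R_xlen_t)c + (R_xlen_t)C * n));
          y[oo] = best;
          which[oo] = (int)(bi - base);
          ++o;
        }
    }
  return List::create(_["y"] = y, _["which"] = which);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector which,
                          IntegerVector in_dim) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = in_dim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          R_xlen_t oo = (R_xlen_t)i + Ho * ((R_xlen_t)j + Wo * ((R_xlen_t)c + (R_xlen_t)C * n));
          dx[base + which[oo]] += dy[oo];
        }
    }
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double v =
              x[(R_xlen_t)i + H * ((R_xlen_t)j + W * ((R_xlen_t)c + (R_xlen_t)C * n))];
          const R_xlen_t b =
              (R_xlen_t)2 * H * ((R_xlen_t)2 * j + 2 * W * ((R_xlen_t)c + (R_xlen_t)C * n));
          y[b + 2 * i] = v;
          y[b + 2 * i + 1] = v;
          y[b + 2 * H + 2 * i] = v;
          y[b + 2 * H + 2 * i + 1] = v;
        }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const R_xlen_t b =
              (R_xlen_t)2 * H * ((R_xlen_t)2 * j + 2 * W * ((R_xlen_t)c + (R_xlen_t)C * n));
          dx[(R_xlen_t)i + H * ((R_xlen_t)j + W * ((R_xlen_t)c + (R_xlen_t)C * n))] =
              dy[b + 2 * i] + dy[b + 2 * i + 1] + dy[b + 2 * H + 2 * i] +
              dy[b + 2 * H + 2 * i + 1];
        }
  return dx;
}
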
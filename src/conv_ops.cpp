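// Batched 2-D convolution and transposed convolution, forward and backward,
// via im2col/col2im and BLAS gemm. Array layout is R column-major:
//   feature maps          (H, W, C, N)
//   conv weights          (kh, kw, Cin, Cout)
//   transposed-conv wts   (kh, kw, Cout, Cin)
// The im2col buffer is kept transposed (rows = output positions, columns =
// kernel-taps x channels) so gathers/scatters run down contiguous memory and
// gemm results land directly in the R array layout. The single-precision
// path halves gemm time; gradients are returned as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims_of(SEXP x) {
  return IntegerVector(Rf_getAttrib(x, R_DimSymbol));
}

template <typename eT>
static void pad_image(const double* src, int H, int W, int C, int p,
                      arma::Col<eT>& buf, int Hp, int Wp) {
  buf.zeros();
  eT* b = buf.memptr();
  for (int c = 0; c < C; ++c) {
    const double* plane = src + (size_t)c * H * W;
    eT* bplane = b + (size_t)c * Hp * Wp;
    for (int w = 0; w < W; ++w) {
      const double* scol = plane + (size_t)w * H;
      eT* bcol = bplane + (size_t)(w + p) * Hp + p;
      for (int h = 0; h < H; ++h) bcol[h] = (eT)scol[h];
    }
  }
}

// Gather: cols(row0 + ho + Ho*wo, r) = xp[(wo*s+kj)*Hp + ho*s + ki]
template <typename eT>
static void im2col(const eT* xp, int Hp, int Wp, int C,
                   int kh, int kw, int s, int Ho, int Wo,
                   arma::Mat<eT>& cols, size_t row0) {
  const size_t R = cols.n_rows;
  eT* cm = cols.memptr();
  for (int c = 0; c < C; ++c) {
    const eT* plane = xp + (size_t)c * Hp * Wp;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        size_t r = (size_t)ki + kh * ((size_t)kj + (size_t)kw * c);
        eT* colbase = cm + r * R + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          const eT* src = plane + (size_t)(wo * s + kj) * Hp + ki;
          eT* dst = colbase + (size_t)wo * Ho;
          if (s == 1) {
            for (int ho = 0; ho < Ho; ++ho) dst[ho] = src[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) dst[ho] = src[(size_t)ho * s];
          }
        }
      }
    }
  }
}

// Scatter-add: xp[(wo*s+kj)*Hp + ho*s + ki] += cols(row0 + ho + Ho*wo, r)
template <typename eT>
static void col2im_add(eT* xp, int Hp, int Wp, int C,
                       int kh, int kw, int s, int Ho, int Wo,
                       const arma::Mat<eT>& cols, size_t row0) {
  const size_t R = cols.n_rows;
  const eT* cm = cols.memptr();
  for (int c = 0; c < C; ++c) {
    eT* plane = xp + (size_t)c * Hp * Wp;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        size_t r = (size_t)ki + kh * ((size_t)kj + (size_t)kw * c);
        const eT* colbase = cm + r * R + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          eT* dst = plane + (size_t)(wo * s + kj) * Hp + ki;
          const eT* src = colbase + (size_t)wo * Ho;
          if (s == 1) {
            for (int ho = 0; ho < Ho; ++ho) dst[ho] += src[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) dst[(size_t)ho * s] += src[ho];
          }
        }
      }
    }
  }
}

template <typename eT>
static arma::Col<eT> to_eT(const NumericVector& x) {
  arma::Col<eT> out(x.size());
  const double* s = x.begin();
  eT* d = out.memptr();
  for (R_xlen_t i = 0; i < x.size(); ++i) d[i] = (eT)s[i];
  return out;
}

template <typename eT>
static NumericVector to_R(const arma::Mat<eT>& m, IntegerVector dim) {
  NumericVector out((R_xlen_t)m.n_elem);
  const eT* s = m.memptr();
  for (size_t i = 0; i < m.n_elem; ++i) out[i] = (double)s[i];
  out.attr("dim") = dim;
  return out;
}

// Copy a (rows x channels) block of an L x C matrix into/out of an R array
// slice (both are column-major with matching layout per image).
template <typename eT>
static void block_to_R(const arma::Mat<eT>& M, size_t row0, size_t nrow,
                       double* dst) {
  for (size_t c = 0; c < M.n_cols; ++c) {
    const eT* s = M.colptr(c) + row0;
    double* d = dst + c * nrow;
    for (size_t i = 0; i < nrow; ++i) d[i] = (double)s[i];
  }
}
template <typename eT>
static void block_from_R(arma::Mat<eT>& M, size_t row0, size_t nrow,
                         const double* src) {
  for (size_t c = 0; c < M.n_cols; ++c) {
    eT* d = M.colptr(c) + row0;
    const double* s = src + c * nrow;
    for (size_t i = 0; i < nrow; ++i) d[i] = (eT)s[i];
  }
}

// ---------------- conv2d ----------------

template <typename eT>
static NumericVector conv2d_fw_t(const NumericVector& x, const NumericVector& w,
                                 const NumericVector& b, int s, int p) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", Cin, C);
  if (H + 2 * p < kh || W + 2 * p < kw)
    stop("conv2d: input %dx%d too small for kernel %d with padding %d", H, W, kh, p);
  int Ho = (H + 2 * p - kh) / s + 1, Wo = (W + 2 * p - kw) / s + 1;
  int Hp = H + 2 * p, Wp = W + 2 * p;
  size_t K = (size_t)kh * kw * C, L = (size_t)Ho * Wo * N;

  arma::Mat<eT> cols(L, K);
  arma::Col<eT> buf((size_t)Hp * Wp * C);
  for (int n = 0; n < N; ++n) {
    pad_image<eT>(x.begin() + (size_t)n * H * W * C, H, W, C, p, buf, Hp, Wp);
    im2col<eT>(buf.memptr(), Hp, Wp, C, kh, kw, s, Ho, Wo, cols,
               (size_t)n * Ho * Wo);
  }
  arma::Col<eT> wv = to_eT<eT>(w);
  arma::Mat<eT> Wm(wv.memptr(), K, Cout, false, true);
  arma::Mat<eT> Y = cols * Wm;                           // L x Cout
  arma::Col<eT> bv = to_eT<eT>(b);
  Y.each_row() += bv.t();

  NumericVector out((R_xlen_t)((size_t)Ho * Wo * Cout * N));
  for (int n = 0; n < N; ++n)
    block_to_R(Y, (size_t)n * Ho * Wo, (size_t)Ho * Wo,
               out.begin() + (size_t)n * Ho * Wo * Cout);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, bool single) {
  return single ? conv2d_fw_t<float>(x, w, b, stride, pad)
                : conv2d_fw_t<double>(x, w, b, stride, pad);
}

template <typename eT>
static List conv2d_bw_t(const NumericVector& x, const NumericVector& w,
                        const NumericVector& gy, int s, int p, bool need_gx) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), gd = dims_of(gy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  int Hp = H + 2 * p, Wp = W + 2 * p;
  size_t K = (size_t)kh * kw * C, L = (size_t)Ho * Wo * N;

  arma::Mat<eT> cols(L, K);
  arma::Col<eT> buf((size_t)Hp * Wp * C);
  for (int n = 0; n < N; ++n) {
    pad_image<eT>(x.begin() + (size_t)n * H * W * C, H, W, C, p, buf, Hp, Wp);
    im2col<eT>(buf.memptr(), Hp, Wp, C, kh, kw, s, Ho, Wo, cols,
               (size_t)n * Ho * Wo);
  }
  arma::Mat<eT> G(L, Cout);
  for (int n = 0; n < N; ++n)
    block_from_R(G, (size_t)n * Ho * Wo, (size_t)Ho * Wo,
                 gy.begin() + (size_t)n * Ho * Wo * Cout);
  arma::Mat<eT> gw = cols.t() * G;                       // K x Cout
  arma::Mat<eT> gb = arma::sum(G, 0).t();

  NumericVector gxR;
  if (need_gx) {
    arma::Col<eT> wv = to_eT<eT>(w);
    arma::Mat<eT> Wm(wv.memptr(), K, Cout, false, true);
    arma::Mat<eT> gcols = G * Wm.t();                    // L x K
    gxR = NumericVector((R_xlen_t)((size_t)H * W * C * N));
    arma::Col<eT> gbuf((size_t)Hp * Wp * C);
    for (int n = 0; n < N; ++n) {
      gbuf.zeros();
      col2im_add<eT>(gbuf.memptr(), Hp, Wp, C, kh, kw, s, Ho, Wo, gcols,
                     (size_t)n * Ho * Wo);
      double* dst = gxR.begin() + (size_t)n * H * W * C;
      const eT* bp = gbuf.memptr();
      for (int c = 0; c < C; ++c)
        for (int ww = 0; ww < W; ++ww) {
          const eT* scol = bp + (size_t)c * Hp * Wp + (size_t)(ww + p) * Hp + p;
          double* dcol = dst + (size_t)c * H * W + (size_t)ww * H;
          for (int h = 0; h < H; ++h) dcol[h] = (double)scol[h];
        }
    }
    gxR.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  return List::create(
    _["gx"] = gxR,
    _["gw"] = to_R(gw, dims_of(w)),
    _["gb"] = to_R(gb, IntegerVector::create(Cout)));
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad, bool need_gx, bool single) {
  return single ? conv2d_bw_t<float>(x, w, gy, stride, pad, need_gx)
                : conv2d_bw_t<double>(x, w, gy, stride, pad, need_gx);
}

// ---------------- transposed conv2d ----------------

template <typename eT>
static NumericVector convt2d_fw_t(const NumericVector& x, const NumericVector& w,
                                  const NumericVector& b, int s, int p, int op) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int Hi = xd[0], Wi = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[2];
  if (wd[3] != Cin) stop("convt2d: channel mismatch");
  int Ho = (Hi - 1) * s - 2 * p + kh + op, Wo = (Wi - 1) * s - 2 * p + kw + op;
  if (Ho < 1 || Wo < 1) stop("convt2d: non-positive output size");
  int Hf = (Hi - 1) * s + kh + op, Wf = (Wi - 1) * s + kw + op;
  size_t K2 = (size_t)kh * kw * Cout, L = (size_t)Hi * Wi * N;

  arma::Mat<eT> X(L, Cin);
  for (int n = 0; n < N; ++n)
    block_from_R(X, (size_t)n * Hi * Wi, (size_t)Hi * Wi,
                 x.begin() + (size_t)n * Hi * Wi * Cin);
  arma::Col<eT> wv = to_eT<eT>(w);
  arma::Mat<eT> Wm(wv.memptr(), K2, Cin, false, true);
  arma::Mat<eT> cols = X * Wm.t();                       // L x K2

  NumericVector out((R_xlen_t)((size_t)Ho * Wo * Cout * N));
  arma::Col<eT> buf((size_t)Hf * Wf * Cout);
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n) {
    buf.zeros();
    col2im_add<eT>(buf.memptr(), Hf, Wf, Cout, kh, kw, s, Hi, Wi, cols,
                   (size_t)n * Hi * Wi);
    double* dst = out.begin() + (size_t)n * Ho * Wo * Cout;
    const eT* sp = buf.memptr();
    for (int c = 0; c < Cout; ++c)
      for (int ww = 0; ww < Wo; ++ww) {
        const eT* scol = sp + (size_t)c * Hf * Wf + (size_t)(ww + p) * Hf + p;
        double* dcol = dst + (size_t)c * Ho * Wo + (size_t)ww * Ho;
        for (int h = 0; h < Ho; ++h) dcol[h] = (double)scol[h] + bp[c];
      }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
NumericVector convt2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int out_pad, bool single) {
  return single ? convt2d_fw_t<float>(x, w, b, stride, pad, out_pad)
                : convt2d_fw_t<double>(x, w, b, stride, pad, out_pad);
}

template <typename eT>
static List convt2d_bw_t(const NumericVector& x, const NumericVector& w,
                         const NumericVector& gy, int s, int p, int op) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), gd = dims_of(gy);
  int Hi = xd[0], Wi = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[2];
  int Ho = gd[0], Wo = gd[1];
  int Hf = (Hi - 1) * s + kh + op, Wf = (Wi - 1) * s + kw + op;
  size_t K2 = (size_t)kh * kw * Cout, L = (size_t)Hi * Wi * N;

  arma::Mat<eT> gycols(L, K2);
  arma::Col<eT> buf((size_t)Hf * Wf * Cout);
  arma::Col<eT> gb(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    buf.zeros();
    const double* src = gy.begin() + (size_t)n * Ho * Wo * Cout;
    eT* bpt = buf.memptr();
    for (int c = 0; c < Cout; ++c) {
      eT acc = 0;
      for (int ww = 0; ww < Wo; ++ww) {
        const double* scol = src + (size_t)c * Ho * Wo + (size_t)ww * Ho;
        eT* dcol = bpt + (size_t)c * Hf * Wf + (size_t)(ww + p) * Hf + p;
        for (int h = 0; h < Ho; ++h) { dcol[h] = (eT)scol[h]; acc += (eT)scol[h]; }
      }
      gb[c] += acc;
    }
    im2col<eT>(buf.memptr(), Hf, Wf, Cout, kh, kw, s, Hi, Wi, gycols,
               (size_t)n * Hi * Wi);
  }
  arma::Col<eT> wv = to_eT<eT>(w);
  arma::Mat<eT> Wm(wv.memptr(), K2, Cin, false, true);
  arma::Mat<eT> GX = gycols * Wm;                        // L x Cin

  NumericVector gxR((R_xlen_t)((size_t)Hi * Wi * Cin * N));
  for (int n = 0; n < N; ++n)
    block_to_R(GX, (size_t)n * Hi * Wi, (size_t)Hi * Wi,
               gxR.begin() + (size_t)n * Hi * Wi * Cin);
  gxR.attr("dim") = IntegerVector::create(Hi, Wi, Cin, N);

  arma::Mat<eT> X(L, Cin);
  for (int n = 0; n < N; ++n)
    block_from_R(X, (size_t)n * Hi * Wi, (size_t)Hi * Wi,
                 x.begin() + (size_t)n * Hi * Wi * Cin);
  arma::Mat<eT> gw = gycols.t() * X;                     // K2 x Cin

  return List::create(
    _["gx"] = gxR,
    _["gw"] = to_R(gw, dims_of(w)),
    _["gb"] = to_R(arma::Mat<eT>(gb), IntegerVector::create(Cout)));
}

// [[Rcpp::export]]
List convt2d_bw_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int out_pad, bool single) {
  return single ? convt2d_bw_t<float>(x, w, gy, stride, pad, out_pad)
                : convt2d_bw_t<double>(x, w, gy, stride, pad, out_pad);
}
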
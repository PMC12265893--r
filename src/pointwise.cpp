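// Fused elementwise kernels for the ConvLSTM cell update, batch-norm
// application and dropout. These are pure pointwise operations; fusing them
// avoids a dozen full-array temporaries per recurrence step in R.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid1(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static NumericVector with_dim(NumericVector v, int H, int W, int C, int N) {
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

// pre: (H, W, 4*hidden, N) gate pre-activations in blocks (i, f, g, o);
// c_prev: (H, W, hidden, N) or NULL. Returns gates, new cell/hidden state
// and tanh(c_new).
// [[Rcpp::export]]
List lstm_point_fw_cpp(NumericVector pre, Nullable<NumericVector> c_prev) {
  IntegerVector d = pre.attr("dim");
  int H = d[0], W = d[1], C4 = d[2], N = d[3];
  int hidden = C4 / 4;
  size_t plane = (size_t)H * W;
  size_t block = plane * hidden;
  NumericVector i_g(block * N), f_g(block * N), g_g(block * N),
      o_g(block * N), c_new(block * N), h_new(block * N), tc(block * N);
  const double* cp = c_prev.isNotNull() ?
      NumericVector(c_prev).begin() : nullptr;
  const double* pp = pre.begin();
  for (int n = 0; n < N; ++n) {
    const double* base = pp + (size_t)n * plane * C4;
    size_t off = (size_t)n * block;
    for (size_t k = 0; k < block; ++k) {
      double iv = sigmoid1(base[k]);
      double fv = sigmoid1(base[k + block]);
      double gv = std::tanh(base[k + 2 * block]);
      double ov = sigmoid1(base[k + 3 * block]);
      double cprev = cp ? cp[off + k] : 0.0;
      double cv = fv * cprev + iv * gv;
      double t = std::tanh(cv);
      i_g[off + k] = iv; f_g[off + k] = fv; g_g[off + k] = gv;
      o_g[off + k] = ov; c_new[off + k] = cv; tc[off + k] = t;
      h_new[off + k] = ov * t;
    }
  }
  return List::create(
    _["h"] = with_dim(h_new, H, W, hidden, N),
    _["c"] = with_dim(c_new, H, W, hidden, N),
    _["i"] = with_dim(i_g, H, W, hidden, N),
    _["f"] = with_dim(f_g, H, W, hidden, N),
    _["g"] = with_dim(g_g, H, W, hidden, N),
    _["o"] = with_dim(o_g, H, W, hidden, N),
    _["tanh_c"] = with_dim(tc, H, W, hidden, N));
}

// Backward of the cell update. gh: gradient on h_t (plus any recurrent
// contribution already added); gc_in: recurrent cell gradient or NULL.
// Returns gate pre-activation gradients (4*hidden blocks) and gc_prev.
// [[Rcpp::export]]
List lstm_point_bw_cpp(NumericVector gh, Nullable<NumericVector> gc_in,
                       NumericVector i_g, NumericVector f_g,
                       NumericVector g_g, NumericVector o_g,
                       NumericVector tc, Nullable<NumericVector> c_prev) {
  IntegerVector d = gh.attr("dim");
  int H = d[0], W = d[1], hidden = d[2], N = d[3];
  size_t plane = (size_t)H * W;
  size_t block = plane * hidden;
  NumericVector gpre(block * N * 4), gc_prev(block * N);
  const double* gci = gc_in.isNotNull() ?
      NumericVector(gc_in).begin() : nullptr;
  const double* cp = c_prev.isNotNull() ?
      NumericVector(c_prev).begin() : nullptr;
  for (int n = 0; n < N; ++n) {
    size_t off = (size_t)n * block;
    double* gp = gpre.begin() + (size_t)n * 4 * block;
    for (size_t k = 0; k < block; ++k) {
      size_t s = off + k;
      double t = tc[s];
      double gc = gh[s] * o_g[s] * (1.0 - t * t);
      if (gci) gc += gci[s];
      double go = gh[s] * t;
      double cprev = cp ? cp[s] : 0.0;
      double gi = gc * g_g[s];
      double gg = gc * i_g[s];
      double gf = gc * cprev;
      gc_prev[s] = gc * f_g[s];
      gp[k] = gi * i_g[s] * (1.0 - i_g[s]);
      gp[k + block] = gf * f_g[s] * (1.0 - f_g[s]);
      gp[k + 2 * block] = gg * (1.0 - g_g[s] * g_g[s]);
      gp[k + 3 * block] = go * o_g[s] * (1.0 - o_g[s]);
    }
  }
  return List::create(
    _["gpre"] = with_dim(gpre, H, W, 4 * hidden, N),
    _["gc_prev"] = with_dim(gc_prev, H, W, hidden, N));
}

// y = x * scale[channel] + shift[channel] for an (H, W, C, N) array.
// [[Rcpp::export]]
NumericVector bn_apply_cpp(NumericVector x, NumericVector scale,
                           NumericVector shift) {
  IntegerVector d = x.attr("dim");
  int C = d[2], N = d[3];
  size_t plane = (size_t)d[0] * d[1];
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = scale[c], b = shift[c];
      const double* xs = xp + ((size_t)n * C + c) * plane;
      double* ys = yp + ((size_t)n * C + c) * plane;
      for (size_t k = 0; k < plane; ++k) ys[k] = xs[k] * a + b;
    }
  y.attr("dim") = d;
  return y;
}

// Inverted dropout using R's RNG: returns the masked activations and the
// mask itself (0 or 1/(1-p)) for the backward pass.
// [[Rcpp::export]]
List dropout_fw_cpp(NumericVector x, double p) {
  RNGScope scope;
  double keep = 1.0 - p;
  NumericVector y(x.size()), mask(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    double m = (unif_rand() < p) ? 0.0 : 1.0 / keep;
    mask[k] = m;
    y[k] = x[k] * m;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mask"] = mask);
}

// ReLU forward returning both activation and, on backward, the masked grad
// is a plain multiply; only the forward fuse is worth exporting.
// [[Rcpp::export]]
NumericVector relu_cpp(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) y[k] = x[k] > 0 ? x[k] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}
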
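#' @useDynLib hicspot, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Internal neural-network primitives. Feature maps are 4-D arrays laid out
# (H, W, C, N); conv weights (kh, kw, Cin, Cout); transposed-conv weights
# (kh, kw, Cout, Cin). `single = TRUE` computes in float32 (training default).

conv2d <- function(x, w, b, stride = 1L, pad = 0L, single = TRUE) {
  conv2d_fw_cpp(x, w, b, as.integer(stride), as.integer(pad), single)
}

conv2d_grad <- function(x, w, gy, stride = 1L, pad = 0L, need_gx = TRUE,
                        single = TRUE) {
  conv2d_bw_cpp(x, w, gy, as.integer(stride), as.integer(pad), need_gx, single)
}

convt2d <- function(x, w, b, stride = 1L, pad = 0L, out_pad = 0L, single = TRUE) {
  convt2d_fw_cpp(x, w, b, as.integer(stride), as.integer(pad),
                 as.integer(out_pad), single)
}

convt2d_grad <- function(x, w, gy, stride = 1L, pad = 0L, out_pad = 0L,
                         single = TRUE) {
  convt2d_bw_cpp(x, w, gy, as.integer(stride), as.integer(pad),
                 as.integer(out_pad), single)
}

conv_out_size <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

sigmoid <- function(x) 1 / (1 + exp(-x))

# Per-channel sums of an (H, W, C, N) array; returns length-C vector.
channel_sums <- function(x) {
  d <- dim(x)
  m <- matrix(.colSums(x, d[1L] * d[2L], d[3L] * d[4L]), d[3L], d[4L])
  .rowSums(m, d[3L], d[4L])
}

# Broadcast a per-channel vector over an (H, W, C, N) array.
channel_expand <- function(v, d) rep(rep(v, each = d[1L] * d[2L]), times = d[4L])

# Batch normalization over (H, W, N) per channel; running statistics use
# momentum 0.1 with the unbiased variance, evaluation mode applies them.
batchnorm_forward <- function(x, bn, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- d[1L] * d[2L] * d[4L]
  if (training) {
    mu <- channel_sums(x) / m
    xhat <- bn_apply_cpp(x, rep(1, d[3L]), -mu)        # centered
    var_b <- channel_sums(xhat * xhat) / m
    invstd <- 1 / sqrt(var_b + eps)
    xhat <- bn_apply_cpp(xhat, invstd, rep(0, d[3L]))
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    var_u <- if (m > 1) var_b * m / (m - 1) else var_b
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * var_u
    cache <- list(xhat = xhat, invstd = invstd)
  } else {
    invstd <- 1 / sqrt(bn$running_var + eps)
    xhat <- bn_apply_cpp(x, invstd, -bn$running_mean * invstd)
    cache <- NULL
  }
  y <- bn_apply_cpp(xhat, bn$gamma, bn$beta)
  list(y = y, bn = bn, cache = cache)
}

batchnorm_backward <- function(gy, bn, cache) {
  d <- dim(gy)
  m <- d[1L] * d[2L] * d[4L]
  xhat <- cache$xhat
  ggamma <- channel_sums(gy * xhat)
  gbeta <- channel_sums(gy)
  s <- bn$gamma * cache$invstd
  gx <- bn_apply_cpp(gy, s, -gbeta * s / m) -
    bn_apply_cpp(xhat, ggamma * s / m, rep(0, d[3L]))
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  dropout_fw_cpp(x, p)
}

dropout_backward <- function(gy, mask) {
  if (is.null(mask)) return(gy)
  g <- gy * mask
  dim(g) <- dim(gy)
  g
}
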
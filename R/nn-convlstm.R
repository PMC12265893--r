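# Convolutional LSTM: gates are 2-D convolutions over the input and previous
# hidden state; state updates follow the standard LSTM algebra. Gate channel
# order within the fused convolution output is (input, forget, candidate,
# output), each block `hidden` channels wide.

#' One convolutional LSTM cell update
#'
#' Applies a single ConvLSTM step: input, forget and output gates and the
#' candidate state are computed by 3x3 (or `k` x `k`) convolutions of the
#' current input and the previous hidden state; the cell state is
#' `c_new = f * c + i * g` and the hidden state `h_new = o * tanh(c_new)`.
#' Spatial size is preserved (padding `(k-1)/2`).
#'
#' @param x Input feature map, array `(H, W, C)` or `(H, W, C, N)`.
#' @param state List with `h` and `c` arrays shaped like the hidden map, or
#'   `NULL` for the all-zero initial state.
#' @param weights List with `wx` (`k, k, C, 4*hidden`), `wh`
#'   (`k, k, hidden, 4*hidden`) and `b` (length `4*hidden`).
#' @param single Compute convolutions in single precision.
#' @return List with updated `h` and `c` (same shape, `hidden` channels) and
#'   the gate maps `i`, `f`, `g`, `o`.
#' @examples
#' w <- list(wx = array(0, c(3, 3, 1, 4)), wh = array(0, c(3, 3, 1, 4)),
#'           b = rep(0, 4))
#' st <- convlstm_cell(array(0, c(5, 5, 1)), NULL, w)
#' stopifnot(all(st$i == 0.5), all(st$h == 0))
#' @export
convlstm_cell <- function(x, state = NULL, weights, single = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  k <- dim(weights$wx)[1L]
  hidden <- dim(weights$wx)[4L] %/% 4L
  hd <- c(d[1L], d[2L], hidden, d[4L])
  if (is.null(state)) state <- list(h = array(0, hd), c = array(0, hd))
  if (!identical(dim(state$h), dim(state$c)))
    stop("convlstm_cell: hidden and cell state shapes differ")
  if (!identical(dim(state$h)[1:2], d[1:2]))
    stop("convlstm_cell: state and input are not spatially aligned")
  pad <- (k - 1L) %/% 2L
  pre <- conv2d(x, weights$wx, weights$b, 1L, pad, single) +
    conv2d(state$h, weights$wh, numeric(dim(weights$wh)[4L]), 1L, pad, single)
  dim(pre) <- c(d[1L], d[2L], 4L * hidden, d[4L])
  lstm_point_fw_cpp(pre, state$c)
}

# Forward pass of one ConvLSTM layer over a full sequence. The input
# convolution has no temporal dependence, so it is evaluated for all T
# frames in one batched call; only the hidden-state convolution recurs.
# xs: list of T arrays (H, W, Cin, N). Returns hidden sequence plus caches.
convlstm_layer_forward <- function(xs, weights, single = TRUE) {
  T_ <- length(xs)
  n <- dim(xs[[1L]])[4L]
  k <- dim(weights$wx)[1L]
  pad <- (k - 1L) %/% 2L
  hidden <- dim(weights$wx)[4L] %/% 4L
  xall <- stack_frames(xs, n)
  pre_x <- conv2d(xall, weights$wx, weights$b, 1L, pad, single)
  d <- dim(pre_x)
  hs <- vector("list", T_)
  caches <- vector("list", T_)
  state <- NULL
  zero_b <- numeric(4L * hidden)
  for (t in seq_len(T_)) {
    pre <- pre_x[, , , (t - 1L) * n + seq_len(n), drop = FALSE]
    if (!is.null(state))
      pre <- pre + conv2d(state$h, weights$wh, zero_b, 1L, pad, single)
    dim(pre) <- c(d[1L], d[2L], d[3L], n)
    st <- lstm_point_fw_cpp(pre, if (is.null(state)) NULL else state$c)
    hs[[t]] <- st$h
    caches[[t]] <- list(
      h_prev = if (is.null(state)) NULL else state$h,
      c_prev = if (is.null(state)) NULL else state$c,
      i = st$i, f = st$f, g = st$g, o = st$o, tanh_c = st$tanh_c)
    state <- list(h = st$h, c = st$c)
  }
  list(hs = hs, caches = caches, xall = xall)
}

# Backward pass (BPTT) of one ConvLSTM layer. Gate pre-activation gradients
# are collected over all T steps and pushed through the input convolution in
# one batched call; the hidden-state convolution is walked backwards in time.
convlstm_layer_backward <- function(xs, weights, caches, ghs, single = TRUE,
                                    xall = NULL) {
  T_ <- length(xs)
  n <- dim(xs[[1L]])[4L]
  k <- dim(weights$wx)[1L]
  pad <- (k - 1L) %/% 2L
  hidden <- dim(weights$wx)[4L] %/% 4L
  gwh <- array(0, dim(weights$wh))
  d <- dim(caches[[T_]]$i)
  gpre_all <- array(0, c(d[1L], d[2L], 4L * hidden, n * T_))
  gh_rec <- NULL
  gc_rec <- NULL
  zeros_h <- array(0, d)
  for (t in rev(seq_len(T_))) {
    cc <- caches[[t]]
    gh <- ghs[[t]]
    if (!is.null(gh_rec)) gh <- gh + gh_rec
    dim(gh) <- d
    pb <- lstm_point_bw_cpp(gh, gc_rec, cc$i, cc$f, cc$g, cc$o,
                            cc$tanh_c, cc$c_prev)
    gpre <- pb$gpre
    gc_rec <- pb$gc_prev
    gpre_all[, , , (t - 1L) * n + seq_len(n)] <- gpre
    h_prev <- if (is.null(cc$h_prev)) zeros_h else cc$h_prev
    bh <- conv2d_grad(h_prev, weights$wh, gpre, 1L, pad,
                      need_gx = !is.null(cc$h_prev), single)
    gwh <- gwh + bh$gw
    gh_rec <- if (is.null(cc$h_prev)) NULL else bh$gx
  }
  if (is.null(xall)) xall <- stack_frames(xs, n)
  bx <- conv2d_grad(xall, weights$wx, gpre_all, 1L, pad, TRUE, single)
  list(gxs = split_frames(bx$gx, n, T_), gwx = bx$gw, gwh = gwh, gb = bx$gb)
}
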
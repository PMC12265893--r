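# Spatiotemporal autoencoder: per-frame convolutional spatial encoder, a
# five-layer ConvLSTM temporal encoder-decoder over the frame sequence, and a
# transposed-convolution spatial decoder ending in a sigmoid. The model is
# trained to reconstruct its input sequence; reconstruction error is the
# anomaly signal.

#' Model architecture configuration
#'
#' Defines the spatial encoder (three strided convolutions, each followed by
#' batch normalization and ReLU), the ConvLSTM stack, and the mirrored
#' transposed-convolution decoder whose final layer uses a sigmoid so outputs
#' lie in (0, 1). Output padding of each decoder layer is computed at build
#' time so the decoder recovers the encoder's input size exactly.
#'
#' @param input_size Window height/width in bins (default 50).
#' @param in_channels Input channels (default 1).
#' @param enc_channels Encoder output channels per layer.
#' @param enc_kernels,enc_strides,enc_pads Encoder convolution geometry.
#' @param lstm_hidden Hidden-state channels of the ConvLSTM layers.
#' @param lstm_kernel ConvLSTM convolution kernel size (spatial size is
#'   preserved).
#' @param dec_kernels,dec_strides,dec_pads Decoder transposed-convolution
#'   geometry (mirror of the encoder).
#' @param dropout Dropout probability used in training mode.
#' @param precision `"single"` (training default) or `"double"`.
#' @return An object of class `hicspot_config`.
#' @export
model_config <- function(input_size = 50L, in_channels = 1L,
                         enc_channels = c(32L, 64L, 64L),
                         enc_kernels = c(7L, 5L, 3L),
                         enc_strides = c(2L, 2L, 1L),
                         enc_pads = c(3L, 2L, 1L),
                         lstm_hidden = c(64L, 64L, 32L, 64L, 64L),
                         lstm_kernel = 3L,
                         dec_kernels = c(3L, 5L, 7L),
                         dec_strides = c(1L, 2L, 2L),
                         dec_pads = c(1L, 2L, 3L),
                         dropout = 0.3,
                         precision = c("single", "double")) {
  precision <- match.arg(precision)
  stopifnot(length(enc_channels) == 3L, length(dec_kernels) == 3L,
            dropout >= 0, dropout < 1)
  sizes <- integer(4L)
  sizes[1L] <- as.integer(input_size)
  for (l in 1:3) {
    if (sizes[l] + 2L * enc_pads[l] < enc_kernels[l])
      stop(sprintf("encoder layer %d: input %d too small for kernel %d",
                   l, sizes[l], enc_kernels[l]))
    sizes[l + 1L] <- conv_out_size(sizes[l], enc_kernels[l], enc_strides[l],
                                   enc_pads[l])
    if (sizes[l + 1L] < 1L)
      stop(sprintf("encoder layer %d collapses input to zero size", l))
  }
  dec_channels <- c(enc_channels[2L], enc_channels[1L], as.integer(in_channels))
  dec_targets <- c(sizes[3L], sizes[2L], sizes[1L])
  dec_out_pads <- integer(3L)
  n_in <- sizes[4L]
  for (m in 1:3) {
    base <- (n_in - 1L) * dec_strides[m] - 2L * dec_pads[m] + dec_kernels[m]
    op <- dec_targets[m] - base
    if (op < 0L || op >= max(dec_strides[m], 1L) + 1L)
      stop(sprintf(
        "decoder layer %d: cannot recover size %d (achievable %d..%d)",
        m, dec_targets[m], base, base + dec_strides[m]))
    dec_out_pads[m] <- op
    n_in <- dec_targets[m]
  }
  structure(list(
    input_size = as.integer(input_size), in_channels = as.integer(in_channels),
    enc_channels = as.integer(enc_channels),
    enc_kernels = as.integer(enc_kernels),
    enc_strides = as.integer(enc_strides), enc_pads = as.integer(enc_pads),
    lstm_hidden = as.integer(lstm_hidden),
    lstm_kernel = as.integer(lstm_kernel),
    dec_channels = dec_channels, dec_kernels = as.integer(dec_kernels),
    dec_strides = as.integer(dec_strides), dec_pads = as.integer(dec_pads),
    dec_out_pads = dec_out_pads, dec_targets = dec_targets,
    sizes = sizes, latent_size = sizes[4L],
    dropout = dropout, precision = precision),
    class = "hicspot_config")
}

#' Reduced-size model configuration for desk-scale experiments
#'
#' Same architecture with halved channel counts: encoder channels
#' `(16, 32, 32)` and ConvLSTM hidden sizes `(32, 32, 16, 32, 32)`.
#'
#' @param ... Overrides passed on to [model_config()].
#' @export
reduced_model_config <- function(...) {
  args <- list(...)
  defaults <- list(enc_channels = c(16L, 32L, 32L),
                   lstm_hidden = c(32L, 32L, 16L, 32L, 32L))
  do.call(model_config, utils::modifyList(defaults, args))
}

new_bn <- function(ch) {
  list(gamma = rep(1, ch), beta = rep(0, ch),
       running_mean = rep(0, ch), running_var = rep(1, ch))
}

#' Initialize an untrained spatiotemporal autoencoder
#'
#' Convolution weights use He-normal initialization; ConvLSTM gate
#' convolutions use Glorot-uniform with the forget-gate bias set to 1.
#'
#' @param config A [model_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class `hicspot_model` holding `config` and `params`.
#' @export
hicspot_model <- function(config = model_config(), seed = NULL) {
  stopifnot(inherits(config, "hicspot_config"))
  if (!is.null(seed)) set.seed(seed)
  he <- function(kh, kw, cin, cout)
    array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
          c(kh, kw, cin, cout))
  glorot <- function(kh, kw, cin, cout) {
    a <- sqrt(6 / (kh * kw * (cin + cout)))
    array(stats::runif(kh * kw * cin * cout, -a, a), c(kh, kw, cin, cout))
  }
  enc <- vector("list", 3L)
  cin <- config$in_channels
  for (l in 1:3) {
    cout <- config$enc_channels[l]
    enc[[l]] <- list(w = he(config$enc_kernels[l], config$enc_kernels[l],
                            cin, cout),
                     b = rep(0, cout), bn = new_bn(cout))
    cin <- cout
  }
  k <- config$lstm_kernel
  lstm <- vector("list", length(config$lstm_hidden))
  for (l in seq_along(config$lstm_hidden)) {
    h <- config$lstm_hidden[l]
    b <- rep(0, 4L * h)
    b[h + 1:h] <- 1  # forget gate bias
    lstm[[l]] <- list(wx = glorot(k, k, cin, 4L * h),
                      wh = glorot(k, k, h, 4L * h), b = b)
    cin <- h
  }
  dec <- vector("list", 3L)
  for (m in 1:3) {
    cout <- config$dec_channels[m]
    # transposed-conv weight layout (kh, kw, Cout, Cin)
    dec[[m]] <- list(w = he(config$dec_kernels[m], config$dec_kernels[m],
                            cout, cin),
                     b = rep(0, cout),
                     bn = if (m < 3L) new_bn(cout) else NULL)
    cin <- cout
  }
  structure(list(config = config, params = list(enc = enc, lstm = lstm,
                                                dec = dec)),
            class = "hicspot_model")
}

single_prec <- function(config) identical(config$precision, "single")

# ---- full forward/backward on an internal batch ----------------------------
# xb: (H, W, C, N*T) with frame-major blocks (frame t = columns (t-1)*N+1 .. t*N)

encoder_forward <- function(model, xb, training) {
  cfg <- model$config
  sp <- single_prec(cfg)
  caches <- vector("list", 3L)
  e <- xb
  for (l in 1:3) {
    z <- tryCatch(
      conv2d(e, model$params$enc[[l]]$w, model$params$enc[[l]]$b,
             cfg$enc_strides[l], cfg$enc_pads[l], sp),
      error = function(err)
        stop(sprintf("spatial encoder layer %d: %s", l, conditionMessage(err))))
    bnf <- batchnorm_forward(z, model$params$enc[[l]]$bn, training)
    model$params$enc[[l]]$bn <- bnf$bn
    a <- relu_cpp(bnf$y)
    dr <- dropout_forward(a, cfg$dropout, training)
    caches[[l]] <- list(x = e, bn_cache = bnf$cache, act = bnf$y,
                        mask = dr$mask)
    e <- dr$y
  }
  list(out = e, caches = caches, model = model)
}

encoder_backward <- function(model, caches, gy) {
  cfg <- model$config
  sp <- single_prec(cfg)
  grads <- vector("list", 3L)
  g <- gy
  for (l in 3:1) {
    cc <- caches[[l]]
    g <- dropout_backward(g, cc$mask)
    g <- g * (cc$act > 0)
    dim(g) <- dim(cc$act)
    bnb <- batchnorm_backward(g, model$params$enc[[l]]$bn, cc$bn_cache)
    cb <- conv2d_grad(cc$x, model$params$enc[[l]]$w, bnb$gx,
                      cfg$enc_strides[l], cfg$enc_pads[l],
                      need_gx = (l > 1L), single = sp)
    grads[[l]] <- list(w = cb$gw, b = cb$gb,
                       bn = list(gamma = bnb$ggamma, beta = bnb$gbeta))
    g <- cb$gx
  }
  list(grads = grads)
}

lstm_forward <- function(model, xs, training) {
  cfg <- model$config
  sp <- single_prec(cfg)
  L <- length(model$params$lstm)
  caches <- vector("list", L)
  seqs <- xs
  for (l in seq_len(L)) {
    fw <- convlstm_layer_forward(seqs, model$params$lstm[[l]], sp)
    hs <- fw$hs
    masks <- NULL
    if (l < L) {
      masks <- vector("list", length(hs))
      for (t in seq_along(hs)) {
        dr <- dropout_forward(hs[[t]], cfg$dropout, training)
        hs[[t]] <- dr$y
        masks[t] <- list(dr$mask)  # keep NULL masks as elements
      }
    }
    caches[[l]] <- list(xs = seqs, lstm = fw$caches, masks = masks,
                        xall = fw$xall)
    seqs <- hs
  }
  list(out = seqs, caches = caches)
}

lstm_backward <- function(model, caches, ghs) {
  cfg <- model$config
  sp <- single_prec(cfg)
  L <- length(model$params$lstm)
  grads <- vector("list", L)
  g <- ghs
  for (l in rev(seq_len(L))) {
    cc <- caches[[l]]
    if (!is.null(cc$masks))
      for (t in seq_along(g)) g[[t]] <- dropout_backward(g[[t]], cc$masks[[t]])
    bw <- convlstm_layer_backward(cc$xs, model$params$lstm[[l]], cc$lstm, g,
                                  sp, xall = cc$xall)
    grads[[l]] <- list(wx = bw$gwx, wh = bw$gwh, b = bw$gb)
    g <- bw$gxs
  }
  list(grads = grads, gxs = g)
}

decoder_forward <- function(model, xb, training) {
  cfg <- model$config
  sp <- single_prec(cfg)
  caches <- vector("list", 3L)
  d <- xb
  for (m in 1:3) {
    z <- convt2d(d, model$params$dec[[m]]$w, model$params$dec[[m]]$b,
                 cfg$dec_strides[m], cfg$dec_pads[m], cfg$dec_out_pads[m], sp)
    if (dim(z)[1L] != cfg$dec_targets[m])
      stop(sprintf("spatial decoder layer %d: expected size %d, achieved %d",
                   m, cfg$dec_targets[m], dim(z)[1L]))
    if (m < 3L) {
      bnf <- batchnorm_forward(z, model$params$dec[[m]]$bn, training)
      model$params$dec[[m]]$bn <- bnf$bn
      a <- relu_cpp(bnf$y)
      dr <- dropout_forward(a, cfg$dropout, training)
      caches[[m]] <- list(x = d, bn_cache = bnf$cache, act = bnf$y,
                          mask = dr$mask)
      d <- dr$y
    } else {
      y <- sigmoid(z)
      dim(y) <- dim(z)
      caches[[m]] <- list(x = d, y = y)
      d <- y
    }
  }
  list(out = d, caches = caches, model = model)
}

split_frames <- function(xb, n, t_len) {
  lapply(seq_len(t_len), function(t)
    xb[, , , (t - 1L) * n + seq_len(n), drop = FALSE])
}

stack_frames <- function(xs, n) {
  d <- dim(xs[[1L]])
  out <- array(0, c(d[1L], d[2L], d[3L], n * length(xs)))
  for (t in seq_along(xs)) out[, , , (t - 1L) * n + seq_len(n)] <- xs[[t]]
  out
}

model_forward <- function(model, xb, n, t_len, training = FALSE) {
  ef <- encoder_forward(model, xb, training)
  model <- ef$model
  xs <- split_frames(ef$out, n, t_len)
  lf <- lstm_forward(model, xs, training)
  hb <- stack_frames(lf$out, n)
  df <- decoder_forward(model, hb, training)
  model <- df$model
  list(xhat = df$out, model = model,
       cache = list(enc = ef$caches, lstm = lf$caches, dec = df$caches,
                    n = n, t_len = t_len))
}

model_backward <- function(model, cache, gxhat) {
  cfg <- model$config
  sp <- single_prec(cfg)
  # decoder backward also yields the gradient w.r.t. its input
  grads_dec <- vector("list", 3L)
  g <- gxhat
  for (m in 3:1) {
    cc <- cache$dec[[m]]
    if (m == 3L) {
      g <- g * cc$y * (1 - cc$y)
      dim(g) <- dim(cc$y)
    } else {
      g <- dropout_backward(g, cc$mask)
      g <- g * (cc$act > 0)
      dim(g) <- dim(cc$act)
      bnb <- batchnorm_backward(g, model$params$dec[[m]]$bn, cc$bn_cache)
      g <- bnb$gx
    }
    cb <- convt2d_grad(cc$x, model$params$dec[[m]]$w, g,
                       cfg$dec_strides[m], cfg$dec_pads[m],
                       cfg$dec_out_pads[m], sp)
    grads_dec[[m]] <- if (m == 3L) list(w = cb$gw, b = cb$gb) else
      list(w = cb$gw, b = cb$gb,
           bn = list(gamma = bnb$ggamma, beta = bnb$gbeta))
    g <- cb$gx
  }
  ghs <- split_frames(g, cache$n, cache$t_len)
  lb <- lstm_backward(model, cache$lstm, ghs)
  genc <- stack_frames(lb$gxs, cache$n)
  eb <- encoder_backward(model, cache$enc, genc)
  list(enc = eb$grads, lstm = lb$grads, dec = grads_dec)
}

# ---- exported stage operations --------------------------------------------

as_thwc <- function(frames) {
  d <- dim(frames)
  if (is.null(d) || length(d) != 4L)
    stop("expected a T x H x W x C array")
  d
}

# (T,H,W,C) -> (H,W,C,T) batch and back
thwc_to_batch <- function(frames) aperm(frames, c(2L, 3L, 4L, 1L))
batch_to_thwc <- function(xb) aperm(xb, c(4L, 1L, 2L, 3L))

#' Spatial encoder: per-frame convolutional feature extraction
#'
#' Passes each frame independently through three strided convolutions with
#' batch normalization and ReLU, reducing spatial resolution (50 -> 13 with
#' the default geometry). Dropout is active only in `"train"` mode.
#'
#' @param frames `T x H x W x C` array.
#' @param model A [hicspot_model()] (or fitted model's `$model`).
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @return `T x H' x W' x C'` feature array.
#' @export
spatial_encode <- function(frames, model, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  as_thwc(frames)
  ef <- encoder_forward(model, thwc_to_batch(frames), mode == "train")
  batch_to_thwc(ef$out)
}

#' ConvLSTM temporal encoder-decoder over a feature sequence
#'
#' Runs the stacked ConvLSTM layers over the full sequence; layer `l` consumes
#' the complete hidden-state sequence of layer `l-1`, states start at zero,
#' and the top layer's hidden-state sequence is returned (one map per frame).
#'
#' @param features `T x H' x W' x C'` array from [spatial_encode()].
#' @inheritParams spatial_encode
#' @return `T x H' x W' x C''` array, `C''` the top hidden size.
#' @export
temporal_encode_decode <- function(features, model, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  d <- as_thwc(features)
  xb <- thwc_to_batch(features)
  xs <- split_frames(xb, 1L, d[1L])
  lf <- lstm_forward(model, xs, mode == "train")
  batch_to_thwc(stack_frames(lf$out, 1L))
}

#' Spatial decoder: transposed convolutions back to input resolution
#'
#' Three transposed convolutions (batch normalization + ReLU after the first
#' two, sigmoid on the last) recover the encoder's input spatial size exactly;
#' outputs are strictly in (0, 1).
#'
#' @param features `T x H' x W' x C''` array from [temporal_encode_decode()].
#' @inheritParams spatial_encode
#' @return `T x H x W x C` array.
#' @export
spatial_decode <- function(features, model, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  as_thwc(features)
  df <- decoder_forward(model, thwc_to_batch(features), mode == "train")
  batch_to_thwc(df$out)
}

#' Reconstruct a normalized window sequence
#'
#' Full autoencoder pass `decode(temporal(encode(X)))` with the mean-squared
#' reconstruction loss attached. Deterministic in `"eval"` mode.
#'
#' @param sample `T x H x W x C` array in `[0, 1]`, or a `window_sample`.
#' @inheritParams spatial_encode
#' @return List with `reconstructed` (same shape, values in (0, 1)) and
#'   `loss` (scalar mean squared error).
#' @export
reconstruct <- function(sample, model, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  x <- if (inherits(sample, "window_sample")) sample$data else sample
  d <- as_thwc(x)
  if (min(x) < 0 || max(x) > 1)
    stop("reconstruct: input must be normalized to [0, 1]; range is [",
         signif(min(x), 4), ", ", signif(max(x), 4), "]")
  if (inherits(model, "hicspot_fit")) model <- model$model
  fw <- model_forward(model, thwc_to_batch(x), 1L, d[1L],
                      training = mode == "train")
  xhat <- batch_to_thwc(fw$xhat)
  list(reconstructed = xhat, loss = reconstruction_loss(x, xhat))
}

#' Mean squared reconstruction error
#'
#' The mean over all `T * H * W * C` elements of the squared difference
#' between a sequence and its reconstruction.
#'
#' @param x,x_hat Arrays of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat)))
    stop("reconstruction_loss: shape mismatch (",
         paste(dim(x), collapse = "x"), " vs ",
         paste(dim(x_hat), collapse = "x"), ")")
  mean((x - x_hat)^2)
}
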
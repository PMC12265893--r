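# Training: AdamW on the mean-squared reconstruction loss, with validation
# based early stopping and best-checkpoint restore.

#' Training hyperparameters
#'
#' @param learning_rate AdamW step size.
#' @param weight_decay Decoupled weight decay (applied to convolution and
#'   ConvLSTM weights, not to biases or batch-norm parameters).
#' @param batch_size Windows per gradient step.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early stopping: stop after this many consecutive epochs
#'   without validation improvement (`0` stops at the first non-improving
#'   epoch).
#' @param beta1,beta2,eps Adam moment parameters.
#' @param max_grad_norm Global gradient-norm clip (`Inf` disables).
#' @export
train_control <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                          batch_size = 32L, max_epochs = 100L, patience = 25L,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          max_grad_norm = Inf) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, patience >= 0, patience <= max_epochs)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 max_grad_norm = max_grad_norm),
            class = "hicspot_control")
}

# recursive AdamW over the grads structure (params may hold extra leaves,
# e.g. batch-norm running stats, which are skipped)
adamw_step <- function(params, grads, state, ctl, step, scale = 1) {
  decay_names <- c("w", "wx", "wh")
  walk <- function(p, g, s, path_name) {
    if (is.numeric(g)) {
      if (is.null(s)) s <- list(m = 0 * g, v = 0 * g)
      g <- as.numeric(g) * scale
      s$m <- ctl$beta1 * s$m + (1 - ctl$beta1) * g
      s$v <- ctl$beta2 * s$v + (1 - ctl$beta2) * g * g
      mhat <- s$m / (1 - ctl$beta1^step)
      vhat <- s$v / (1 - ctl$beta2^step)
      upd <- mhat / (sqrt(vhat) + ctl$eps)
      if (path_name %in% decay_names) upd <- upd + ctl$weight_decay * p
      pnew <- p - ctl$learning_rate * upd
      dim(pnew) <- dim(p)
      return(list(p = pnew, s = s))
    }
    if (is.null(s)) s <- vector("list", length(g))
    for (i in seq_along(g)) {
      nm <- if (!is.null(names(g))) names(g)[i] else ""
      key <- if (nzchar(nm)) nm else i
      res <- walk(p[[key]], g[[i]], s[[i]], nm)
      p[[key]] <- res$p
      s[[i]] <- res$s
    }
    list(p = p, s = s)
  }
  walk(params, grads, state, "")
}

grad_sumsq <- function(g) {
  if (is.numeric(g)) return(sum(as.numeric(g)^2))
  sum(vapply(g, grad_sumsq, numeric(1)))
}

# windows: list of (T,H,W,C) arrays / window_samples, or a 5-D (T,H,W,C,N)
# array. Returns list of plain arrays.
as_window_list <- function(windows) {
  if (is.array(windows) && length(dim(windows)) == 5L) {
    d <- dim(windows)
    return(lapply(seq_len(d[5L]), function(i)
      array(windows[, , , , i], d[1:4])))
  }
  if (is.array(windows) && length(dim(windows)) == 4L) return(list(windows))
  lapply(windows, function(w) if (inherits(w, "window_sample")) w$data else w)
}

# list of (T,H,W,C) -> (H,W,C,N*T) frame-major batch
windows_to_batch <- function(wl) {
  arr <- simplify2array(wl)              # (T,H,W,C,N)
  d <- dim(arr)
  xb <- aperm(arr, c(2L, 3L, 4L, 5L, 1L))  # (H,W,C,N,T)
  dim(xb) <- c(d[2L], d[3L], d[4L], d[5L] * d[1L])
  xb
}

batch_loss_grad <- function(model, wl, training) {
  t_len <- dim(wl[[1L]])[1L]
  n <- length(wl)
  xb <- windows_to_batch(wl)
  fw <- model_forward(model, xb, n, t_len, training)
  loss <- mean((xb - fw$xhat)^2)
  list(fw = fw, xb = xb, loss = loss, n = n, t_len = t_len)
}

eval_loss <- function(model, wl, batch_size = 32L) {
  n <- length(wl)
  tot <- 0
  for (i in seq(1L, n, by = batch_size)) {
    idx <- i:min(i + batch_size - 1L, n)
    bl <- batch_loss_grad(model, wl[idx], training = FALSE)
    tot <- tot + bl$loss * length(idx)
  }
  tot / n
}

#' Fit the spatiotemporal autoencoder to normalized Hi-C windows
#'
#' Trains the ConvLSTM autoencoder to reconstruct its input window sequences
#' by minimizing the mean squared reconstruction error with AdamW, stopping
#' early when the validation loss has not improved for `control$patience`
#' epochs and restoring the best-validation checkpoint.
#'
#' @param train List of `T x H x W x C` window arrays (values in `[0, 1]`),
#'   `window_sample` objects, or a 5-D array.
#' @param val Validation windows in the same form (required for early
#'   stopping; if `NULL` the training loss is monitored instead).
#' @param config A [model_config()].
#' @param control A [train_control()].
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return An object of class `hicspot_fit` with elements `model` (the
#'   trained [hicspot_model()]), `history` (per-epoch data frame),
#'   `best_epoch`, `control`, and `seed`.
#' @export
hicspot_fit <- function(train, val = NULL, config = model_config(),
                        control = train_control(), seed = 1L,
                        verbose = FALSE) {
  train <- as_window_list(train)
  if (length(train) == 0L) stop("hicspot_fit: empty training set")
  monitor_val <- !is.null(val)
  if (monitor_val) {
    val <- as_window_list(val)
    if (length(val) == 0L) stop("hicspot_fit: empty validation set")
  }
  for (w in train)
    if (min(w) < 0 || max(w) > 1)
      stop("hicspot_fit: windows must be normalized to [0, 1]")
  set.seed(seed)
  model <- hicspot_model(config)
  opt_state <- NULL
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  stall <- 0L
  step <- 0L
  n <- length(train)
  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (i in seq(1L, n, by = control$batch_size)) {
      idx <- ord[i:min(i + control$batch_size - 1L, n)]
      bl <- batch_loss_grad(model, train[idx], training = TRUE)
      if (!is.finite(bl$loss))
        stop(sprintf("hicspot_fit: non-finite loss at epoch %d", epoch))
      model <- bl$fw$model  # batch-norm running stats
      gxhat <- 2 * (bl$fw$xhat - bl$xb) / length(bl$xb)
      grads <- model_backward(model, bl$fw$cache, gxhat)
      scale <- 1
      if (is.finite(control$max_grad_norm)) {
        gn <- sqrt(grad_sumsq(grads))
        if (gn > control$max_grad_norm) scale <- control$max_grad_norm / gn
      }
      step <- step + 1L
      upd <- adamw_step(model$params, grads, opt_state, control, step, scale)
      model$params <- upd$p
      opt_state <- upd$s
      ep_loss <- ep_loss + bl$loss * length(idx)
    }
    ep_loss <- ep_loss / n
    vl <- if (monitor_val) eval_loss(model, val, control$batch_size) else ep_loss
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f", epoch, ep_loss, vl))
    if (vl < best$loss) {
      best <- list(loss = vl, params = model$params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > control$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 best_val_loss = best$loss, control = control, seed = seed),
            class = "hicspot_fit")
}

#' @export
print.hicspot_fit <- function(x, ...) {
  cfg <- x$model$config
  cat("Spatiotemporal Hi-C autoencoder fit\n")
  cat(sprintf("  window %dx%d, latent %dx%d, encoder channels (%s), ConvLSTM hidden (%s)\n",
              cfg$input_size, cfg$input_size, cfg$latent_size, cfg$latent_size,
              paste(cfg$enc_channels, collapse = ","),
              paste(cfg$lstm_hidden, collapse = ",")))
  cat(sprintf("  epochs run: %d, best epoch: %d, best val loss: %.6g\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.hicspot_fit <- function(object, ...) {
  print(object)
  count <- function(g) if (is.numeric(g)) length(g) else
    sum(vapply(g, count, numeric(1)))
  cat(sprintf("  trainable + state parameters: %d\n",
              count(object$model$params)))
  cat("  training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.hicspot_fit <- function(object, ...) object$model$params

#' Reconstruct windows with a fitted model
#'
#' @param object A `hicspot_fit`.
#' @param newdata Windows as in [hicspot_fit()].
#' @param batch_size Windows per forward pass.
#' @param ... Unused.
#' @return List of reconstructed `T x H x W x C` arrays.
#' @export
predict.hicspot_fit <- function(object, newdata, batch_size = 32L, ...) {
  wl <- as_window_list(newdata)
  t_len <- dim(wl[[1L]])[1L]
  out <- vector("list", length(wl))
  for (i in seq(1L, length(wl), by = batch_size)) {
    idx <- i:min(i + batch_size - 1L, length(wl))
    xb <- windows_to_batch(wl[idx])
    fw <- model_forward(object$model, xb, length(idx), t_len, training = FALSE)
    for (j in seq_along(idx)) {
      sel <- (seq_len(t_len) - 1L) * length(idx) + j
      out[[idx[j]]] <- aperm(fw$xhat[, , , sel, drop = FALSE],
                             c(4L, 1L, 2L, 3L))
    }
  }
  out
}

#' Reconstruction residuals (anomaly maps)
#'
#' @param object A `hicspot_fit`.
#' @param newdata Windows as in [hicspot_fit()].
#' @param ... Passed to [predict.hicspot_fit()].
#' @return List of `T x H x W x C` absolute-difference arrays.
#' @export
residuals.hicspot_fit <- function(object, newdata, ...) {
  wl <- as_window_list(newdata)
  rec <- predict(object, wl, ...)
  Map(function(x, xh) anomaly_map(x, xh), wl, rec)
}

#' Plot training history
#'
#' @param x A `hicspot_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hicspot_fit <- function(x, ...) {
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "reconstruction loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted model
#'
#' The checkpoint is a single weights container with a JSON sidecar holding
#' the architecture configuration.
#'
#' @param object A `hicspot_fit`.
#' @param path Checkpoint file path (the sidecar gets extension `.json`).
#' @export
save_hicspot <- function(object, path) {
  stopifnot(inherits(object, "hicspot_fit"))
  saveRDS(object, path)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  cfg <- object$model$config
  jsonlite::write_json(unclass(cfg), side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_hicspot
#' @export
load_hicspot <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "hicspot_fit"))
  obj
}
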
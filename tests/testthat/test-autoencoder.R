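test_that("encoder/decoder conv arithmetic gives the documented sizes", {
  cfg <- model_config()
  expect_identical(cfg$sizes, c(50L, 25L, 13L, 13L))
  expect_identical(cfg$dec_out_pads, c(0L, 0L, 1L))
  # per-layer formula oracle floor((n + 2p - k)/s) + 1
  n <- 50L
  for (l in 1:3)
    n <- (n + 2L * cfg$enc_pads[l] - cfg$enc_kernels[l]) %/%
      cfg$enc_strides[l] + 1L
  expect_identical(n, 13L)
  expect_error(model_config(input_size = 4, enc_pads = c(0L, 0L, 0L)),
               "too small")
})

test_that("spatial stages preserve shapes and ranges through the round trip", {
  for (hw in c(50L, 64L)) {
    cfg <- model_config(input_size = hw, enc_channels = c(4L, 6L, 6L),
                        lstm_hidden = c(6L, 6L, 4L, 6L, 6L),
                        dropout = 0, precision = "double")
    m <- hicspot_model(cfg, seed = 1)
    x <- array(runif(3 * hw * hw), c(3, hw, hw, 1))
    e <- spatial_encode(x, m)
    expect_identical(dim(e), c(3L, cfg$latent_size, cfg$latent_size, 6L))
    h <- temporal_encode_decode(e, m)
    expect_identical(dim(h), c(3L, cfg$latent_size, cfg$latent_size, 6L))
    y <- spatial_decode(h, m)
    expect_identical(dim(y), dim(x))
    expect_true(all(y > 0 & y < 1))
  }
})

test_that("zero weights force zero encoder output and eval mode is deterministic", {
  cfg <- tiny_config()
  m <- hicspot_model(cfg, seed = 2)
  x <- array(runif(2 * 16 * 16), c(2, 16, 16, 1))
  mz <- m
  for (l in 1:3) {
    mz$params$enc[[l]]$w[] <- 0
    mz$params$enc[[l]]$b[] <- 0
  }
  expect_true(all(spatial_encode(x, mz) == 0))
  m2 <- hicspot_model(model_config(dropout = 0.3, input_size = 16,
                                   enc_channels = c(2L, 3L, 3L),
                                   lstm_hidden = c(3L, 3L, 2L, 3L, 3L),
                                   precision = "double"), seed = 2)
  e1 <- spatial_encode(x, m2, mode = "eval")
  e2 <- spatial_encode(x, m2, mode = "eval")
  expect_identical(e1, e2)
})

test_that("ConvLSTM gate algebra matches its closed forms", {
  # zero weights: sigmoid(0) = 0.5, tanh(0) = 0 at every location
  w0 <- list(wx = array(0, c(3, 3, 2, 8)), wh = array(0, c(3, 3, 2, 8)),
             b = rep(0, 8))
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  c0 <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  st <- convlstm_cell(x, list(h = 0 * c0, c = c0), w0)
  expect_equal(as.numeric(st$i), rep(0.5, 50), tolerance = 1e-12)
  expect_equal(st$c, 0.5 * c0, tolerance = 1e-12)
  expect_equal(st$h, 0.5 * tanh(0.5 * c0), tolerance = 1e-12)
  # forced gates: f = 1, i = 0 gives exact memory passthrough
  wf <- w0
  wf$b <- c(-50, -50, 50, 50, 0, 0, -50, -50)  # gate order i, f, g, o
  stf <- convlstm_cell(x, list(h = 0 * c0, c = c0), wf)
  expect_equal(stf$c, c0, tolerance = 1e-10)
  # scalar case, all weights one: independent gate-arithmetic oracle
  w1 <- list(wx = array(1, c(3, 3, 1, 4)), wh = array(1, c(3, 3, 1, 4)),
             b = rep(0, 4))
  st1 <- convlstm_cell(array(1, c(1, 1, 1)),
                       list(h = array(0, c(1, 1, 1, 1)),
                            c = array(0, c(1, 1, 1, 1))), w1)
  sig1 <- 1 / (1 + exp(-1))
  c_exp <- sig1 * tanh(1)
  expect_equal(as.numeric(st1$i), sig1, tolerance = 1e-6)
  expect_equal(as.numeric(st1$g), tanh(1), tolerance = 1e-6)
  expect_equal(as.numeric(st1$c), c_exp, tolerance = 1e-6)
  expect_equal(as.numeric(st1$h), sig1 * tanh(c_exp), tolerance = 1e-6)
  expect_equal(round(c(sig1, tanh(1), c_exp), 4), c(0.7311, 0.7616, 0.5568))
  expect_error(convlstm_cell(x, list(h = 0 * c0, c = array(0, c(4, 4, 2, 1))),
                             w0), "shapes differ")
})

test_that("the temporal stack recurses from zero states with the configured channels", {
  cfg <- tiny_config()
  m <- hicspot_model(cfg, seed = 3)
  f1 <- array(rnorm(13 * 5 * 5 * 3), c(1, 5, 5, 3))
  dim(f1) <- c(1L, 5L, 5L, 3L)
  # T = 1 equals one cell application per layer from the zero state
  out1 <- temporal_encode_decode(f1, m)
  x <- aperm(f1, c(2, 3, 4, 1))
  state <- NULL
  for (l in seq_along(m$params$lstm))
    x <- convlstm_cell(x, NULL, m$params$lstm[[l]])$h
  expect_equal(aperm(out1, c(2, 3, 4, 1)), x, tolerance = 1e-12)
  # per-layer channel counts follow the hidden-dimension configuration
  cfg2 <- model_config(enc_channels = c(4L, 6L, 6L),
                       lstm_hidden = c(6L, 6L, 4L, 6L, 6L), dropout = 0,
                       precision = "double")
  m2 <- hicspot_model(cfg2, seed = 4)
  xs <- lapply(1:2, function(t) array(rnorm(13 * 13 * 6), c(13, 13, 6, 1)))
  seqs <- xs
  for (l in seq_along(m2$params$lstm)) {
    fw <- ns$convlstm_layer_forward(seqs, m2$params$lstm[[l]],
                                    single = FALSE)
    expect_identical(dim(fw$hs[[1]])[3], cfg2$lstm_hidden[l])
    seqs <- fw$hs
  }
})

test_that("reconstruction loss is the brute-force mean of squared differences", {
  x <- array(runif(2 * 4 * 4 * 1), c(2, 4, 4, 1))
  expect_identical(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x, x + 0.3), 0.09, tolerance = 1e-12)
  y <- array(runif(2 * 4 * 4 * 1), c(2, 4, 4, 1))
  brute <- 0
  for (i in seq_along(x)) brute <- brute + (x[i] - y[i])^2
  expect_equal(reconstruction_loss(x, y), brute / length(x),
               tolerance = 1e-12)
  expect_identical(reconstruction_loss(x, y), reconstruction_loss(y, x))
  expect_error(reconstruction_loss(x, array(0, c(2, 4, 4, 2))), "mismatch")
})

test_that("reconstruct returns input-shaped output in (0,1) and rejects unnormalized data", {
  cfg <- tiny_config()
  m <- hicspot_model(cfg, seed = 5)
  x <- array(runif(3 * 16 * 16), c(3, 16, 16, 1))
  r1 <- reconstruct(x, m)
  r2 <- reconstruct(x, m)
  expect_identical(dim(r1$reconstructed), dim(x))
  expect_true(all(r1$reconstructed > 0 & r1$reconstructed < 1))
  expect_identical(r1$reconstructed, r2$reconstructed)
  expect_equal(r1$loss, reconstruction_loss(x, r1$reconstructed))
  expect_error(reconstruct(x * 3, m), "normalized")
})

test_that("analytic gradients match finite differences through the full network", {
  cfg <- tiny_config()
  m <- hicspot_model(cfg, seed = 6)
  t_len <- 2L; n <- 2L
  set.seed(6)
  x <- array(runif(16 * 16 * n * t_len), c(16, 16, 1, n * t_len))
  fw <- ns$model_forward(m, x, n, t_len, training = TRUE)
  g <- ns$model_backward(fw$model, fw$cache, 2 * (fw$xhat - x) / length(x))
  lossfun <- function(model) {
    f <- ns$model_forward(model, x, n, t_len, training = TRUE)
    mean((x - f$xhat)^2)
  }
  eps <- 1e-5
  spots <- list(
    list(function(m) m$params$enc[[1]]$w,
         function(m, a) { m$params$enc[[1]]$w <- a; m }, g$enc[[1]]$w),
    list(function(m) m$params$lstm[[2]]$wx,
         function(m, a) { m$params$lstm[[2]]$wx <- a; m }, g$lstm[[2]]$wx),
    list(function(m) m$params$lstm[[4]]$wh,
         function(m, a) { m$params$lstm[[4]]$wh <- a; m }, g$lstm[[4]]$wh),
    list(function(m) m$params$dec[[2]]$w,
         function(m, a) { m$params$dec[[2]]$w <- a; m }, g$dec[[2]]$w),
    list(function(m) m$params$enc[[2]]$bn$gamma,
         function(m, a) { m$params$enc[[2]]$bn$gamma <- a; m },
         g$enc[[2]]$bn$gamma))
  set.seed(99)
  for (s in spots) {
    arr <- s[[1]](m)
    for (i in sample(length(arr), 2)) {
      a1 <- arr; a1[i] <- a1[i] + eps
      a2 <- arr; a2[i] <- a2[i] - eps
      num <- (lossfun(s[[2]](m, a1)) - lossfun(s[[2]](m, a2))) / (2 * eps)
      expect_equal(s[[3]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("training overfits one batch and respects the early-stopping contract", {
  cfg <- tiny_config()
  set.seed(1)
  batch <- lapply(1:4, function(i) {
    base <- outer(seq(0, 1, length.out = 16), seq(0, 1, length.out = 16))
    array(rep(pmin(1, base + 0.1 * i / 4), each = 2), c(2, 16, 16, 1))
  })
  ctl <- train_control(learning_rate = 6e-3, weight_decay = 0,
                       batch_size = 4, max_epochs = 200, patience = 200,
                       max_grad_norm = 5)
  fit <- hicspot_fit(batch, batch, config = cfg, control = ctl, seed = 1)
  h <- fit$history
  expect_lt(min(h$train_loss), 0.1 * h$train_loss[1])
  expect_lte(nrow(h), 200)
  # best-so-far training loss is non-increasing
  expect_true(all(diff(cummin(h$train_loss)) <= 0))
  # patience 0: stops at the first non-improving epoch (lr 0 cannot improve)
  ctl0 <- train_control(learning_rate = 1e-12, batch_size = 4,
                        max_epochs = 50, patience = 0)
  fit0 <- hicspot_fit(batch, batch, config = cfg, control = ctl0, seed = 1)
  expect_lte(nrow(fit0$history), 3)
  expect_error(hicspot_fit(list(), batch, config = cfg), "empty")
})

test_that("fitted-model methods expose predictions, residuals and coefficients", {
  cfg <- tiny_config()
  set.seed(2)
  wl <- lapply(1:6, function(i) array(runif(2 * 16 * 16), c(2, 16, 16, 1)))
  ctl <- train_control(learning_rate = 1e-3, batch_size = 3, max_epochs = 2,
                       patience = 2)
  fit <- hicspot_fit(wl[1:4], wl[5:6], config = cfg, control = ctl, seed = 3)
  expect_s3_class(fit, "hicspot_fit")
  pred <- predict(fit, wl[5:6])
  expect_length(pred, 2)
  expect_identical(dim(pred[[1]]), c(2L, 16L, 16L, 1L))
  # batched prediction equals the one-sample forward pass
  single <- reconstruct(wl[[5]], fit$model)
  expect_equal(pred[[1]], single$reconstructed, tolerance = 1e-6)
  res <- residuals(fit, wl[5:6])
  expect_equal(res[[1]], abs(wl[[5]] - pred[[1]]), tolerance = 1e-12)
  expect_type(coef(fit), "list")
  expect_output(print(fit), "autoencoder")
  path <- withr::local_tempfile(fileext = ".rds")
  save_hicspot(fit, path)
  expect_true(file.exists(sub("rds$", "json", path)))
  back <- load_hicspot(path)
  expect_equal(predict(back, wl[5])[[1]], pred[[1]], tolerance = 1e-12)
})
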
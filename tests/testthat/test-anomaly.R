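test_that("anomaly maps and frame scores equal their brute-force definitions", {
  set.seed(1)
  x <- array(runif(3 * 6 * 6 * 1), c(3, 6, 6, 1))
  expect_identical(anomaly_map(x, x), array(0, dim(x)))
  expect_equal(anomaly_map(x, x + 0.2), array(0.2, dim(x)),
               tolerance = 1e-12)
  y <- array(runif(length(x)), dim(x))
  m <- anomaly_map(x, y)
  for (i in sample(length(x), 20)) expect_identical(m[i], abs(x[i] - y[i]))
  expect_identical(frame_anomaly_scores(x, x), rep(0, 3))
  y2 <- x
  y2[2, , , ] <- y2[2, , , ] + 0.3
  expect_equal(frame_anomaly_scores(x, y2), c(0, 0.09, 0),
               tolerance = 1e-12)
  fs <- frame_anomaly_scores(x, y)
  for (t in 1:3)
    expect_equal(fs[t], mean((x[t, , , ] - y[t, , , ])^2), tolerance = 1e-12)
  # frame-score mean is the reconstruction loss (module consistency)
  expect_equal(mean(fs), reconstruction_loss(x, y), tolerance = 1e-12)
  expect_error(frame_anomaly_scores(x, array(0, c(3, 6, 6, 2))), "mismatch")
})

test_that("frame flagging thresholds at mean + k*sd of the reference scores", {
  expect_false(any(flag_frames(rep(0.2, 5))$flagged))
  sc <- c(0, 0, 0, 0, 1, 0)
  fl <- flag_frames(sc, k = 1)
  expect_identical(which(fl$flagged), 5L)
  expect_equal(fl$threshold, mean(sc) + sd(sc), tolerance = 1e-12)
  expect_false(any(flag_frames(sc, k = 1e9)$flagged))
  # baseline reference shifts the threshold to the normal-dynamics scale
  base <- c(0.01, 0.012, 0.011, 0.013)
  fl2 <- flag_frames(c(0.011, 0.2), k = 1, baseline = base)
  expect_identical(which(fl2$flagged), 2L)
  expect_error(flag_frames(0.5), "two frames")
})

test_that("the identity metric vector is exact for any input", {
  set.seed(2)
  x <- array(runif(2 * 20 * 20 * 1), c(2, 20, 20, 1))
  p <- metrics_panel(x, x)
  avg <- p[p$frame == "average", ]
  expect_equal(avg$mse, 0)
  expect_equal(avg$l1, 0)
  expect_equal(avg$ssi, 1, tolerance = 1e-12)
  expect_equal(avg$pcc, 1, tolerance = 1e-12)
  expect_equal(avg$scc, 1, tolerance = 1e-12)
  expect_equal(avg$psnr, 100)
  expect_equal(avg$nrmse, 0)
  expect_equal(avg$kl, 0, tolerance = 1e-12)
  expect_equal(avg$js, 0, tolerance = 1e-12)
  expect_equal(avg$cosine, 1, tolerance = 1e-12)
})

test_that("metrics agree with naive reimplementations on random frames", {
  set.seed(3)
  x <- array(runif(2 * 8 * 8 * 1), c(2, 8, 8, 1))
  y <- array(runif(length(x)), dim(x))
  p <- metrics_panel(x, y)
  for (t in 1:2) {
    oracle <- naive_panel_row(x[t, , , ], y[t, , , ])
    row <- p[t, ]
    for (nm in names(oracle))
      expect_equal(row[[nm]], oracle[[nm]], tolerance = 1e-10,
                   label = paste("frame", t, nm))
    expect_equal(row$ssi, naive_ssim(x[t, , , 1], y[t, , , 1], size = 7),
                 tolerance = 1e-10)
  }
  # anticorrelation and divergence identities
  p2 <- metrics_panel(x, 1 - x)
  expect_equal(p2$pcc[1:2], c(-1, -1), tolerance = 1e-12)
  expect_true(all(p$kl[1:2] >= p$js[1:2]))
  expect_true(all(p$js[1:2] >= 0 & p$js[1:2] <= log(2)))
  pxy <- metrics_panel(x, y)
  pyx <- metrics_panel(y, x)
  expect_equal(pxy$js[1:2], pyx$js[1:2], tolerance = 1e-12)
  # permutation equivariance across frames
  perm <- c(2L, 1L)
  pp <- metrics_panel(x[perm, , , , drop = FALSE], y[perm, , , , drop = FALSE])
  expect_equal(as.numeric(pp[1, -1]), as.numeric(p[2, -1]),
               tolerance = 1e-12)
  # constant frames yield NA correlations excluded from averages
  xc <- x
  xc[1, , , ] <- 0.5
  pc <- metrics_panel(xc, y)
  expect_true(is.na(pc$pcc[1]))
  expect_equal(pc[pc$frame == "average", "pcc"], pc$pcc[2],
               tolerance = 1e-12)
})

test_that("detection metrics reproduce brute-force confusion counts", {
  set.seed(4)
  truth <- array(FALSE, c(2, 10, 10))
  truth[1, 3:5, 3:5] <- TRUE
  perfect <- array(0, c(2, 10, 10, 1))
  perfect[1, 3:5, 3:5, 1] <- 1
  rep1 <- anomaly_report(array(0, c(2, 10, 10, 1)), -perfect)
  dm <- detection_metrics(rep1, truth)
  expect_equal(dm$pixel$precision, 1)
  expect_equal(dm$pixel$recall, 1)
  zero <- anomaly_report(array(0, c(2, 10, 10, 1)),
                         array(0, c(2, 10, 10, 1)))
  expect_equal(detection_metrics(zero, truth)$pixel$recall, 0)
  x <- array(runif(2 * 10 * 10), c(2, 10, 10, 1))
  y <- array(runif(length(x)), dim(x))
  repr <- anomaly_report(x, y)
  dmr <- detection_metrics(repr, truth)
  mv <- abs(x - y)
  thr <- mean(mv) + sd(as.numeric(mv))
  pred <- array(mv > thr, c(2, 10, 10))
  expect_identical(dmr$counts[["tp"]], sum(pred & truth))
  expect_identical(dmr$counts[["fp"]], sum(pred & !truth))
  expect_identical(dmr$counts[["fn"]], sum(!pred & truth))
})

test_that("the time-swap harness rejects degenerate swaps and localizes input differences", {
  frames <- lapply(1:4, function(i) random_contact(60, seed = i, scale = 80))
  s <- hic_series(frames)
  cfg <- model_config(input_size = 30, enc_channels = c(2L, 3L, 3L),
                      lstm_hidden = c(3L, 3L, 2L, 3L, 3L), dropout = 0,
                      precision = "double")
  set.seed(5)
  wl <- normalize_windows(extract_windows(s, 30, 10), 0, 100)
  fit <- hicspot_fit(wl[1:3], wl[4], config = cfg,
                     control = train_control(learning_rate = 1e-3,
                                             batch_size = 3, max_epochs = 1,
                                             patience = 1), seed = 1)
  expect_error(timeswap_report(fit, s, 2, 2), "must differ")
  tr <- timeswap_report(fit, s, 2, 4, size = 30, diag_stride = 10,
                        clip_lo = 0, clip_hi = 100)
  mse_in <- tr$panel_input$mse[1:4]
  expect_equal(mse_in[c(1, 3)], c(0, 0), tolerance = 1e-12)
  expect_true(all(mse_in[c(2, 4)] > 0))
  expect_identical(tr$swapped, c(2, 4))
  expect_length(tr$scores, 4L)
})
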
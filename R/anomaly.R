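# Anomaly evaluation: pixel maps are absolute input-reconstruction
# differences; frame scores are the per-frame decomposition of the mean
# squared reconstruction loss; the metrics panel reproduces the standard
# ten-metric reconstruction-fidelity table.

#' Pixel-level anomaly map
#'
#' Element-wise absolute difference between a sequence and its
#' reconstruction.
#'
#' @param x,x_hat Arrays of identical shape.
#' @export
anomaly_map <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat)))
    stop("anomaly_map: shape mismatch")
  m <- abs(x - x_hat)
  dim(m) <- dim(x)
  m
}

#' Per-frame anomaly scores
#'
#' Frame `t`'s score is the mean squared difference over that frame's
#' `H * W * C` elements, so the mean score over frames equals
#' [reconstruction_loss()].
#'
#' @param x,x_hat `T x H x W x C` arrays.
#' @return Numeric vector of length `T`.
#' @export
frame_anomaly_scores <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat)))
    stop("frame_anomaly_scores: shape mismatch")
  d <- dim(x)
  sq <- (x - x_hat)^2
  dim(sq) <- c(d[1L], prod(d[-1L]))
  .rowMeans(sq, d[1L], prod(d[-1L]))
}

#' Flag anomalous frames by score elevation
#'
#' A frame is flagged when its score exceeds `mean + k * sd` of the
#' reference score vector — by default the scores themselves; supplying
#' `baseline` scores from a matched unperturbed series thresholds elevation
#' relative to normal dynamics instead.
#'
#' @param scores Per-frame scores (length at least 2).
#' @param k Threshold stringency in standard deviations.
#' @param baseline Optional reference score vector for the threshold.
#' @return List with logical `flagged` and the numeric `threshold`.
#' @export
flag_frames <- function(scores, k = 1, baseline = NULL) {
  if (length(scores) < 2L)
    stop("flag_frames: need at least two frames")
  ref <- if (is.null(baseline)) scores else baseline
  threshold <- mean(ref) + k * stats::sd(ref)
  list(flagged = scores > threshold, threshold = threshold)
}

# -- metrics -----------------------------------------------------------------

gaussian_kernel2d <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Structural similarity of two 2-D images, Gaussian-windowed (11x11,
# sigma 1.5), data range 1, valid borders. The window shrinks to the largest
# odd size fitting the image when the image is smaller than 11.
ssim2d <- function(x, y, data_range = 1) {
  size <- min(11L, nrow(x), ncol(x))
  if (size %% 2L == 0L) size <- size - 1L
  if (size < 3L) stop("ssim2d: image too small for a windowed comparison")
  k <- gaussian_kernel2d(size)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  filt <- function(img) {
    a <- array(img, c(nrow(img), ncol(img), 1L, 1L))
    w <- array(k, c(size, size, 1L, 1L))
    out <- conv2d(a, w, 0, 1L, 0L, single = FALSE)
    matrix(out, dim(out)[1L], dim(out)[2L])
  }
  mx <- filt(x); my <- filt(y)
  mxx <- filt(x * x); myy <- filt(y * y); mxy <- filt(x * y)
  vx <- mxx - mx^2; vy <- myy - my^2; cxy <- mxy - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

divergence_dist <- function(v, eps = 1e-10) {
  p <- as.numeric(v) + eps
  p / sum(p)
}

kl_div <- function(p, q) sum(p * log(p / q))

#' Ten-metric reconstruction-fidelity panel
#'
#' Per frame: mean squared error, mean absolute error (L1), structural
#' similarity (Gaussian-windowed, data range 1, channel-averaged), Pearson
#' and Spearman correlation over flattened entries, peak signal-to-noise
#' ratio `10 log10(1 / mse)` capped at 100 dB, range-normalized RMSE,
#' Kullback-Leibler and Jensen-Shannon divergences between the frames
#' normalized to probability distributions (natural log, `1e-10`
#' smoothing), and cosine similarity. A final `average` row holds the
#' across-frame means (undefined correlations on constant frames are `NA`
#' and excluded from averages).
#'
#' @param x,x_hat `T x H x W x C` arrays with values in `[0, 1]`.
#' @return Data frame with `T + 1` rows (class `metrics_panel`).
#' @export
metrics_panel <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat)))
    stop("metrics_panel: shape mismatch")
  d <- dim(x)
  t_len <- d[1L]
  one <- function(t) {
    a <- array(x[t, , , ], d[2:4])
    b <- array(x_hat[t, , , ], d[2:4])
    av <- as.numeric(a); bv <- as.numeric(b)
    mse <- mean((av - bv)^2)
    l1 <- mean(abs(av - bv))
    ssi <- mean(vapply(seq_len(d[4L]), function(ch)
      ssim2d(a[, , ch], b[, , ch]), numeric(1)))
    pcc <- if (stats::sd(av) == 0 || stats::sd(bv) == 0) NA_real_ else
      stats::cor(av, bv)
    scc <- if (stats::sd(av) == 0 || stats::sd(bv) == 0) NA_real_ else
      stats::cor(av, bv, method = "spearman")
    psnr <- if (mse == 0) 100 else min(100, 10 * log10(1 / mse))
    nrmse <- sqrt(mse)
    p <- divergence_dist(av); q <- divergence_dist(bv)
    kl <- kl_div(p, q)
    mmid <- (p + q) / 2
    js <- 0.5 * kl_div(p, mmid) + 0.5 * kl_div(q, mmid)
    na <- sqrt(sum(av^2)); nb <- sqrt(sum(bv^2))
    cosine <- if (na == 0 || nb == 0) NA_real_ else sum(av * bv) / (na * nb)
    c(mse = mse, l1 = l1, ssi = ssi, pcc = pcc, scc = scc, psnr = psnr,
      nrmse = nrmse, kl = kl, js = js, cosine = cosine)
  }
  rows <- t(vapply(seq_len(t_len), one, numeric(10)))
  avg <- colMeans(rows, na.rm = TRUE)
  out <- as.data.frame(rbind(rows, avg))
  out <- cbind(frame = c(as.character(seq_len(t_len)), "average"), out)
  rownames(out) <- NULL
  class(out) <- c("metrics_panel", "data.frame")
  out
}

#' @export
print.metrics_panel <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  df[-1L] <- lapply(df[-1L], function(col) signif(col, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Build an anomaly report from input and reconstruction
#'
#' @param x,x_hat `T x H x W x C` arrays.
#' @param k Flagging stringency for [flag_frames()].
#' @param baseline Optional reference frame scores.
#' @return Object of class `anomaly_report` with `pixel_maps`,
#'   `frame_scores`, `flagged_frames` and `threshold`.
#' @export
anomaly_report <- function(x, x_hat, k = 1, baseline = NULL) {
  scores <- frame_anomaly_scores(x, x_hat)
  fl <- flag_frames(scores, k, baseline)
  structure(list(pixel_maps = anomaly_map(x, x_hat), frame_scores = scores,
                 flagged_frames = fl$flagged, threshold = fl$threshold,
                 k = k),
            class = "anomaly_report")
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat("anomaly_report:", length(x$frame_scores), "frames\n")
  cat("  scores:", paste(signif(x$frame_scores, 4), collapse = ", "), "\n")
  cat(sprintf("  threshold %.4g -> flagged: %s\n", x$threshold,
              if (any(x$flagged_frames))
                paste(which(x$flagged_frames), collapse = ", ") else "none"))
  invisible(x)
}

#' Precision and recall against a ground-truth mask
#'
#' Pixel level: the absolute-difference map is thresholded at its own
#' `mean + k * sd` and compared with the mask. Frame level: flagged frames
#' are compared with frames containing any true mask entry.
#'
#' @param report An [anomaly_report()] built on full-frame arrays aligned
#'   with `truth`.
#' @param truth `T x N x N` logical ground-truth array.
#' @param k Pixel threshold stringency.
#' @return List with `pixel` and `frame` precision/recall, plus counts.
#' @export
detection_metrics <- function(report, truth, k = 1) {
  maps <- report$pixel_maps
  t_len <- dim(truth)[1L]
  if (dim(maps)[1L] != t_len ||
      prod(dim(maps)[-1L]) != prod(dim(truth)[-1L]))
    stop("detection_metrics: report and truth shapes are not aligned")
  mv <- as.numeric(maps)
  thr <- mean(mv) + k * stats::sd(mv)
  pred <- array(maps > thr, dim(truth))
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  pixel <- list(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
                recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
  truth_frames <- apply(truth, 1L, any)
  flagged <- report$flagged_frames
  tpf <- sum(flagged & truth_frames)
  fpf <- sum(flagged & !truth_frames)
  fnf <- sum(!flagged & truth_frames)
  frame <- list(precision = if (tpf + fpf == 0) NA_real_ else tpf / (tpf + fpf),
                recall = if (tpf + fnf == 0) NA_real_ else tpf / (tpf + fnf))
  list(pixel = pixel, frame = frame,
       counts = c(tp = tp, fp = fp, fn = fn, tpf = tpf, fpf = fpf, fnf = fnf),
       pixel_threshold = thr)
}

# -- series-level scoring ----------------------------------------------------

#' Score every frame of a series with a fitted model
#'
#' Extracts diagonal windows, normalizes with the clip bounds, reconstructs
#' with the model, and aggregates per-frame mean squared error across all
#' windows (all windows weigh equally).
#'
#' @param fit A [hicspot_fit()].
#' @param series A [hic_series()].
#' @param size,diag_stride Window geometry (see [extract_windows()]).
#' @param clip_lo,clip_hi Normalization bounds (see [clip_minmax()]).
#' @return List with `frame_scores`, per-window score matrix `window_scores`
#'   (windows x frames), and the windows/reconstructions.
#' @export
series_frame_scores <- function(fit, series, size = 50L, diag_stride = 3L,
                                clip_lo = 0, clip_hi = 100) {
  wins <- extract_windows(series, size = size, diag_stride = diag_stride)
  wins <- normalize_windows(wins, clip_lo, clip_hi)
  rec <- predict(fit, wins)
  ws <- t(vapply(seq_along(wins), function(i)
    frame_anomaly_scores(wins[[i]]$data, rec[[i]]),
    numeric(length(series$frames))))
  list(frame_scores = colMeans(ws), window_scores = ws,
       windows = wins, reconstructions = rec)
}

#' Time-swap experiment report
#'
#' Swaps frames `i` and `j` of a series, reconstructs the swapped series
#' with the model, and reports per-frame anomaly scores plus two metric
#' panels: original vs swapped input (the injected perturbation) and
#' swapped input vs reconstruction (the detected deviation).
#'
#' @param fit A [hicspot_fit()].
#' @param series A [hic_series()].
#' @param i,j Distinct 1-based frame indices to interchange.
#' @param k Flagging stringency.
#' @param ... Window/normalization parameters for [series_frame_scores()].
#' @return List with `report` (an [anomaly_report()] on per-frame score
#'   aggregates), `panel_input` and `panel_reconstruction` metric panels,
#'   `swapped` frame pair, and `scores`.
#' @export
timeswap_report <- function(fit, series, i, j, k = 1, ...) {
  if (i == j) stop("timeswap_report: i and j must differ")
  swapped <- time_swap(series, i, j)
  sc <- series_frame_scores(fit, swapped, ...)
  dots <- list(...)
  lo <- dots$clip_lo %||% 0
  hi <- dots$clip_hi %||% 100
  orig_stack <- frames_to_array(series, lo, hi)
  swap_stack <- frames_to_array(swapped, lo, hi)
  panel_input <- metrics_panel(orig_stack, swap_stack)
  rec_stack <- reassemble_series(sc, swap_stack)
  panel_rec <- metrics_panel(swap_stack, rec_stack)
  fl <- flag_frames(sc$frame_scores, k)
  report <- structure(list(pixel_maps = NULL,
                           frame_scores = sc$frame_scores,
                           flagged_frames = fl$flagged,
                           threshold = fl$threshold, k = k),
                      class = "anomaly_report")
  list(report = report, panel_input = panel_input,
       panel_reconstruction = panel_rec, swapped = c(i, j),
       scores = sc$frame_scores)
}

# Normalized full-frame stack (T, N, N, 1) of a series.
frames_to_array <- function(series, lo, hi) {
  nb <- n_bins(series)
  t_len <- length(series$frames)
  out <- array(0, c(t_len, nb, nb, 1L))
  for (t in seq_len(t_len))
    out[t, , , 1L] <- clip_minmax(series$frames[[t]]$values, lo, hi)
  out
}

# Stitch window reconstructions back into a (T, N, N, 1) stack (average of
# overlapping windows); pixels not covered by any window keep the input
# value so frame-level metrics are not polluted by coverage gaps.
reassemble_series <- function(sc, input_stack) {
  wins <- sc$windows
  rec <- sc$reconstructions
  t_len <- dim(input_stack)[1L]
  nb <- dim(input_stack)[2L]
  out <- input_stack
  for (t in seq_len(t_len)) {
    acc <- matrix(0, nb, nb)
    cov <- matrix(0, nb, nb)
    for (i in seq_along(wins)) {
      size <- dim(wins[[i]]$data)[2L]
      ri <- wins[[i]]$row_bin + seq_len(size)
      ci <- wins[[i]]$col_bin + seq_len(size)
      acc[ri, ci] <- acc[ri, ci] + rec[[i]][t, , , 1L]
      cov[ri, ci] <- cov[ri, ci] + 1
    }
    vals <- out[t, , , 1L]
    vals[cov > 0] <- acc[cov > 0] / cov[cov > 0]
    out[t, , , 1L] <- vals
  }
  out
}

#' Scenario detection experiment
#'
#' Applies a perturbation scenario to a clean series, scores both the clean
#' and perturbed series with the model, flags frames whose perturbed score
#' is elevated relative to the clean-series baseline scores, and evaluates
#' frame-level detection against the scenario's ground truth.
#'
#' @param fit A [hicspot_fit()].
#' @param series Clean baseline [hic_series()].
#' @param specs List of [perturbation_spec()] (may be empty for a null run).
#' @param k Flagging stringency.
#' @param params Simulator parameters for [apply_scenario()].
#' @param ... Window/normalization parameters for [series_frame_scores()].
#' @return List with `flagged`, `truth_frames`, `recall`, `false_flags`,
#'   `scores`, `baseline_scores`, and the scenario `mask`.
#' @export
scenario_report <- function(fit, series, specs, k = 1,
                            params = power_law_params(), ...) {
  sim <- apply_scenario(series, specs, params)
  clean <- series_frame_scores(fit, series, ...)$frame_scores
  pert <- series_frame_scores(fit, sim$series, ...)$frame_scores
  fl <- flag_frames(pert, k, baseline = clean)
  truth_frames <- apply(sim$mask, 1L, any)
  recall <- if (any(truth_frames))
    sum(fl$flagged & truth_frames) / sum(truth_frames) else NA_real_
  list(flagged = fl$flagged, truth_frames = truth_frames, recall = recall,
       false_flags = sum(fl$flagged & !truth_frames),
       scores = pert, baseline_scores = clean, threshold = fl$threshold,
       mask = sim$mask, series = sim$series)
}
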
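# Shared builders and independent oracles for the test suite.

ns <- asNamespace("hicspot")

# tiny double-precision architecture for analytic/gradient tests
tiny_config <- function(...) {
  model_config(input_size = 16L, enc_channels = c(2L, 3L, 3L),
               lstm_hidden = c(3L, 3L, 2L, 3L, 3L), dropout = 0,
               precision = "double", ...)
}

# symmetric non-negative random contact matrix
random_contact <- function(n, seed = 1, scale = 10) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  contact_matrix(m, "chrT", 4e4)
}

# quick two-frame series from matrices
series_of <- function(...) hic_series(list(...))

# naive windowed SSIM (plain loops) used as the independent oracle
naive_ssim <- function(x, y, size, sigma = 1.5, data_range = 1) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in 1:(H - size + 1)) for (j in 1:(W - size + 1)) {
    wx <- x[i:(i + size - 1), j:(j + size - 1)]
    wy <- y[i:(i + size - 1), j:(j + size - 1)]
    mx <- sum(k * wx); my <- sum(k * wy)
    vx <- sum(k * wx^2) - mx^2; vy <- sum(k * wy^2) - my^2
    cxy <- sum(k * wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

# per-frame metric oracle computed with straightforward loops
naive_panel_row <- function(a, b) {
  av <- as.numeric(a); bv <- as.numeric(b)
  mse <- mean((av - bv)^2)
  eps <- 1e-10
  p <- (av + eps) / sum(av + eps); q <- (bv + eps) / sum(bv + eps)
  m <- (p + q) / 2
  c(mse = mse,
    l1 = mean(abs(av - bv)),
    pcc = stats::cor(av, bv),
    scc = stats::cor(av, bv, method = "spearman"),
    psnr = if (mse == 0) 100 else min(100, 10 * log10(1 / mse)),
    nrmse = sqrt(mse),
    kl = sum(p * log(p / q)),
    js = 0.5 * sum(p * log(p / m)) + 0.5 * sum(q * log(q / m)),
    cosine = sum(av * bv) / sqrt(sum(av^2) * sum(bv^2)))
}
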
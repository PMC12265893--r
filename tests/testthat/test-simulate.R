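no_noise <- function(...) power_law_params(p_noise = 0, ...)

test_that("power-law mean matches direct evaluation and guards its domain", {
  expect_identical(power_law_mean(0, 400, -0.8, 1), 400)
  expect_identical(power_law_mean(17, 400, 0, 1), 400)
  # independent log-space computation
  expect_equal(power_law_mean(1, 400, -0.8, 1),
               exp(log(400) - 0.8 * log(2)), tolerance = 1e-12)
  d <- 0:30
  v <- power_law_mean(d, 400, -0.8, 1)
  expect_true(all(diff(v) < 0))
  expect_error(power_law_mean(-1, 400, -0.8, 1), "non-negative")
  expect_error(power_law_mean(1, 400, -0.8, 0.5), "offset")
})

test_that("noise component fires with probability p_noise at its power-law value", {
  set.seed(1)
  expect_identical(noise_component(0:9, power_law_params(p_noise = 0)),
                   rep(0, 10))
  set.seed(1)
  always <- noise_component(0, power_law_params(p_noise = 1))
  expect_identical(always, 50)
  set.seed(7)
  draws <- noise_component(rep(5, 1e5), power_law_params())
  expect_equal(mean(draws > 0), 0.5, tolerance = 0.01)
  expect_equal(unique(draws[draws > 0]), 50 * 6^(-0.7), tolerance = 1e-12)
})

test_that("de novo TAD on a zero matrix equals the power-law profile off-diagonal", {
  m <- contact_matrix(matrix(0, 6, 6), "chrT", 4e4)
  out <- tad_add(m, perturb_region(1, 4), no_noise())
  # oracle: direct per-pair evaluation, strict lower triangle mirrored
  expected <- matrix(0, 6, 6)
  for (x in 2:5) for (y in 2:5) if (x != y)
    expected[x, y] <- 400 * (abs(x - y) + 1)^(-0.8)
  expect_equal(out$values, expected, tolerance = 1e-12)
  expect_identical(out$values, t(out$values))
  # entries already above the maximum achievable value stay unchanged
  big <- contact_matrix(matrix(1e6, 6, 6), "chrT", 4e4)
  set.seed(2)
  expect_identical(tad_add(big, perturb_region(1, 4))$values, big$values)
})

test_that("TAD add never decreases and split never increases any entry", {
  m <- random_contact(40, seed = 5, scale = 300)
  set.seed(11)
  up <- tad_add(m, perturb_region(5, 25))
  expect_true(all(up$values >= m$values))
  set.seed(11)
  dn <- tad_split(m, perturb_region(5, 25))
  expect_true(all(dn$values <= m$values))
  expect_identical(up$values, t(up$values))
  expect_identical(dn$values, t(dn$values))
})

test_that("TAD split reaches the weak profile on a high-signal matrix", {
  m <- contact_matrix(matrix(1e4, 8, 8), "chrT", 4e4)
  out <- tad_split(m, perturb_region(0, 7), no_noise())
  expected <- matrix(1e4, 8, 8)
  for (x in 1:8) for (y in 1:8) if (x != y)
    expected[x, y] <- 200 * (abs(x - y) + 1)^(-0.8)
  expect_equal(out$values, expected, tolerance = 1e-12)
  zero <- contact_matrix(matrix(0, 8, 8), "chrT", 4e4)
  set.seed(3)
  expect_identical(tad_split(zero, perturb_region(1, 6))$values, zero$values)
})

test_that("TAD shift moves the block and weakens the vacated region", {
  zero <- contact_matrix(matrix(0, 60, 60), "chrT", 4e4)
  strong <- tad_add(zero, perturb_region(10, 20), no_noise())
  shifted <- tad_shift(strong, perturb_region(10, 20), 15, no_noise())
  # hand-rolled oracle: copy block, weaken source, superimpose at target
  v <- strong$values
  idx <- 11:21
  block <- v[idx, idx]
  weak <- block
  for (x in 1:11) for (y in 1:11) if (x != y)
    weak[x, y] <- min(block[x, y], 200 * (abs(x - y) + 1)^(-0.8))
  expected <- v
  expected[idx, idx] <- weak
  didx <- idx + 15
  expected[didx, didx] <- pmax(expected[didx, didx],
                               block * (row(block) != col(block)))
  expect_equal(shifted$values, expected, tolerance = 1e-12)
  # identity offset leaves the matrix unchanged
  expect_equal(tad_shift(strong, perturb_region(10, 20), 0,
                         no_noise())$values,
               strong$values, tolerance = 0)
  set.seed(4)
  expect_identical(tad_shift(zero, perturb_region(10, 20), 15)$values,
                   zero$values)
  expect_error(tad_shift(strong, perturb_region(10, 20), 45), "out of bounds")
})

test_that("strength change scales the profile in the intended direction only", {
  zero <- contact_matrix(matrix(0, 30, 30), "chrT", 4e4)
  base <- tad_add(zero, perturb_region(2, 27), no_noise())
  up <- tad_strength(base, perturb_region(2, 27), 1.5, no_noise())
  off <- base$values > 0
  expect_equal(up$values[off] / base$values[off], rep(1.5, sum(off)),
               tolerance = 1e-12)
  set.seed(5)
  expect_identical(tad_strength(zero, perturb_region(2, 27), 0.5)$values,
                   zero$values)
  m <- random_contact(30, seed = 6, scale = 500)
  set.seed(6)
  expect_true(all(tad_strength(m, perturb_region(2, 27), 1.5)$values >=
                    m$values))
  set.seed(6)
  expect_true(all(tad_strength(m, perturb_region(2, 27), 0.5)$values <=
                    m$values))
  expect_error(tad_strength(m, perturb_region(2, 27), 1), "no-op")
})

test_that("loop strength increase writes the capped reference signature", {
  m <- random_contact(40, seed = 7)
  rows <- c(25, 29); cols <- c(5, 9)
  target <- m$values[26:30, 6:10]
  same <- replicate(5, target, simplify = FALSE)
  expect_identical(loop_strength_increase(m, rows, cols, same)$values,
                   m$values)
  zero <- contact_matrix(matrix(0, 40, 40), "chrT", 4e4)
  tens <- replicate(5, matrix(10, 5, 5), simplify = FALSE)
  out <- loop_strength_increase(zero, rows, cols, tens, cap = 8)
  expect_true(all(out$values[26:30, 6:10] == 8))
  expect_identical(out$values, t(out$values))
  set.seed(8)
  refs <- replicate(6, matrix(runif(25, 0, 20), 5, 5), simplify = FALSE)
  out2 <- loop_strength_increase(m, rows, cols, refs, cap = 1e6)
  sig <- Reduce(`+`, refs[1:5]) / 5  # averaging oracle (top five)
  expect_equal(out2$values[26:30, 6:10], pmax(target, sig),
               tolerance = 1e-12)
  expect_error(loop_strength_increase(m, rows, cols, refs[1:4]),
               "five reference")
})

test_that("loop strength decrease equals the four-flank window mean", {
  const <- contact_matrix(matrix(3, 60, 60), "chrT", 4e4)
  expect_identical(loop_strength_decrease(const, c(30, 33), c(12, 15))$values,
                   const$values)
  m <- random_contact(60, seed = 9)
  rows <- c(30, 33); cols <- c(12, 15)
  out <- loop_strength_decrease(m, rows, cols)
  # brute-force oracle over the expanded window
  ri <- (30 - 2):(33 + 2) + 1L
  ci <- (12 - 2):(15 + 2) + 1L
  he <- length(ri); we <- length(ci)
  expected <- m$values
  for (a in seq_along(ri)) for (b in seq_along(ci))
    expected[ri[a], ci[b]] <- mean(c(m$values[ri[a] - he, ci[b]],
                                     m$values[ri[a] + he, ci[b]],
                                     m$values[ri[a], ci[b] - we],
                                     m$values[ri[a], ci[b] + we]))
  expected[ci, ri] <- t(expected[ri, ci])
  expect_equal(out$values, expected, tolerance = 1e-12)
  expect_error(loop_strength_decrease(m, c(1, 4), c(5, 8)), "out of bounds")
  # isolated bright pixel with empty flanks is absorbed to zero
  z <- matrix(0, 60, 60)
  z[31, 14] <- 9; z[14, 31] <- 9
  bright <- contact_matrix(z, "chrT", 4e4)
  gone <- loop_strength_decrease(bright, c(30, 31), c(13, 14))
  expect_identical(max(gone$values[28:35, 11:18]), 0)
})

test_that("baseline generator is deterministic, symmetric and drift-controlled", {
  a <- generate_baseline_series(n_bins = 80, t_len = 3, seed = 42)
  b <- generate_baseline_series(n_bins = 80, t_len = 3, seed = 42)
  expect_identical(a$series$frames[[2]]$values, b$series$frames[[2]]$values)
  for (f in a$series$frames) {
    expect_identical(f$values, t(f$values))
    expect_true(all(f$values >= 0))
  }
  # distance decay in expectation: average over long diagonals decreases
  v <- a$series$frames[[1]]$values
  band_mean <- vapply(c(2, 10, 30, 60), function(d)
    mean(v[row(v) - col(v) == d]), numeric(1))
  expect_true(all(diff(band_mean) < 0))
  # zero drift + shared frame seed -> identical frames
  c0 <- generate_baseline_series(n_bins = 60, t_len = 2, temporal_drift = 0,
                                 seed = 1, frame_seeds = c(7L, 7L))
  expect_identical(c0$series$frames[[1]]$values, c0$series$frames[[2]]$values)
  expect_error(generate_baseline_series(n_bins = 40), "50 bins")
  expect_error(
    generate_baseline_series(n_bins = 100, tads = list(
      perturb_region(10, 30), perturb_region(35, 60))),
    "tolerance")
})

test_that("scenarios are local, masked exactly, and conflict-checked", {
  base <- generate_baseline_series(n_bins = 120, t_len = 4,
                                   tads = list(perturb_region(20, 45),
                                               perturb_region(70, 95)),
                                   loops = list(), seed = 3)
  null <- apply_scenario(base$series, list())
  expect_identical(null$series$frames[[3]]$values,
                   base$series$frames[[3]]$values)
  expect_false(any(null$mask))
  spec <- perturbation_spec("tad_add", perturb_region(50, 60), frames = 2)
  set.seed(10)
  one <- apply_scenario(base$series, list(spec))
  expect_false(any(one$mask[c(1, 3, 4), , ]))
  changed <- which(one$mask[2, , ], arr.ind = TRUE)
  expect_true(all(changed >= 51 & changed <= 61))
  expect_identical(one$series$frames[[1]]$values,
                   base$series$frames[[1]]$values)
  # mask marks exactly the entries that differ (diff oracle)
  diffm <- one$series$frames[[2]]$values != base$series$frames[[2]]$values
  expect_identical(one$mask[2, , ], diffm)
  clash <- list(
    perturbation_spec("tad_add", perturb_region(50, 60), frames = 2),
    perturbation_spec("tad_split", perturb_region(65, 80), frames = 2))
  expect_error(apply_scenario(base$series, clash), "tolerance")
})

test_that("the four-perturbation scenario masks match brute-force diffs", {
  fx <- make_fixture("small", seed = 2)
  base <- generate_baseline_series(
    n_bins = 400, t_len = 6,
    tads = list(perturb_region(30, 69), perturb_region(120, 159),
                perturb_region(210, 249), perturb_region(300, 339)),
    loops = list(c(69, 30), c(339, 300)), seed = 2)
  for (t in 1:6) {
    diffm <- fx$series$frames[[t]]$values != base$series$frames[[t]]$values
    expect_identical(fx$mask[t, , ], diffm)
  }
  expect_identical(which(apply(fx$mask, 1, any)), c(2L, 4L, 5L, 6L))
})

test_that("time swap is an involution that permutes frame checksums", {
  frames <- lapply(1:6, function(i) random_contact(30, seed = i))
  s <- hic_series(frames)
  expect_identical(time_swap(s, 3, 3), s)
  expect_identical(time_swap(time_swap(s, 2, 6), 2, 6), s)
  sums <- vapply(frames, function(f) sum(f$values), numeric(1))
  swapped <- time_swap(s, 2, 6)
  got <- vapply(swapped$frames, function(f) sum(f$values), numeric(1))
  expect_identical(got, sums[c(1, 6, 3, 4, 5, 2)])
  expect_error(time_swap(s, 0, 3), "out of range")
  expect_error(time_swap(s, 1, 7), "out of range")
})

test_that("scenario files round trip through YAML", {
  specs <- list(
    perturbation_spec("tad_strength", perturb_region(10, 30), frames = c(2, 3),
                      params = list(factor = 0.5)),
    perturbation_spec("tad_shift", perturb_region(50, 70), frames = 4,
                      params = list(offset = 15)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(specs, path)
  back <- read_scenario(path)
  expect_identical(back[[1]]$kind, "tad_strength")
  expect_identical(back[[1]]$frames, c(2L, 3L))
  expect_equal(back[[2]]$params$offset, 15)
  expect_identical(back[[2]]$region$s, 50L)
})
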
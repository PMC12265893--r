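# Power-law structural-perturbation simulator. Contact decay follows
# k * (d + p)^c with distance d in bins, offset p >= 1 guarding d = 0, and
# negative exponent c. Perturbations act on the strict lower triangle
# (x > y) of the matrix and are mirrored to the upper triangle, so the main
# diagonal is never modified. All randomness flows through R's RNG: callers
# seed with set.seed(); draw order within a region is column-major over the
# strict lower triangle (all noise-gate uniforms first, then one sign
# uniform per firing entry).

#' Simulator parameter set
#'
#' Defaults are the standard experimental values: TAD baseline `k_t = 400`
#' with decay exponent `c_t = -0.8`, weak-region baseline `k_weak = 200`
#' (same exponent), noise baseline/exponent `(50, -0.7)`, distance offset
#' `p = 1`, and noise probability `p_noise = 0.5`.
#'
#' @param k_t TAD baseline constant (contact units).
#' @param c_t TAD decay exponent (dimensionless, negative).
#' @param k_weak Weak-region baseline used by split/vacate operations.
#' @param k_n,c_n Noise-component baseline and decay exponent.
#' @param p Distance offset prior in bins (at least 1).
#' @param p_noise Probability that the noise component fires for an entry.
#' @export
power_law_params <- function(k_t = 400, c_t = -0.8, k_weak = 200,
                             k_n = 50, c_n = -0.7, p = 1, p_noise = 0.5) {
  if (!(k_t > k_weak && k_weak > 0))
    stop("power_law_params: need k_t > k_weak > 0")
  if (p < 1) stop("power_law_params: offset p must be >= 1")
  if (p_noise < 0 || p_noise > 1)
    stop("power_law_params: p_noise must lie in [0, 1]")
  structure(list(k_t = k_t, c_t = c_t, k_weak = k_weak, k_n = k_n,
                 c_n = c_n, p = p, p_noise = p_noise),
            class = "power_law_params")
}

#' Power-law mean contact at a bin distance
#'
#' `k * (d + p)^c`; strictly decreasing in `d` when `c < 0`. The offset `p`
#' keeps the expression finite at distance zero.
#'
#' @param d Bin distance(s), non-negative.
#' @param k Baseline constant, positive.
#' @param c Decay exponent.
#' @param p Distance offset, at least 1.
#' @export
power_law_mean <- function(d, k, c, p = 1) {
  if (any(d < 0)) stop("power_law_mean: distance must be non-negative")
  if (k <= 0) stop("power_law_mean: baseline k must be positive")
  if (p < 1) stop("power_law_mean: offset p must be >= 1 (division guard)")
  k * (d + p)^c
}

#' Stochastic noise component of the perturbation model
#'
#' Returns `k_n * (d + p)^{c_n}` with probability `p_noise` and 0 otherwise;
#' one uniform draw is consumed per element of `d`.
#'
#' @param d Bin distance(s).
#' @param params A [power_law_params()].
#' @export
noise_component <- function(d, params = power_law_params()) {
  if (any(d < 0)) stop("noise_component: distance must be non-negative")
  u <- stats::runif(length(d))
  out <- ifelse(u < params$p_noise,
                params$k_n * (d + params$p)^params$c_n, 0)
  out
}

#' A perturbation region on the bin axis
#'
#' @param s,e 0-based inclusive start and end bins, `s <= e`.
#' @export
perturb_region <- function(s, e) {
  s <- as.integer(s); e <- as.integer(e)
  if (s < 0 || e < s) stop("perturb_region: need 0 <= s <= e")
  structure(list(s = s, e = e, w = e - s + 1L), class = "perturb_region")
}

check_region <- function(m, region, min_width = 2L) {
  nb <- nrow(m$values)
  if (!inherits(region, "perturb_region")) stop("not a perturb_region")
  if (region$e >= nb)
    stop(sprintf("region [%d, %d] out of bounds for %d bins",
                 region$s, region$e, nb))
  if (region$w < min_width)
    stop(sprintf("region [%d, %d] narrower than %d bins",
                 region$s, region$e, min_width))
}

# Strict lower-triangle machinery for a region's square block.
region_lower <- function(region) {
  w <- region$w
  lt <- lower.tri(matrix(0, w, w))
  dmat <- abs(outer(seq_len(w), seq_len(w), "-"))
  list(lt = lt, d = dmat[lt])
}

# Draw the signed noise vector for `d` distances. For `signed = TRUE` the
# sign is +/- with equal probability (one extra uniform per firing entry);
# otherwise the noise is always subtracted.
draw_signed_noise <- function(d, params, signed) {
  u <- stats::runif(length(d))
  fire <- u < params$p_noise
  noise <- numeric(length(d))
  noise[fire] <- params$k_n * (d[fire] + params$p)^params$c_n
  if (signed && any(fire)) {
    sgn <- ifelse(stats::runif(sum(fire)) < 0.5, 1, -1)
    noise[fire] <- noise[fire] * sgn
  } else if (!signed) {
    noise <- -noise
  }
  noise
}

# shared update: compute target mu over the region's strict lower triangle,
# apply the directional replace rule, mirror.
apply_region_update <- function(m, region, mu_fun, direction) {
  check_region(m, region)
  idx <- region$s + seq_len(region$w)   # 1-based rows/cols
  sub <- m$values[idx, idx, drop = FALSE]
  rl <- region_lower(region)
  mu <- mu_fun(rl$d)
  mu <- pmax(mu, 0)
  cur <- sub[rl$lt]
  new <- if (direction > 0) ifelse(mu > cur, mu, cur) else
    ifelse(mu < cur, mu, cur)
  sub[rl$lt] <- new
  sub[upper.tri(sub)] <- t(sub)[upper.tri(sub)]
  m$values[idx, idx] <- sub
  m
}

#' De novo TAD formation
#'
#' Raises contacts inside `[s, e]^2` toward the power-law TAD profile
#' `k_t (d + p)^{c_t}` plus a randomly signed noise component; an entry is
#' replaced only if the drawn value exceeds the current one, so the
#' operation never decreases any entry.
#'
#' @param m A [contact_matrix()].
#' @param region A [perturb_region()].
#' @param params A [power_law_params()].
#' @export
tad_add <- function(m, region, params = power_law_params()) {
  apply_region_update(m, region, function(d)
    power_law_mean(d, params$k_t, params$c_t, params$p) +
      draw_signed_noise(d, params, signed = TRUE),
    direction = +1)
}

#' TAD splitting (contact weakening)
#'
#' Lowers contacts inside `[s, e]^2` toward the weak-region profile
#' `k_weak (d + p)^{c_t}` with the noise component always subtracted;
#' an entry is replaced only if the drawn value is smaller (negative
#' intermediate values are floored at 0), so the operation never increases
#' any entry.
#'
#' @inheritParams tad_add
#' @export
tad_split <- function(m, region, params = power_law_params()) {
  apply_region_update(m, region, function(d)
    power_law_mean(d, params$k_weak, params$c_t, params$p) +
      draw_signed_noise(d, params, signed = FALSE),
    direction = -1)
}

#' TAD shift (repositioning)
#'
#' Copies the TAD block at `[s, e]^2`, weakens the vacated region with the
#' splitting procedure, then superimposes the copied block at
#' `[s+offset, e+offset]^2`, replacing destination entries only where the
#' copied value is larger.
#'
#' @inheritParams tad_add
#' @param offset Signed shift in bins.
#' @export
tad_shift <- function(m, region, offset, params = power_law_params()) {
  check_region(m, region)
  offset <- as.integer(offset)
  nb <- nrow(m$values)
  if (region$s + offset < 0L || region$e + offset >= nb)
    stop(sprintf("tad_shift: shifted region [%d, %d] out of bounds",
                 region$s + offset, region$e + offset))
  idx <- region$s + seq_len(region$w)
  rl <- region_lower(region)
  block <- m$values[idx, idx, drop = FALSE][rl$lt]
  m <- tad_split(m, region, params)
  dest <- perturb_region(region$s + offset, region$e + offset)
  didx <- dest$s + seq_len(dest$w)
  sub <- m$values[didx, didx, drop = FALSE]
  cur <- sub[rl$lt]
  sub[rl$lt] <- ifelse(block > cur, block, cur)
  sub[upper.tri(sub)] <- t(sub)[upper.tri(sub)]
  m$values[didx, didx] <- sub
  m
}

#' TAD strength change
#'
#' Rescales the in-TAD target profile by `factor` (`k_t -> factor * k_t`)
#' plus randomly signed noise. For `factor > 1` entries are updated only
#' upward, for `factor < 1` only downward, matching the intended direction
#' of change.
#'
#' @inheritParams tad_add
#' @param factor Positive multiplier, not equal to 1 (0.5 and 1.5 are the
#'   conventional weakening/strengthening choices).
#' @export
tad_strength <- function(m, region, factor, params = power_law_params()) {
  if (factor <= 0) stop("tad_strength: factor must be positive")
  if (factor == 1) stop("tad_strength: factor 1 is a no-op")
  apply_region_update(m, region, function(d)
    power_law_mean(d, factor * params$k_t, params$c_t, params$p) +
      draw_signed_noise(d, params, signed = TRUE),
    direction = if (factor > 1) +1 else -1)
}

loop_window_idx <- function(rows, cols) {
  list(ri = rows[1L] + seq_len(rows[2L] - rows[1L] + 1L),
       ci = cols[1L] + seq_len(cols[2L] - cols[1L] + 1L))
}

mirror_window <- function(m, ri, ci, block) {
  m$values[ri, ci] <- block
  m$values[ci, ri] <- t(block)
  m
}

#' Loop strength increase
#'
#' Builds a representative loop signature as the element-wise mean of the
#' top five reference loop windows and writes it into the target window
#' wherever it exceeds the current value, capped from above; updates are
#' mirrored for symmetry.
#'
#' @param m A [contact_matrix()].
#' @param rows,cols 0-based inclusive `(start, end)` bin pairs of the target
#'   loop window (rows > cols for the lower triangle).
#' @param references List of at least five matrices with the window's shape.
#' @param cap Upper bound imposed on modified values.
#' @export
loop_strength_increase <- function(m, rows, cols, references, cap = 100) {
  if (length(references) < 5L)
    stop("loop_strength_increase: at least five reference loops required")
  iw <- loop_window_idx(rows, cols)
  nb <- nrow(m$values)
  if (max(iw$ri, iw$ci) > nb || min(iw$ri, iw$ci) < 1L)
    stop("loop_strength_increase: window out of bounds")
  shape <- c(length(iw$ri), length(iw$ci))
  refs <- references[seq_len(5L)]
  for (r in refs)
    if (!identical(dim(as.matrix(r)), as.integer(shape)))
      stop("loop_strength_increase: reference window shape mismatch")
  signature <- Reduce(`+`, lapply(refs, as.matrix)) / 5
  cur <- m$values[iw$ri, iw$ci, drop = FALSE]
  new <- ifelse(signature > cur, pmin(signature, cap), cur)
  mirror_window(m, iw$ri, iw$ci, new)
}

#' Loop strength decrease
#'
#' Expands the loop window by two bins in each direction, then replaces each
#' entry by the mean of the four entries at the same offset in the windows
#' translated one window-height up and down and one window-width left and
#' right, absorbing the focal peak into the local background. Updated
#' entries are mirrored.
#'
#' @inheritParams loop_strength_increase
#' @export
loop_strength_decrease <- function(m, rows, cols) {
  rows <- c(rows[1L] - 2L, rows[2L] + 2L)
  cols <- c(cols[1L] - 2L, cols[2L] + 2L)
  iw <- loop_window_idx(rows, cols)
  he <- length(iw$ri)
  we <- length(iw$ci)
  nb <- nrow(m$values)
  lo_r <- min(iw$ri - he); hi_r <- max(iw$ri + he)
  lo_c <- min(iw$ci - we); hi_c <- max(iw$ci + we)
  if (lo_r < 1L || lo_c < 1L || hi_r > nb || hi_c > nb)
    stop("loop_strength_decrease: expanded or flanking windows out of bounds")
  v <- m$values
  new <- (v[iw$ri - he, iw$ci] + v[iw$ri + he, iw$ci] +
            v[iw$ri, iw$ci - we] + v[iw$ri, iw$ci + we]) / 4
  mirror_window(m, iw$ri, iw$ci, new)
}

# -- baseline generator ------------------------------------------------------

default_tad_layout <- function(nb) {
  widths <- c(25L, 35L, 30L, 20L, 40L)
  gap <- 12L
  tads <- list()
  s <- 5L
  i <- 0L
  while (TRUE) {
    w <- widths[(i %% length(widths)) + 1L]
    if (s + w - 1L >= nb - 5L) break
    tads[[length(tads) + 1L]] <- perturb_region(s, s + w - 1L)
    s <- s + w + gap
    i <- i + 1L
  }
  tads
}

default_loop_layout <- function(tads) {
  picks <- tads[seq(1L, length(tads), by = 2L)]
  lapply(picks, function(r) c(r$e, r$s))  # focal contact between boundaries
}

#' Generate a synthetic baseline spatiotemporal Hi-C series
#'
#' Each frame is a power-law background `k_bg (d + p)^{c_bg}` with nested
#' TAD blocks (the TAD power-law profile, replace-if-larger), focal
#' Gaussian loop peaks at TAD boundary contacts, and multiplicative
#' lognormal pixel noise. TAD and loop intensities grow smoothly by
#' `temporal_drift` per frame so consecutive frames evolve gradually;
#' per-frame noise is independent. Deterministic for a fixed seed.
#'
#' @param n_bins Matrix size (at least 50, one window).
#' @param t_len Number of frames (at least 2).
#' @param tads List of [perturb_region()] TAD spans (default: an automatic
#'   tiling with 12-bin gaps).
#' @param loops List of `c(row_bin, col_bin)` loop focus positions (default:
#'   corners of alternate TADs).
#' @param params A [power_law_params()].
#' @param temporal_drift Fractional intensity change of TADs/loops per frame.
#' @param noise_sigma Lognormal sigma of multiplicative pixel noise.
#' @param k_bg,c_bg Background power-law baseline and exponent.
#' @param seed Integer seed.
#' @param frame_seeds Optional per-frame noise seeds (length `t_len`);
#'   overrides the seed-derived default.
#' @param chrom,resolution Metadata for the generated frames.
#' @return List with `series` (a [hic_series()]), `tads`, and `loops`.
#' @export
generate_baseline_series <- function(n_bins = 400L, t_len = 6L, tads = NULL,
                                     loops = NULL,
                                     params = power_law_params(),
                                     temporal_drift = 0.1,
                                     noise_sigma = 0.1,
                                     k_bg = 100, c_bg = -1,
                                     seed = 1L, frame_seeds = NULL,
                                     chrom = "chrS", resolution = 4e4) {
  n_bins <- as.integer(n_bins)
  t_len <- as.integer(t_len)
  if (n_bins < 50L) stop("generate_baseline_series: need at least 50 bins")
  if (t_len < 2L) stop("generate_baseline_series: need at least 2 frames")
  if (is.null(tads)) tads <- default_tad_layout(n_bins)
  if (is.null(loops)) loops <- default_loop_layout(tads)
  check_tolerance(tads, n_bins)
  set.seed(seed)
  if (is.null(frame_seeds))
    frame_seeds <- sample.int(.Machine$integer.max - 1L, t_len)
  dmat <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  background <- power_law_mean(dmat, k_bg, c_bg, params$p)
  frames <- vector("list", t_len)
  for (t in seq_len(t_len)) {
    scale_t <- (1 + temporal_drift)^(t - 1L)
    mval <- background
    for (r in tads) {
      idx <- r$s + seq_len(r$w)
      prof <- power_law_mean(dmat[idx, idx], params$k_t * scale_t,
                             params$c_t, params$p)
      blk <- mval[idx, idx]
      mval[idx, idx] <- ifelse(prof > blk, prof, blk)
    }
    for (lp in loops) {
      r0 <- lp[1L]; c0 <- lp[2L]
      d0 <- abs(r0 - c0)
      amp <- 1.5 * power_law_mean(d0, params$k_t * scale_t, params$c_t,
                                  params$p)
      span <- -4:4
      ri <- r0 + 1L + span
      ci <- c0 + 1L + span
      keep_r <- ri >= 1L & ri <= n_bins
      keep_c <- ci >= 1L & ci <= n_bins
      bump <- amp * exp(-(outer(span[keep_r]^2, span[keep_c]^2, "+")) /
                          (2 * 1.5^2))
      blk <- mval[ri[keep_r], ci[keep_c]]
      mval[ri[keep_r], ci[keep_c]] <- pmax(blk, bump)
      mval[ci[keep_c], ri[keep_r]] <- t(mval[ri[keep_r], ci[keep_c]])
    }
    set.seed(frame_seeds[t])
    lt <- lower.tri(mval, diag = TRUE)
    noise <- exp(stats::rnorm(sum(lt), -noise_sigma^2 / 2, noise_sigma))
    mval[lt] <- mval[lt] * noise
    mval[upper.tri(mval)] <- t(mval)[upper.tri(mval)]
    frames[[t]] <- contact_matrix(mval, chrom, resolution)
  }
  list(series = hic_series(frames), tads = tads, loops = loops,
       seed = seed, frame_seeds = frame_seeds)
}

# Regions of concurrently applied perturbations must be separated by the
# 10-bin boundary tolerance.
BOUNDARY_TOLERANCE <- 10L

check_tolerance <- function(regions, nb) {
  if (length(regions) < 2L) return(invisible(TRUE))
  iv <- t(vapply(regions, function(r) c(r$s, r$e), integer(2)))
  ord <- order(iv[, 1L])
  iv <- iv[ord, , drop = FALSE]
  for (i in seq_len(nrow(iv) - 1L)) {
    if (iv[i + 1L, 1L] - iv[i, 2L] <= BOUNDARY_TOLERANCE)
      stop(sprintf(
        "regions [%d, %d] and [%d, %d] violate the %d-bin boundary tolerance",
        iv[i, 1L], iv[i, 2L], iv[i + 1L, 1L], iv[i + 1L, 2L],
        BOUNDARY_TOLERANCE))
  }
  invisible(TRUE)
}

#' Describe one injected structural perturbation
#'
#' @param kind One of `"tad_add"`, `"tad_split"`, `"tad_shift"`,
#'   `"tad_strength"`, `"loop_up"`, `"loop_down"`.
#' @param region A [perturb_region()] for TAD kinds; for loop kinds use
#'   `rows`/`cols` in `params`.
#' @param frames 1-based frame indices affected.
#' @param params Kind-specific parameters: `offset` (tad_shift), `factor`
#'   (tad_strength), `rows`/`cols`/`references`/`cap` (loop kinds).
#' @export
perturbation_spec <- function(kind, region = NULL, frames, params = list()) {
  kind <- match.arg(kind, c("tad_add", "tad_split", "tad_shift",
                            "tad_strength", "loop_up", "loop_down"))
  structure(list(kind = kind, region = region,
                 frames = as.integer(frames), params = params),
            class = "perturbation_spec")
}

spec_intervals <- function(sp) {
  switch(sp$kind,
    tad_shift = list(c(sp$region$s, sp$region$e),
                     c(sp$region$s + sp$params$offset,
                       sp$region$e + sp$params$offset)),
    loop_up = ,
    loop_down = list(range(c(sp$params$rows, sp$params$cols))),
    list(c(sp$region$s, sp$region$e)))
}

apply_one_spec <- function(frame, sp, plp) {
  switch(sp$kind,
    tad_add = tad_add(frame, sp$region, plp),
    tad_split = tad_split(frame, sp$region, plp),
    tad_shift = tad_shift(frame, sp$region, sp$params$offset, plp),
    tad_strength = tad_strength(frame, sp$region, sp$params$factor, plp),
    loop_up = loop_strength_increase(frame, sp$params$rows, sp$params$cols,
                                     sp$params$references,
                                     sp$params$cap %||% 100),
    loop_down = loop_strength_decrease(frame, sp$params$rows,
                                       sp$params$cols))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a perturbation scenario to a series
#'
#' Deep-copies the series, applies each perturbation to its frames, and
#' returns the perturbed series together with a ground-truth mask marking
#' exactly the entries whose values changed. Unperturbed frames are
#' bitwise-identical to the input.
#'
#' @param series A [hic_series()].
#' @param specs List of [perturbation_spec()].
#' @param params A [power_law_params()] shared by the TAD operations.
#' @return List with `series` (perturbed) and `mask` (`T x N x N` logical).
#' @export
apply_scenario <- function(series, specs, params = power_law_params()) {
  stopifnot(inherits(series, "hic_series"))
  t_len <- length(series$frames)
  nb <- n_bins(series)
  for (sp in specs)
    if (any(sp$frames < 1L | sp$frames > t_len))
      stop("apply_scenario: frame index out of range in spec ", sp$kind)
  for (t in seq_len(t_len)) {
    active <- Filter(function(sp) t %in% sp$frames, specs)
    if (length(active) > 1L) {
      ivs <- lapply(active, spec_intervals)
      for (a in seq_len(length(active) - 1L)) {
        for (b in (a + 1L):length(active)) {
          for (iva in ivs[[a]]) {
            for (ivb in ivs[[b]]) {
              gap <- max(ivb[1L] - iva[2L], iva[1L] - ivb[2L])
              if (gap <= BOUNDARY_TOLERANCE)
                stop(sprintf(
                  paste0("apply_scenario: conflicting specs in frame %d: ",
                         "regions [%d, %d] (%s) and [%d, %d] (%s) violate ",
                         "the %d-bin tolerance"),
                  t, iva[1L], iva[2L], active[[a]]$kind,
                  ivb[1L], ivb[2L], active[[b]]$kind, BOUNDARY_TOLERANCE))
            }
          }
        }
      }
    }
  }
  out <- series
  mask <- array(FALSE, c(t_len, nb, nb))
  for (sp in specs) {
    for (t in sp$frames) {
      before <- out$frames[[t]]$values
      out$frames[[t]] <- apply_one_spec(out$frames[[t]], sp, params)
      mask[t, , ] <- mask[t, , ] | (out$frames[[t]]$values != before)
    }
  }
  list(series = out, mask = mask)
}

#' Swap two frames of a series
#'
#' @param series A [hic_series()].
#' @param i,j 1-based frame indices.
#' @return A new series with frames `i` and `j` exchanged (labels follow
#'   the frames' new positions; the input is not mutated).
#' @export
time_swap <- function(series, i, j) {
  stopifnot(inherits(series, "hic_series"))
  t_len <- length(series$frames)
  if (i < 1L || i > t_len || j < 1L || j > t_len)
    stop(sprintf("time_swap: frame index out of range (T = %d)", t_len))
  out <- series
  out$frames[[i]] <- series$frames[[j]]
  out$frames[[j]] <- series$frames[[i]]
  out
}

#' Read / write scenario files
#'
#' Scenarios are YAML lists with keys `kind`, `region` (`[s, e]`), `frames`
#' and kind-specific `params`.
#'
#' @param path YAML file path.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x)
    perturbation_spec(x$kind,
                      if (!is.null(x$region))
                        perturb_region(x$region[[1L]], x$region[[2L]]),
                      unlist(x$frames), x$params %||% list()))
}

#' @rdname read_scenario
#' @param specs List of [perturbation_spec()].
#' @export
write_scenario <- function(specs, path) {
  yaml::write_yaml(lapply(specs, function(sp) {
    out <- list(kind = sp$kind, frames = sp$frames)
    if (!is.null(sp$region)) out$region <- c(sp$region$s, sp$region$e)
    if (length(sp$params) > 0) out$params <- sp$params
    out
  }), path)
  invisible(path)
}

#' Write a ground-truth mask as per-frame BED-like intervals
#'
#' Each line is `chrom  start_bp  end_bp  frame` for a maximal run of
#' anomalous rows (bins touched by any changed entry) in that frame.
#'
#' @param mask `T x N x N` logical array from [apply_scenario()].
#' @param path Output path.
#' @param chrom Chromosome label.
#' @param resolution Bin size in bp.
#' @export
write_mask_bed <- function(mask, path, chrom = "chrS", resolution = 4e4) {
  lines <- character()
  for (t in seq_len(dim(mask)[1L])) {
    rows <- which(apply(mask[t, , ], 1L, any))
    if (length(rows) == 0L) next
    runs <- split(rows, cumsum(c(1L, diff(rows) != 1L)))
    for (r in runs)
      lines <- c(lines, sprintf("%s\t%d\t%d\t%d", chrom,
                                (min(r) - 1L) * as.integer(resolution),
                                max(r) * as.integer(resolution), t))
  }
  writeLines(lines, path)
  invisible(path)
}
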
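# Contact-map containers and I/O. A contact matrix is a symmetric,
# non-negative N x N interaction-frequency matrix with chromosome, bin-size
# and bin-offset metadata; a series is an ordered, bin-aligned list of such
# matrices, one per time point. Coordinates are 0-based bin indices;
# genomic bp = (start_bin + i) * resolution.

SYMMETRY_TOL <- 1e-8

#' Construct a contact matrix
#'
#' @param values Square, symmetric, non-negative numeric matrix of balanced
#'   interaction frequencies. `NaN`/`NA` entries (unmappable bins after
#'   balancing) are replaced by 0.
#' @param chrom Chromosome label.
#' @param resolution Bin size in bp.
#' @param start_bin 0-based index of the first represented bin.
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, chrom, resolution, start_bin = 0L) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("contact_matrix: values must be square")
  values[is.na(values)] <- 0
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("contact_matrix: negative entry at bin (%d, %d)",
                 neg[1, 1] - 1L, neg[1, 2] - 1L))
  if (max(abs(values - t(values))) > SYMMETRY_TOL)
    stop("contact_matrix: values are not symmetric within tolerance")
  values <- (values + t(values)) / 2
  dimnames(values) <- NULL
  structure(list(values = values, chrom = as.character(chrom),
                 resolution = as.numeric(resolution),
                 start_bin = as.integer(start_bin)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins at %g bp (bins %d..%d), total signal %.4g\n",
              x$chrom, nrow(x$values), x$resolution, x$start_bin,
              x$start_bin + nrow(x$values) - 1L, sum(x$values)))
  invisible(x)
}

#' Construct a spatiotemporal Hi-C series
#'
#' @param frames List of [contact_matrix()] objects sharing chromosome,
#'   resolution, offset and size; at least two frames.
#' @param labels Optional per-frame time-point names.
#' @return Object of class `hic_series`.
#' @export
hic_series <- function(frames, labels = NULL) {
  stopifnot(length(frames) >= 2L)
  lapply(frames, function(f) stopifnot(inherits(f, "contact_matrix")))
  ref <- frames[[1L]]
  for (f in frames[-1L]) {
    if (!identical(f$chrom, ref$chrom) || f$resolution != ref$resolution ||
        f$start_bin != ref$start_bin ||
        nrow(f$values) != nrow(ref$values))
      stop("hic_series: frames are not aligned on the same bins")
  }
  if (is.null(labels)) labels <- paste0("T", seq_along(frames))
  stopifnot(length(labels) == length(frames))
  structure(list(frames = frames, labels = as.character(labels)),
            class = "hic_series")
}

#' @export
print.hic_series <- function(x, ...) {
  cat(sprintf("hic_series: %d frames (%s), %s, %d bins at %g bp\n",
              length(x$frames), paste(x$labels, collapse = ", "),
              x$frames[[1L]]$chrom, nrow(x$frames[[1L]]$values),
              x$frames[[1L]]$resolution))
  invisible(x)
}

n_bins <- function(x) nrow(x$frames[[1L]]$values)

#' Read a contact map
#'
#' Reads the dense tab-separated dialect: a one-line header
#' `#<chrom>\t<resolution>\t<start_bin>` followed by an N x N matrix. A file
#' storing only one triangle is mirrored to a full symmetric matrix.
#' Cooler (`.cool`, HDF5) input is not supported by this build; convert to
#' the dense dialect first (e.g. with `cooler dump`).
#'
#' @param path File path.
#' @param chrom Expected chromosome label (checked against the header).
#' @param resolution Expected bin size in bp (checked against the header).
#' @return A [contact_matrix()].
#' @export
load_contact_map <- function(path, chrom, resolution) {
  if (!file.exists(path)) stop("load_contact_map: no such file: ", path)
  if (grepl("\\.(cool|mcool|h5|hdf5)$", path, ignore.case = TRUE))
    stop("load_contact_map: HDF5/cooler input is not supported; ",
         "export the matrix to the dense tab-separated dialect first")
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("load_contact_map: missing '#chrom\\tresolution\\tstart_bin' header")
  hf <- strsplit(sub("^#", "", header), "\t")[[1L]]
  if (length(hf) < 3L)
    stop("load_contact_map: malformed header: ", header)
  if (!identical(hf[1L], as.character(chrom)))
    stop(sprintf("load_contact_map: chromosome '%s' not in file (file has '%s')",
                 chrom, hf[1L]))
  if (as.numeric(hf[2L]) != as.numeric(resolution))
    stop(sprintf("load_contact_map: resolution %g not in file (file has %s bp)",
                 as.numeric(resolution), hf[2L]))
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    stop("load_contact_map: stored matrix is not square")
  m[is.na(m)] <- 0
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("load_contact_map: negative entry at bin (%d, %d)",
                 neg[1, 1] - 1L, neg[1, 2] - 1L))
  lower0 <- all(m[lower.tri(m)] == 0)
  upper0 <- all(m[upper.tri(m)] == 0)
  if (max(abs(m - t(m))) > SYMMETRY_TOL) {
    if (lower0 || upper0) {
      m <- m + t(m)
      diag(m) <- diag(m) / 2
    } else {
      stop("load_contact_map: matrix is asymmetric and not a stored triangle")
    }
  }
  contact_matrix(m, hf[1L], as.numeric(hf[2L]), as.integer(hf[3L]))
}

#' Write a contact map in the dense dialect
#'
#' @param cm A [contact_matrix()].
#' @param path Output path.
#' @export
write_contact_map <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s\t%.15g\t%d", cm$chrom, cm$resolution, cm$start_bin),
             con)
  utils::write.table(format(cm$values, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Clip and min-max normalize
#'
#' Clips to `[lo, hi]` and rescales with the fixed clip bounds as min/max:
#' `(clip(x, lo, hi) - lo) / (hi - lo)`, so values are comparable across
#' windows and chromosomes. Typical presets: counts at 40 kb clip `0-100`,
#' balanced 10 kb maps clip `0-0.02`.
#'
#' @param x Numeric vector/array of raw contact values.
#' @param lo,hi Fixed clip bounds, `hi > lo`.
#' @return Same shape as `x`, values exactly in `[0, 1]`.
#' @export
clip_minmax <- function(x, lo = 0, hi = 100) {
  if (!(hi > lo)) stop("clip_minmax: hi must exceed lo")
  y <- (pmin(pmax(x, lo), hi) - lo) / (hi - lo)
  dim(y) <- dim(x)
  y
}

#' Dataset normalization presets
#'
#' @param name `"counts40kb"` (clip 0-100, stride 3) or `"balanced10kb"`
#'   (clip 0-0.02, stride 25 with rightward sweep).
#' @return List with `clip_lo`, `clip_hi`, `window`, `diag_stride`,
#'   `right_stride`, `max_span`.
#' @export
dataset_preset <- function(name = c("counts40kb", "balanced10kb")) {
  name <- match.arg(name)
  switch(name,
    counts40kb = list(clip_lo = 0, clip_hi = 100, window = 50L,
                      diag_stride = 3L, right_stride = NULL, max_span = 2e6),
    balanced10kb = list(clip_lo = 0, clip_hi = 0.02, window = 50L,
                        diag_stride = 25L, right_stride = 25L, max_span = 2e6))
}

new_window_sample <- function(data, row_bin, col_bin, chrom, resolution) {
  structure(list(data = data, row_bin = as.integer(row_bin),
                 col_bin = as.integer(col_bin), chrom = chrom,
                 resolution = resolution),
            class = "window_sample")
}

#' @export
print.window_sample <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("window_sample: %s @ bins (%d, %d), %d frames of %dx%dx%d, range [%.3g, %.3g]\n",
              x$chrom, x$row_bin, x$col_bin, d[1L], d[2L], d[3L], d[4L],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Extract submatrix windows along the diagonal
#'
#' Takes `size` x `size` windows whose top-left corner runs along the main
#' diagonal at bins `0, diag_stride, 2*diag_stride, ...`. When
#' `right_stride` is set, each diagonal anchor `i` additionally yields
#' off-diagonal windows at columns `i + k*right_stride` while the window
#' stays within `max_span` bp of the diagonal. Windows that would overrun
#' the matrix edge are dropped, never padded. Values are copied raw; apply
#' [clip_minmax()] (or [normalize_windows()]) afterwards.
#'
#' @param series A [hic_series()].
#' @param size Window side length in bins.
#' @param diag_stride Diagonal stride in bins.
#' @param right_stride Optional rightward stride in bins.
#' @param max_span Maximum genomic span from the diagonal in bp.
#' @return List of `window_sample` objects whose `data` is `T x H x W x 1`.
#' @export
extract_windows <- function(series, size = 50L, diag_stride = 3L,
                            right_stride = NULL, max_span = 2e6) {
  stopifnot(inherits(series, "hic_series"))
  nb <- n_bins(series)
  size <- as.integer(size)
  if (size > nb)
    stop(sprintf("extract_windows: window size %d exceeds matrix size %d",
                 size, nb))
  if (diag_stride < 1L || (!is.null(right_stride) && right_stride < 1L))
    stop("extract_windows: strides must be >= 1")
  res <- series$frames[[1L]]$resolution
  t_len <- length(series$frames)
  anchors <- seq(0L, nb - size, by = as.integer(diag_stride))
  offsets <- 0L
  if (!is.null(right_stride)) {
    k <- 1L
    while ((k * right_stride + size) * res <= max_span) {
      offsets <- c(offsets, k * as.integer(right_stride))
      k <- k + 1L
    }
  }
  out <- list()
  for (i in anchors) {
    for (off in offsets) {
      j <- i + off
      if (j + size > nb) next
      data <- array(0, c(t_len, size, size, 1L))
      for (t in seq_len(t_len))
        data[t, , , 1L] <-
          series$frames[[t]]$values[i + seq_len(size), j + seq_len(size)]
      out[[length(out) + 1L]] <-
        new_window_sample(data, i, j, series$frames[[1L]]$chrom, res)
    }
  }
  out
}

#' Normalize a list of raw windows in place
#'
#' @param windows List of `window_sample` from [extract_windows()].
#' @param lo,hi Clip bounds for [clip_minmax()].
#' @return The windows with `data` normalized to `[0, 1]`.
#' @export
normalize_windows <- function(windows, lo = 0, hi = 100) {
  lapply(windows, function(w) {
    w$data <- clip_minmax(w$data, lo, hi)
    w
  })
}

#' Chromosome-level train/validation/test split
#'
#' Deterministically partitions chromosome labels: validation and test sets
#' are taken from the split specification and all remaining labels train
#' (the conventional arrangement keeps one chromosome for validation and two
#' for testing).
#'
#' @param chroms Character vector of chromosome labels.
#' @param val_chroms,test_chroms Disjoint label sets drawn from `chroms`.
#' @return List with `train`, `val`, `test` character vectors partitioning
#'   `chroms`.
#' @export
split_by_chromosome <- function(chroms, val_chroms = "chr19",
                                test_chroms = c("chr2", "chr6")) {
  overlap <- intersect(val_chroms, test_chroms)
  if (length(overlap) > 0)
    stop("split_by_chromosome: labels in both val and test: ",
         paste(overlap, collapse = ", "))
  missing <- setdiff(c(val_chroms, test_chroms), chroms)
  if (length(missing) > 0)
    stop("split_by_chromosome: labels not present: ",
         paste(missing, collapse = ", "))
  list(train = setdiff(chroms, c(val_chroms, test_chroms)),
       val = intersect(chroms, val_chroms),
       test = intersect(chroms, test_chroms))
}

#' Reassemble diagonal windows onto a frame-sized accumulator
#'
#' Utility for checking copy semantics and for stitching per-window maps
#' back into chromosome coordinates; overlapping contributions are averaged.
#'
#' @param windows List of `window_sample`.
#' @param n_bins Matrix size of the target frame.
#' @param frame Frame index (1-based).
#' @return List with `values` (N x N) and `coverage` (N x N counts).
#' @export
reassemble_windows <- function(windows, n_bins, frame = 1L) {
  acc <- matrix(0, n_bins, n_bins)
  cov <- matrix(0, n_bins, n_bins)
  for (w in windows) {
    size <- dim(w$data)[2L]
    ri <- w$row_bin + seq_len(size)
    ci <- w$col_bin + seq_len(size)
    acc[ri, ci] <- acc[ri, ci] + w$data[frame, , , 1L]
    cov[ri, ci] <- cov[ri, ci] + 1
  }
  vals <- acc
  vals[cov > 0] <- vals[cov > 0] / cov[cov > 0]
  list(values = vals, coverage = cov)
}

#' Save / load window batches
#'
#' Windows are written as a flat tab-separated value table (one row per
#' window, flattened `T*H*W*C` values) with a JSON sidecar recording window
#' coordinates and dimensions.
#'
#' @param windows List of `window_sample`.
#' @param path Output path for the value table; the sidecar gets `.json`.
#' @export
save_windows <- function(windows, path) {
  stopifnot(length(windows) > 0)
  d <- dim(windows[[1L]]$data)
  vals <- t(vapply(windows, function(w) as.numeric(w$data),
                   numeric(prod(d))))
  utils::write.table(vals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- list(dim = d,
               row_bin = vapply(windows, `[[`, integer(1), "row_bin"),
               col_bin = vapply(windows, `[[`, integer(1), "col_bin"),
               chrom = windows[[1L]]$chrom,
               resolution = windows[[1L]]$resolution)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_windows
#' @export
load_windows <- function(path) {
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  lapply(seq_len(nrow(vals)), function(i) {
    new_window_sample(array(as.numeric(vals[i, ]), meta$dim),
                      meta$row_bin[i], meta$col_bin[i], meta$chrom,
                      meta$resolution)
  })
}
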
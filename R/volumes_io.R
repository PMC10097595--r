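#' Eye mask
#'
#' A 3D boolean mask delineating the eyeballs (and optic-nerve region) in
#' template voxel space.
#'
#' @param grid logical 3D array (numeric arrays are binarised at > 0).
#' @param voxel_size_mm numeric(3) voxel size.
#' @return an object of class `eye_mask`.
#' @export
eye_mask <- function(grid, voxel_size_mm = c(2, 2, 2)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("mask grid must be a 3D array")
  grid <- array(as.logical(grid > 0 | grid == TRUE), dim(grid))
  if (!any(grid)) stop("eye mask is empty (all FALSE)")
  ncomp <- count_components(grid)
  if (ncomp > 4L)
    warning("eye mask has ", ncomp,
            " connected components; expected at most 4 (two eyes +/- nerves)")
  structure(list(grid = grid, voxel_size_mm = voxel_size_mm),
            class = "eye_mask")
}

# 6-connected component count via flood fill; masks here are small.
count_components <- function(grid) {
  d <- dim(grid)
  lab <- array(0L, d)
  idx <- which(grid)
  comp <- 0L
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  coord <- arrayInd(idx, d)
  key <- function(m) (m[, 3] - 1) * d[1] * d[2] + (m[, 2] - 1) * d[1] + m[, 1]
  for (i in seq_along(idx)) {
    if (lab[idx[i]] != 0L) next
    comp <- comp + 1L
    queue <- idx[i]
    lab[idx[i]] <- comp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      cv <- arrayInd(v, d)
      for (n in 1:6) {
        cn <- cv + nbr[n, , drop = FALSE]
        if (any(cn < 1) || any(cn > d)) next
        vn <- key(cn)
        if (grid[vn] && lab[vn] == 0L) { lab[vn] <- comp; queue <- c(queue, vn) }
      }
    }
  }
  comp
}

#' Load an eye mask from a NIfTI file
#' @param path path to a 3D NIfTI file.
#' @return an [eye_mask()]; voxel size taken from the header.
#' @export
load_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  eye_mask(array(as.numeric(img), dim(img)[1:3]), voxel_size_mm = vs)
}

#' Mask bounding box
#'
#' Inclusive per-axis voxel ranges (0-based in the exported table form,
#' 1-based internally) containing all mask voxels, optionally expanded
#' symmetrically — within the grid — so each side length is a multiple of
#' `pad_multiple` (the convolutional decoder needs dims divisible by 8).
#'
#' @param mask an [eye_mask()].
#' @param pad_multiple integer; 1 means the tight box.
#' @param pad_to optional integer(3) of explicit box dimensions (>= the tight
#'   box, <= the grid); overrides `pad_multiple`. Useful to keep margins
#'   around compact masks.
#' @return list with `lower`, `upper` (1-based inclusive) and `dims`.
#' @export
bounding_box <- function(mask, pad_multiple = 1L, pad_to = NULL) {
  d <- dim(mask$grid)
  idx <- which(mask$grid, arr.ind = TRUE)
  lower <- apply(idx, 2, min)
  upper <- apply(idx, 2, max)
  if (!is.null(pad_to) || pad_multiple > 1L) {
    for (k in 1:3) {
      len <- upper[k] - lower[k] + 1L
      want <- if (!is.null(pad_to)) as.integer(pad_to[k]) else
        as.integer(ceiling(len / pad_multiple) * pad_multiple)
      if (want < len)
        stop(sprintf("axis %d: pad_to %d smaller than the tight box (%d)",
                     k, want, len))
      if (want > d[k])
        stop(sprintf("axis %d: cannot pad box of %d to multiple of %d within grid of %d",
                     k, len, pad_multiple, d[k]))
      extra <- want - len
      lo <- lower[k] - extra %/% 2
      hi <- upper[k] + (extra - extra %/% 2)
      if (lo < 1L) { hi <- hi + (1L - lo); lo <- 1L }
      if (hi > d[k]) { lo <- lo - (hi - d[k]); hi <- d[k] }
      lower[k] <- lo; upper[k] <- hi
    }
  }
  list(lower = as.integer(lower), upper = as.integer(upper),
       dims = as.integer(upper - lower + 1L))
}

#' Volume series: per-TR eye-mask crops for one participant/run
#'
#' Crops each volume to the mask bounding box and zeroes voxels inside the box
#' but outside the mask, so the decoder input depends only on mask content.
#'
#' @param volumes 4D array (x, y, z, t) on the mask grid.
#' @param mask an [eye_mask()].
#' @param tr_s repetition time in seconds.
#' @param participant_id,run_id identifiers.
#' @param pad_multiple,pad_to passed to [bounding_box()].
#' @return an object of class `volume_series` with fields `data` (cropped 4D
#'   array), `mask_crop` (logical 3D array), `bbox`, `tr_s`, ids.
#' @export
volume_series <- function(volumes, mask, tr_s = 1, participant_id = "p1",
                          run_id = "run1", pad_multiple = 1L, pad_to = NULL) {
  if (length(dim(volumes)) == 3L)
    volumes <- array(volumes, c(dim(volumes), 1L))
  if (!all(dim(volumes)[1:3] == dim(mask$grid)))
    stop(sprintf("volume grid %s does not match mask grid %s",
                 paste(dim(volumes)[1:3], collapse = "x"),
                 paste(dim(mask$grid), collapse = "x")))
  if (tr_s <= 0) stop("tr_s must be > 0")
  bb <- bounding_box(mask, pad_multiple, pad_to)
  sl <- lapply(1:3, function(k) bb$lower[k]:bb$upper[k])
  mask_crop <- mask$grid[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  data <- volumes[sl[[1]], sl[[2]], sl[[3]], , drop = FALSE]
  zero <- !mask_crop
  if (any(zero)) {
    for (t in seq_len(dim(data)[4])) {
      v <- data[, , , t]; v[zero] <- 0; data[, , , t] <- v
    }
  }
  structure(list(data = data, mask_crop = mask_crop, bbox = bb, tr_s = tr_s,
                 participant_id = participant_id, run_id = run_id),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("Volume series %s/%s: %s box, %d TRs (TR = %gs), %d mask voxels\n",
              x$participant_id, x$run_id,
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              x$tr_s, sum(x$mask_crop)))
  invisible(x)
}

#' Load a 4D NIfTI series and crop it to the eye mask
#' @param path_4d path to a 4D NIfTI file.
#' @param mask an [eye_mask()] on the same grid.
#' @param ... passed to [volume_series()].
#' @return a [volume_series()].
#' @export
load_series <- function(path_4d, mask, ...) {
  img <- RNifti::readNifti(path_4d)
  dm <- dim(img)
  if (length(dm) == 3L) dm <- c(dm, 1L)
  volume_series(array(as.numeric(img), dm), mask, ...)
}

#' Temporal normalization (median/MAD over time, per voxel)
#'
#' For every voxel, subtracts the across-run median and divides by the median
#' absolute deviation over time (plain MAD, no 1.4826 consistency factor).
#' Voxels with MAD 0 are set to 0: constant voxels carry no gaze information
#' and must not poison training.
#'
#' @param series a [volume_series()] with >= 2 samples.
#' @return list with `series` (normalized) and `stats` (per-voxel `median`
#'   and `mad` arrays).
#' @export
temporal_normalize <- function(series) {
  d <- dim(series$data)
  if (d[4] < 2L) stop("temporal normalization needs >= 2 samples")
  v <- matrix(series$data, prod(d[1:3]), d[4])
  med <- matrixStats_rowMedians(v)
  madv <- matrixStats_rowMedians(abs(v - med))
  out <- (v - med) / ifelse(madv > 0, madv, Inf)
  series$data <- array(out, d)
  list(series = series,
       stats = list(median = array(med, d[1:3]), mad = array(madv, d[1:3])))
}

# rowMedians without a matrixStats dependency
matrixStats_rowMedians <- function(m) apply(m, 1, stats::median)

#' Spatial normalization (z-score across mask voxels, per sample)
#'
#' For every sample, subtracts the mean across mask voxels and divides by the
#' population (n, not n-1) standard deviation across mask voxels. Voxels
#' outside the mask stay 0. Zero-sd samples are set to 0.
#'
#' @param series a [volume_series()].
#' @return the normalized [volume_series()].
#' @export
spatial_normalize <- function(series) {
  d <- dim(series$data)
  midx <- which(series$mask_crop)
  if (!length(midx)) stop("series has no mask voxels")
  v <- matrix(series$data, prod(d[1:3]), d[4])
  mv <- v[midx, , drop = FALSE]
  mu <- colMeans(mv)
  sdv <- sqrt(colMeans(sweep(mv, 2, mu)^2))
  sc <- ifelse(sdv > 0, sdv, Inf)
  v[midx, ] <- sweep(sweep(mv, 2, mu), 2, sc, "/")
  series$data <- array(v, d)
  series
}

#' Canonical two-stage normalization
#'
#' Temporal (median/MAD) then spatial (mask z-score) normalization, the order
#' the decoder input pipeline uses. The composition is invariant to any
#' per-voxel affine rescaling of the raw input with positive gain.
#'
#' @param series a [volume_series()].
#' @return the normalized [volume_series()].
#' @export
normalize_series <- function(series) {
  spatial_normalize(temporal_normalize(series)$series)
}

#' Clean a raw camera gaze trace
#'
#' Applies, in order and each optionally: blink/gap removal, pupil-size
#' outlier removal at `k` sd, polynomial detrending, 100-ms running-average
#' smoothing and median centering — the standard preparation of camera
#' eye-tracker exports before binning into TR labels.
#'
#' @param trace data.frame with columns `t` (seconds), `x`, `y` and optionally
#'   `pupil`; rows with NA x/y are treated as blinks/gaps.
#' @param rate_hz sampling rate (> 0).
#' @param remove_blinks drop rows with missing coordinates.
#' @param pupil_sd_k remove samples whose pupil size diverges more than `k` sd
#'   from the mean (`NULL` to skip, or no pupil column).
#' @param detrend_order polynomial detrend order (0 = skip, 1 = linear, ...).
#' @param smooth_ms running-average kernel width in milliseconds (0 = skip).
#' @param center_median subtract the median gaze position.
#' @return the cleaned trace (same columns, possibly fewer rows).
#' @export
clean_gaze_trace <- function(trace, rate_hz,
                             remove_blinks = TRUE,
                             pupil_sd_k = NULL,
                             detrend_order = 1L,
                             smooth_ms = 100,
                             center_median = FALSE) {
  if (rate_hz <= 0) stop("rate_hz must be > 0")
  if (!nrow(trace)) stop("empty gaze trace")
  if (remove_blinks)
    trace <- trace[stats::complete.cases(trace[, c("x", "y")]), , drop = FALSE]
  if (!nrow(trace)) stop("gaze trace empty after blink removal")
  if (!is.null(pupil_sd_k) && "pupil" %in% names(trace)) {
    z <- abs(trace$pupil - mean(trace$pupil)) / stats::sd(trace$pupil)
    z[is.na(z)] <- 0
    trace <- trace[z <= pupil_sd_k, , drop = FALSE]
  }
  if (detrend_order >= 1L && nrow(trace) > detrend_order + 1) {
    for (col in c("x", "y")) {
      v <- trace[[col]]
      if (stats::sd(v) > 0) {
        fit <- stats::lm(v ~ stats::poly(trace$t, detrend_order, raw = TRUE))
        trace[[col]] <- mean(v) + stats::residuals(fit)
      }
    }
  }
  if (smooth_ms > 0) {
    w <- max(1L, round(rate_hz * smooth_ms / 1000))
    if (w > 1L) {
      kern <- rep(1 / w, w)
      for (col in c("x", "y"))
        trace[[col]] <- running_mean(trace[[col]], w)
    }
  }
  if (center_median) {
    trace$x <- trace$x - stats::median(trace$x)
    trace$y <- trace$y - stats::median(trace$y)
  }
  trace
}

# centered running mean with edge truncation (window shrinks at the borders)
running_mean <- function(v, w) {
  n <- length(v)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Bin a cleaned gaze trace into sub-TR labels
#'
#' Splits each TR into `n_sub` equal bins and takes the per-bin median of the
#' samples falling in it. Empty bins are filled from the nearest nonempty bin
#' (forward, then backward); a fully empty TR copies the previous TR's labels
#' and is flagged in the attached gap report.
#'
#' @param trace data.frame with columns `t` (seconds from run start), `x`, `y`.
#' @param tr_s repetition time in seconds.
#' @param n_tr number of TRs in the run.
#' @param n_sub sub-TR bins per TR (default 10).
#' @param window a [screen_window()] recorded on the labels.
#' @return a [gaze_labels()] with attribute `"gap_report"` listing copied TRs.
#' @export
bin_to_subtr <- function(trace, tr_s, n_tr, n_sub = 10L,
                         window = screen_window(20, 20)) {
  n_sub <- as.integer(n_sub)
  coords <- array(NA_real_, c(n_tr, n_sub, 2))
  bin_s <- tr_s / n_sub
  bin_idx <- floor(trace$t / bin_s)
  for (tr in seq_len(n_tr)) {
    base <- (tr - 1L) * n_sub
    for (b in seq_len(n_sub)) {
      in_bin <- bin_idx == (base + b - 1L)
      if (any(in_bin)) {
        coords[tr, b, 1] <- stats::median(trace$x[in_bin])
        coords[tr, b, 2] <- stats::median(trace$y[in_bin])
      }
    }
  }
  gap_trs <- integer(0)
  for (tr in seq_len(n_tr)) {
    row <- coords[tr, , 1]
    if (all(is.na(row))) {
      gap_trs <- c(gap_trs, tr)
      if (tr > 1L) coords[tr, , ] <- coords[tr - 1L, , ]
      next
    }
    for (dim2 in 1:2) coords[tr, , dim2] <- fill_nearest(coords[tr, , dim2])
  }
  # a leading fully-empty TR copies the first filled TR backward
  if (length(gap_trs) && gap_trs[1] == 1L) {
    first_ok <- setdiff(seq_len(n_tr), gap_trs)[1]
    if (is.na(first_ok)) stop("gaze trace covers no TR at all")
    for (tr in rev(seq_len(first_ok - 1L))) coords[tr, , ] <- coords[tr + 1L, , ]
  }
  out <- gaze_labels(coords, window, tr_s = tr_s)
  attr(out, "gap_report") <- gap_trs
  out
}

# fill NA entries from the nearest non-NA neighbour (forward then backward)
fill_nearest <- function(v) {
  n <- length(v)
  ok <- which(!is.na(v))
  if (!length(ok)) return(v)
  for (i in seq_len(n)) {
    if (is.na(v[i])) {
      prev <- ok[ok < i]
      nxt <- ok[ok > i]
      src <- if (length(prev)) max(prev) else min(nxt)
      v[i] <- v[src]
    }
  }
  v
}

#' Median gaze position per TR
#'
#' Component-wise median of the `n_sub` sub-TR labels; for even counts the
#' convention is the mean of the middle two.
#'
#' @param labels a [gaze_labels()] or an array `n_tr x n_sub x 2`.
#' @return matrix `n_tr x 2` of (x, y) degrees.
#' @export
median_gaze <- function(labels) {
  coords <- if (inherits(labels, "gaze_labels")) labels$coords else labels
  cbind(apply(coords[, , 1, drop = FALSE], 1, stats::median),
        apply(coords[, , 2, drop = FALSE], 1, stats::median))
}

#' Estimate and apply a screen-center offset
#'
#' The offset of the average gaze from the screen centre can be estimated in
#' the training labels (median over all training TRs) and subtracted after
#' decoding.
#'
#' @param labels a [gaze_labels()].
#' @return `estimate_center_offset`: numeric(2) (dx, dy) degrees.
#' @export
estimate_center_offset <- function(labels) {
  mg <- median_gaze(labels)
  c(stats::median(mg[, 1]), stats::median(mg[, 2]))
}

#' @rdname estimate_center_offset
#' @param offset numeric(2) to subtract from every coordinate.
#' @return `apply_offset`: the shifted [gaze_labels()].
#' @export
apply_offset <- function(labels, offset) {
  labels$coords[, , 1] <- labels$coords[, , 1] - offset[1]
  labels$coords[, , 2] <- labels$coords[, , 2] - offset[2]
  labels
}

#' Read/write gaze label tables
#'
#' TSV with header columns tr_index, sub_index, x_deg, y_deg
#' `[, closed_fraction]`; indices are 1-based.
#'
#' @param labels a [gaze_labels()].
#' @param path output path.
#' @return `write_gaze_tsv`: invisibly, `path`.
#' @export
write_gaze_tsv <- function(labels, path) {
  n_tr <- dim(labels$coords)[1]
  n_sub <- labels$n_sub
  df <- data.frame(
    tr_index = rep(seq_len(n_tr), each = n_sub),
    sub_index = rep(seq_len(n_sub), n_tr),
    x_deg = as.vector(t(labels$coords[, , 1])),
    y_deg = as.vector(t(labels$coords[, , 2])))
  if (!is.null(labels$closed))
    df$closed_fraction <- rep(labels$closed, each = n_sub)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @param window,tr_s metadata for the reconstructed labels.
#' @return `read_gaze_tsv`: a [gaze_labels()].
#' @export
read_gaze_tsv <- function(path, window = screen_window(20, 20), tr_s = 1) {
  df <- utils::read.delim(path)
  n_tr <- max(df$tr_index)
  n_sub <- max(df$sub_index)
  coords <- array(NA_real_, c(n_tr, n_sub, 2))
  coords[cbind(df$tr_index, df$sub_index, 1L)] <- df$x_deg
  coords[cbind(df$tr_index, df$sub_index, 2L)] <- df$y_deg
  closed <- NULL
  if ("closed_fraction" %in% names(df))
    closed <- df$closed_fraction[df$sub_index == 1L][order(df$tr_index[df$sub_index == 1L])]
  gaze_labels(coords, window, tr_s = tr_s, closed = closed)
}
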
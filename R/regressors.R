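#' Per-TR eye-movement index
#'
#' Euclidean distance between the (median) gaze positions of subsequent
#' volumes: `amplitude[t] = ||gaze[t+1] - gaze[t]||`. The forward difference
#' leaves the final TR undefined; it is set to 0.
#'
#' @param path matrix `n_tr x 2` of per-TR gaze positions (degrees).
#' @return numeric(n_tr) movement amplitudes (degrees, >= 0).
#' @export
movement_index <- function(path) {
  if (nrow(path) < 2L) stop("movement index needs >= 2 TRs")
  d <- sqrt(rowSums((path[-1, , drop = FALSE] -
                     path[-nrow(path), , drop = FALSE])^2))
  c(d, 0)
}

#' Binarize movement amplitudes into far/short regressors
#'
#' `far = 1` where the amplitude exceeds its within-run 66th percentile,
#' `short = 1` where it falls below the 33rd percentile; the midsection is
#' excluded (both 0) to separate the modeled events in time. Percentiles use
#' linear interpolation between order statistics (R quantile type 7).
#'
#' @param index numeric movement amplitudes for one run.
#' @return list with binary `far` and `short` series and the percentile
#'   `cutoffs`.
#' @export
binarize_far_short <- function(index) {
  if (!length(index)) stop("empty movement index")
  p66 <- stats::quantile(index, 0.66, names = FALSE)
  p33 <- stats::quantile(index, 0.33, names = FALSE)
  far <- as.integer(index > p66)
  short <- as.integer(index < p33)
  if (all(far == 0L) && all(short == 0L))
    warning("all movement amplitudes equal: far/short regressors are empty")
  list(far = far, short = short, cutoffs = c(p33 = p33, p66 = p66))
}

#' Canonical double-gamma HRF kernel
#'
#' The conventional canonical hemodynamic response function: a response gamma
#' density minus a scaled undershoot gamma density, sampled at the TR and
#' normalized to unit peak.
#'
#' @param tr_s sampling step (repetition time) in seconds.
#' @param peak_delay_s,undershoot_delay_s gamma delays (defaults 6 and 16 s).
#' @param peak_disp,undershoot_disp dispersions (defaults 1 and 1).
#' @param undershoot_ratio response/undershoot amplitude ratio (default 6).
#' @param length_s kernel support in seconds (default 32).
#' @return object of class `hrf_kernel`: list with `values`, `times_s`, and
#'   the parameters.
#' @export
hrf_kernel <- function(tr_s, peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_disp = 1, undershoot_disp = 1,
                       undershoot_ratio = 6, length_s = 32) {
  if (tr_s <= 0) stop("tr_s must be > 0")
  t <- seq(0, length_s, by = tr_s)
  h <- stats::dgamma(t, shape = peak_delay_s / peak_disp,
                     rate = 1 / peak_disp) -
    stats::dgamma(t, shape = undershoot_delay_s / undershoot_disp,
                  rate = 1 / undershoot_disp) / undershoot_ratio
  h <- h / max(h)
  structure(list(values = h, times_s = t, tr_s = tr_s,
                 params = c(peak_delay_s = peak_delay_s,
                            undershoot_delay_s = undershoot_delay_s,
                            peak_disp = peak_disp,
                            undershoot_disp = undershoot_disp,
                            undershoot_ratio = undershoot_ratio,
                            length_s = length_s)),
            class = "hrf_kernel")
}

#' Convolve a regressor with an HRF kernel
#'
#' Causal convolution truncated to the run length.
#'
#' @param series numeric regressor (one run).
#' @param kernel an [hrf_kernel()].
#' @return numeric series of the same length.
#' @export
convolve_regressor <- function(series, kernel) {
  n <- length(series)
  full <- stats::convolve(series, rev(kernel$values), type = "open")
  full[seq_len(n)]
}

#' Far/short eye-movement regressor set for one run
#'
#' @param path matrix `n_tr x 2` decoded per-TR gaze.
#' @param tr_s repetition time in seconds.
#' @param hrf `TRUE` to return HRF-convolved regressors alongside the binary
#'   ones; `FALSE` models instantaneous (e.g. artifact-driven) effects.
#' @param run_id identifier.
#' @return object of class `regressor_set`: list with `far`, `short`
#'   (binary), `far_conv`, `short_conv` (or `NULL`), `index`, `run_id`,
#'   `hrf` kernel used.
#' @export
regressor_set <- function(path, tr_s, hrf = TRUE, run_id = "run1") {
  idx <- movement_index(path)
  bin <- binarize_far_short(idx)
  kern <- NULL
  far_conv <- short_conv <- NULL
  if (hrf) {
    kern <- hrf_kernel(tr_s)
    far_conv <- convolve_regressor(bin$far, kern)
    short_conv <- convolve_regressor(bin$short, kern)
  }
  structure(list(far = bin$far, short = bin$short, far_conv = far_conv,
                 short_conv = short_conv, cutoffs = bin$cutoffs, index = idx,
                 run_id = run_id, hrf = kern),
            class = "regressor_set")
}

#' Assemble a GLM design-matrix table
#'
#' Stacks per-run far/short regressors (HRF-convolved if `hrf = "on"`),
#' optional head-motion columns, and block-diagonal run intercepts.
#'
#' @param regressor_sets list of [regressor_set()]s, one per run.
#' @param motion optional data.frame/matrix with 6 head-motion columns
#'   (`trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`), rows matching the
#'   concatenated runs.
#' @param hrf `"on"` to use the convolved regressors, `"off"` for the raw
#'   binary series.
#' @return data.frame with columns `far`, `short`, the motion columns if
#'   given, and one `run_<id>` intercept per run.
#' @export
build_design <- function(regressor_sets, motion = NULL, hrf = c("on", "off")) {
  hrf <- match.arg(hrf)
  n_per_run <- vapply(regressor_sets, function(r) length(r$far), 1L)
  n_total <- sum(n_per_run)
  far <- unlist(lapply(regressor_sets, function(r)
    if (hrf == "on") {
      if (is.null(r$far_conv))
        stop("hrf = 'on' but run ", r$run_id, " has no convolved regressors")
      r$far_conv
    } else r$far))
  short <- unlist(lapply(regressor_sets, function(r)
    if (hrf == "on") r$short_conv else r$short))
  df <- data.frame(far = far, short = short)
  if (!is.null(motion)) {
    motion <- as.data.frame(motion)
    if (nrow(motion) != n_total)
      stop(sprintf("motion table has %d rows but runs total %d TRs",
                   nrow(motion), n_total))
    if (ncol(motion) != 6L)
      stop("motion table must have 6 columns")
    names(motion) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
    df <- cbind(df, motion)
  }
  offset <- 0L
  for (r in regressor_sets) {
    col <- numeric(n_total)
    col[(offset + 1):(offset + length(r$far))] <- 1
    df[[paste0("run_", r$run_id)]] <- col
    offset <- offset + length(r$far)
  }
  df
}

#' Write a design matrix as TSV
#' @param design a [build_design()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
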
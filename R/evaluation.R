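#' Pearson correlation between true and decoded gaze paths
#'
#' Computed per coordinate (horizontal, vertical) and averaged.
#'
#' @param true,decoded matrices `n_tr x 2` of per-TR gaze positions.
#' @return scalar in `[-1, 1]`, or `NA` with a warning if either series has
#'   zero variance.
#' @export
pearson_gaze <- function(true, decoded) {
  check_paths(true, decoded, min_tr = 3L)
  rs <- vapply(1:2, function(k) {
    if (stats::sd(true[, k]) == 0 || stats::sd(decoded[, k]) == 0)
      return(NA_real_)
    stats::cor(true[, k], decoded[, k])
  }, 1)
  if (any(is.na(rs))) {
    warning("zero-variance gaze series: Pearson r undefined")
    return(NA_real_)
  }
  mean(rs)
}

#' Coefficient of determination of the decoded gaze path
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)` per coordinate, then
#' averaged. Unlike the squared correlation it is sensitive to scale and
#' offset and can be arbitrarily negative.
#'
#' @inheritParams pearson_gaze
#' @return scalar `<= 1`, or `NA` with a warning on zero-variance truth.
#' @export
r_squared_gaze <- function(true, decoded) {
  check_paths(true, decoded, min_tr = 3L)
  rs <- vapply(1:2, function(k) {
    den <- sum((true[, k] - mean(true[, k]))^2)
    if (den == 0) return(NA_real_)
    1 - sum((true[, k] - decoded[, k])^2) / den
  }, 1)
  if (any(is.na(rs))) {
    warning("zero-variance truth: R^2 undefined")
    return(NA_real_)
  }
  mean(rs)
}

#' Per-participant Euclidean error
#'
#' Mean over TRs of the 2D Euclidean distance between true and decoded
#' per-TR (median) gaze positions, in visual degrees. `aggregate = "median"`
#' is exposed as an alternative TR aggregation.
#'
#' @inheritParams pearson_gaze
#' @param aggregate `"mean"` (default) or `"median"` over TRs.
#' @return scalar degrees (>= 0).
#' @export
participant_ee <- function(true, decoded, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  check_paths(true, decoded, min_tr = 1L)
  d <- sqrt(rowSums((true - decoded)^2))
  if (aggregate == "mean") mean(d) else stats::median(d)
}

check_paths <- function(true, decoded, min_tr) {
  if (nrow(true) != nrow(decoded))
    stop(sprintf("path length mismatch: %d vs %d TRs", nrow(true),
                 nrow(decoded)))
  if (nrow(true) < min_tr)
    stop("need at least ", min_tr, " TRs")
  invisible(TRUE)
}

#' Error as a fraction of stimulus size (FoS)
#'
#' The Euclidean error divided by the stimulus diagonal
#' `sqrt(x_range^2 + y_range^2)`.
#'
#' @param ee Euclidean error in degrees.
#' @param window a [screen_window()].
#' @return fraction (>= 0).
#' @export
fos <- function(ee, window) {
  ee / window_diag(window)
}

#' @rdname fos
#' @return `fos_percent`: the display form — the percentage truncated
#'   (floored) to an integer, the convention consistent with the printed
#'   values for all reference datasets.
#' @export
fos_percent <- function(ee, window) {
  floor(100 * fos(ee, window))
}

#' Evaluate decoded gaze for a set of participants
#'
#' @param truths,decodeds lists of `n_tr x 2` per-TR gaze paths.
#' @param pes optional list/vector of per-TR predicted errors per participant.
#' @param window a [screen_window()] for the FoS column.
#' @param ids participant identifiers.
#' @return data.frame of class `metrics_report`: one row per participant with
#'   `ee`, `pearson_r`, `r_squared`, `fos`, `fos_pct`, `mean_pe`.
#' @export
evaluate_decoding <- function(truths, decodeds, pes = NULL,
                              window = screen_window(10, 10),
                              ids = NULL) {
  n <- length(truths)
  if (is.null(ids)) ids <- paste0("sub-", sprintf("%02d", seq_len(n)))
  rows <- lapply(seq_len(n), function(i) {
    ee <- participant_ee(truths[[i]], decodeds[[i]])
    data.frame(
      participant = ids[i],
      ee = ee,
      pearson_r = pearson_gaze(truths[[i]], decodeds[[i]]),
      r_squared = r_squared_gaze(truths[[i]], decodeds[[i]]),
      fos = fos(ee, window),
      fos_pct = fos_percent(ee, window),
      mean_pe = if (is.null(pes)) NA_real_ else mean(pes[[i]]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Group summary of a metrics report
#'
#' Median across participants (the group summary used for headline numbers),
#' optionally restricted to the low-PE subset.
#'
#' @param report a [evaluate_decoding()] result.
#' @param low_pe_only summarise only the 80% most reliable participants.
#' @param keep_fraction fraction kept as low-PE.
#' @return named numeric vector of group medians.
#' @export
summarize_metrics <- function(report, low_pe_only = FALSE,
                              keep_fraction = 0.8) {
  if (low_pe_only) {
    sp <- pe_split(report, keep_fraction)
    report <- report[report$participant %in% sp$low_pe, , drop = FALSE]
  }
  c(ee = stats::median(report$ee),
    pearson_r = stats::median(report$pearson_r),
    r_squared = stats::median(report$r_squared),
    fos = stats::median(report$fos),
    mean_pe = stats::median(report$mean_pe))
}

#' Split participants by predicted error
#'
#' Ranks participants by mean PE and keeps the lowest `keep_fraction`
#' (default 80%) as the reliable ("low PE") group. Ties break by participant
#' id order (first listed wins the low-PE slot).
#'
#' @param report a [evaluate_decoding()] result (or data.frame with
#'   `participant` and `mean_pe`).
#' @param keep_fraction fraction of participants kept, in (0, 1].
#' @return object of class `pe_split`: list with `low_pe`, `high_pe` id
#'   vectors and the `threshold` mean PE.
#' @export
pe_split <- function(report, keep_fraction = 0.8) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  n <- nrow(report)
  n_low <- round(keep_fraction * n)
  ord <- order(report$mean_pe, seq_len(n))
  low <- report$participant[ord[seq_len(n_low)]]
  high <- report$participant[ord[setdiff(seq_len(n), seq_len(n_low))]]
  structure(list(low_pe = low, high_pe = high,
                 threshold = if (n_low > 0 && n_low < n)
                   report$mean_pe[ord[n_low]] else NA_real_),
            class = "pe_split")
}

#' Drop unreliable samples within a participant
#'
#' Removes TRs whose PE exceeds the given within-participant percentile.
#'
#' @param decoded matrix `n_tr x 2` decoded path.
#' @param pe numeric(n_tr) predicted errors.
#' @param percentile keep TRs with PE at or below this percentile (0-100).
#' @return list with filtered `decoded`, `kept` indices.
#' @export
filter_samples_by_pe <- function(decoded, pe, percentile = 80) {
  thr <- stats::quantile(pe, percentile / 100, names = FALSE)
  kept <- which(pe <= thr)
  list(decoded = decoded[kept, , drop = FALSE], kept = kept)
}

#' Linear upsampling of a decoded sub-TR path
#'
#' Places the `n` decoded labels of each TR at within-TR times
#' `(h - 0.5) / n` and linearly interpolates the concatenated run path at the
#' 10-labels-per-TR grid, so decodings with different head counts are
#' compared on an equal footing.
#'
#' @param path matrix `(n_tr * n) x 2` decoded sub-TR path, TR-major.
#' @param n labels per TR of the input path.
#' @param n_out labels per TR of the output grid (default 10).
#' @param n_tr number of TRs.
#' @return matrix `(n_tr * n_out) x 2`.
#' @export
upsample_path <- function(path, n, n_tr, n_out = 10L) {
  t_in <- rep(seq_len(n_tr) - 1, each = n) + (seq_len(n) - 0.5) / n
  t_out <- rep(seq_len(n_tr) - 1, each = n_out) + (seq_len(n_out) - 0.5) / n_out
  out <- matrix(0, length(t_out), 2)
  for (k in 1:2)
    out[, k] <- stats::approx(t_in, path[, k], xout = t_out, rule = 2)$y
  out
}

#' Sub-TR temporal resolution analysis
#'
#' For each head count `n` in `n_labels`, trains a decoder with `n` sub-TR
#' heads (targets are the per-bin medians of the 10-label truth), decodes the
#' test participants, upsamples the decoded path to 10 labels/TR by linear
#' interpolation, and computes the R^2 against the 10-label ground truth.
#' The per-participant curves are range-normalized.
#'
#' @param train_pool,test_pool [training_pool()]s built with 10-label targets.
#' @param cfg_base a [model_config()] whose `n_sub` is overridden per run.
#' @param schedule a [training_schedule()].
#' @param n_labels head counts to evaluate.
#' @param augmentation optional [augmentation_config()].
#' @param seed build/training seed.
#' @return list with `r2` (participants x head counts matrix),
#'   `normalized` (range-normalized within participant), `n_labels`.
#' @export
subtr_analysis <- function(train_pool, test_pool, cfg_base, schedule,
                           n_labels = c(1L, 3L, 10L), augmentation = NULL,
                           seed = 1L) {
  r2 <- matrix(NA_real_, length(test_pool), length(n_labels),
               dimnames = list(NULL, paste0("n", n_labels)))
  for (j in seq_along(n_labels)) {
    n <- n_labels[j]
    cfg <- cfg_base
    cfg$n_sub <- as.integer(n)
    tp <- rebin_targets(train_pool, n)
    net <- build_network(cfg, seed = seed)
    fit <- train_network(net, tp, schedule, augmentation)
    for (i in seq_along(test_pool)) {
      te <- test_pool[[i]]
      pr <- net_predict(fit$net, te$x)
      n_tr <- te$n_tr
      dec <- matrix(0, n_tr * n, 2)
      for (h in seq_len(n)) {
        dec[seq(h, n_tr * n, by = n), 1] <- pr$gaze[h, 1, ]
        dec[seq(h, n_tr * n, by = n), 2] <- pr$gaze[h, 2, ]
      }
      dec10 <- upsample_path(dec, n, n_tr, 10L)
      truth10 <- matrix(0, n_tr * 10L, 2)
      for (h in 1:10) {
        truth10[seq(h, n_tr * 10L, by = 10L), 1] <- te$targets[h, 1, ]
        truth10[seq(h, n_tr * 10L, by = 10L), 2] <- te$targets[h, 2, ]
      }
      r2[i, j] <- r_squared_gaze(truth10, dec10)
    }
  }
  normalized <- t(apply(r2, 1, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  }))
  list(r2 = r2, normalized = normalized, n_labels = n_labels)
}

# collapse 10-label gaze targets to n per-bin medians
rebin_targets <- function(pool, n) {
  lapply(pool, function(p) {
    t10 <- p$targets     # 10 x 2 x n_tr
    n10 <- dim(t10)[1]
    bins <- split(seq_len(n10), ceiling(seq_len(n10) / (n10 / n)))
    tn <- array(0, c(n, 2L, dim(t10)[3]))
    for (h in seq_len(n)) {
      tn[h, 1, ] <- apply(t10[bins[[h]], 1, , drop = FALSE], 3, stats::median)
      tn[h, 2, ] <- apply(t10[bins[[h]], 2, , drop = FALSE], 3, stats::median)
    }
    p$targets <- tn
    p
  })
}

#' Train an eyes-closed decoder and decode a closure series
#'
#' Trains the closure variant of the network (one scalar output per volume,
#' pure MSE loss) on per-TR closed fractions and decodes the test pool.
#'
#' @param train_pool,test_pool [training_pool()]s built with
#'   `target = "closure"`.
#' @param cfg a [model_config()] with `target = "closure"`.
#' @param schedule a [training_schedule()].
#' @param augmentation optional [augmentation_config()].
#' @param seed build seed.
#' @return list with `fit` (trained network + history) and `decoded`
#'   (list of per-participant decoded closed-fraction series).
#' @export
decode_closure <- function(train_pool, test_pool, cfg, schedule,
                           augmentation = NULL, seed = 1L) {
  if (cfg$target != "closure") stop("cfg must have target = 'closure'")
  net <- build_network(cfg, seed = seed)
  fit <- train_network(net, train_pool, schedule, augmentation)
  decoded <- lapply(test_pool, function(p) drop(net_predict(fit$net, p$x)$gaze))
  list(fit = fit, decoded = decoded)
}

#' Classify eyes-open versus eyes-closed volumes
#'
#' Binarizes the decoded (continuous) closed-fraction series and the ground
#' truth at `threshold` and reports the confusion counts, accuracy, balanced
#' accuracy `(TPR + TNR) / 2`, and the ROC curve/AUC of the continuous series
#' against the binarized truth.
#'
#' @param decoded numeric decoded closed-fraction series.
#' @param truth numeric true closed-fraction series.
#' @param threshold closed-fraction cutoff in `[0, 1)`.
#' @return object of class `closure_classification`: list with `threshold`,
#'   `confusion` (tp, fn, tn, fp), `accuracy`, `balanced_accuracy`, `roc`
#'   (data.frame fpr, tpr), `auc`.
#' @export
classify_closure <- function(decoded, truth, threshold = 0.1) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  stopifnot(length(decoded) == length(truth))
  truth_bin <- truth > threshold
  pred_bin <- decoded > threshold
  tp <- sum(pred_bin & truth_bin); fn <- sum(!pred_bin & truth_bin)
  tn <- sum(!pred_bin & !truth_bin); fp <- sum(pred_bin & !truth_bin)
  acc <- (tp + tn) / length(truth)
  bal <- if (tp + fn == 0 || tn + fp == 0) {
    warning("degenerate truth (single class): balanced accuracy undefined")
    NA_real_
  } else (tp / (tp + fn) + tn / (tn + fp)) / 2
  roc <- roc_points(decoded, truth_bin)
  structure(list(threshold = threshold,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 accuracy = acc, balanced_accuracy = bal,
                 roc = roc$points, auc = roc$auc),
            class = "closure_classification")
}

roc_points <- function(score, truth_bin) {
  if (!any(truth_bin) || all(truth_bin))
    return(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auc = NA_real_))
  cuts <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pred <- score >= cuts[i]
    tpr[i] <- sum(pred & truth_bin) / sum(truth_bin)
    fpr[i] <- sum(pred & !truth_bin) / sum(!truth_bin)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Balanced accuracy from confusion counts
#' @param tp,fn,tn,fp confusion counts.
#' @return `(TPR + TNR) / 2`.
#' @export
balanced_accuracy <- function(tp, fn, tn, fp) {
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Slice-shuffling voxel-wise saliency
#'
#' Per iteration, picks a slice (along one of the three axes), permutes that
#' slice's voxel values across time (destroying its information while keeping
#' its marginal distribution), re-decodes, and credits the increase in the
#' participant's Euclidean error to every voxel of the slice. The final map
#' is the summed credit divided by each voxel's participation count.
#'
#' @param net a trained network.
#' @param x matrix `V x n_tr` of normalized input volumes (one participant).
#' @param truth matrix `n_tr x 2` per-TR true (median) gaze.
#' @param n_iters shuffle iterations (>= 1); slices are cycled systematically.
#' @param seed permutation seed.
#' @return object of class `saliency_map`: list with `map` (3D array of mean
#'   Euclidean-error increase in degrees), `counts` (participation), and
#'   `baseline_ee`.
#' @export
saliency <- function(net, x, truth, n_iters = 96L, seed = 1L) {
  if (n_iters < 1) stop("n_iters must be >= 1")
  dims <- net$cfg$input_dims
  n_tr <- ncol(x)
  base <- net_predict(net, x)
  base_ee <- participant_ee(truth, t(apply(base$gaze, 3, function(g)
    apply(matrix(g, net$cfg$n_sub, 2), 2, stats::median))))
  slice_list <- list()
  for (ax in 1:3) for (s in seq_len(dims[ax]))
    slice_list[[length(slice_list) + 1L]] <- c(ax, s)
  set.seed(seed)
  order_it <- rep(seq_along(slice_list), length.out = n_iters)
  sums <- array(0, dims)
  counts <- array(0, dims)
  vol_idx <- array(seq_len(prod(dims)), dims)
  for (it in seq_len(n_iters)) {
    ax <- slice_list[[order_it[it]]][1]
    s <- slice_list[[order_it[it]]][2]
    vox <- switch(ax,
                  as.vector(vol_idx[s, , ]),
                  as.vector(vol_idx[, s, ]),
                  as.vector(vol_idx[, , s]))
    xs <- x
    xs[vox, ] <- x[vox, sample.int(n_tr)]
    pr <- net_predict(net, xs)
    ee <- participant_ee(truth, t(apply(pr$gaze, 3, function(g)
      apply(matrix(g, net$cfg$n_sub, 2), 2, stats::median))))
    sums[vox] <- sums[vox] + (ee - base_ee)
    counts[vox] <- counts[vox] + 1
  }
  map <- sums
  map[counts > 0] <- map[counts > 0] / counts[counts > 0]
  structure(list(map = map, counts = counts, baseline_ee = base_ee),
            class = "saliency_map")
}

#' Decoded per-TR median gaze path from network output
#'
#' @param gaze array `n_sub x 2 x n_tr` as returned by [net_predict()].
#' @return matrix `n_tr x 2` of per-TR medians.
#' @export
decoded_median_path <- function(gaze) {
  t(apply(gaze, 3, function(g) apply(matrix(g, dim(gaze)[1], 2), 2,
                                     stats::median)))
}

#' Write a metrics report as TSV and JSON
#'
#' @param report a [evaluate_decoding()] result.
#' @param tsv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, the written paths.
#' @export
write_metrics <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(report, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(participants = report,
                              group_median = as.list(summarize_metrics(report))),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(c(tsv_path, json_path))
}

#' Write a saliency map as NIfTI (input-box space)
#'
#' @param sal a [saliency()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_saliency_nifti <- function(sal, path) {
  RNifti::writeNifti(RNifti::asNifti(sal$map), path)
  invisible(path)
}
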
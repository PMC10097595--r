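#' Fit an MR-based gaze decoder
#'
#' The main fitting function: trains the 3D convolutional decoder on the
#' eye-mask voxel patterns of a set of training participants and returns a
#' fitted-model object with the usual methods (`print`, `summary`, `coef`,
#' `predict`, `plot`).
#'
#' Input series are normalized internally with the canonical two-stage
#' pipeline ([temporal_normalize()] then [spatial_normalize()]) unless
#' `normalize = FALSE` (pass pre-normalized data then).
#'
#' @param series_list list of [volume_series()], one per training
#'   participant/run.
#' @param labels_list list of matching [gaze_labels()].
#' @param config a [model_config()]; its `input_dims` must equal the cropped
#'   series dims.
#' @param schedule a [training_schedule()].
#' @param augmentation an [augmentation_config()] or `NULL`.
#' @param normalize normalize the input series internally.
#' @param seed weight-initialization seed.
#' @param verbose print per-epoch losses.
#' @return an object of class `gaze_decoder`.
#' @export
gaze_decoder <- function(series_list, labels_list,
                         config = model_config(),
                         schedule = training_schedule(),
                         augmentation = augmentation_config(),
                         normalize = TRUE, seed = 1L, verbose = FALSE) {
  if (normalize) series_list <- lapply(series_list, normalize_series)
  dims <- dim(series_list[[1]]$data)[1:3]
  if (!all(dims == config$input_dims))
    stop(sprintf("series box %s does not match config input_dims %s",
                 paste(dims, collapse = "x"),
                 paste(config$input_dims, collapse = "x")))
  pool <- training_pool(series_list, labels_list,
                        target = config$target)
  center_offset <- if (config$target == "gaze") {
    offs <- vapply(labels_list, estimate_center_offset, numeric(2))
    rowMeans(offs)
  } else c(0, 0)
  net <- build_network(config, seed = seed)
  fit <- train_network(net, pool, schedule, augmentation, verbose = verbose)
  structure(list(net = fit$net, config = config, schedule = schedule,
                 history = fit$history,
                 samples_per_epoch = fit$samples_per_epoch,
                 center_offset = center_offset,
                 window = labels_list[[1]]$window,
                 n_train = length(pool),
                 normalize = normalize),
            class = "gaze_decoder")
}

#' @export
print.gaze_decoder <- function(x, ...) {
  cat("MR-based gaze decoder\n")
  cat(sprintf("  trained on %d participant(s), %d epoch(s) x %d steps x batch %d\n",
              x$n_train, nrow(x$history), x$schedule$steps_per_epoch,
              x$schedule$batch_size))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses: l = %.4f (l_ed = %.4f, l_mse = %.4f)\n",
              last$l, last$l_ed, last$l_mse))
  cat(sprintf("  input %s, %d sub-TR head(s)%s\n",
              paste(x$config$input_dims, collapse = "x"), x$config$n_sub,
              if (x$config$use_pe) " + PE head" else ""))
  invisible(x)
}

#' @export
summary.gaze_decoder <- function(object, ...) {
  cat("MR-based gaze decoder\n\n")
  print(object$net$shape$stages, row.names = FALSE)
  cat(sprintf("\nBottleneck: %d units; outputs per volume: %d\n",
              object$net$shape$bottleneck_units, object$net$shape$n_outputs))
  cat(sprintf("Parameters: %s\n",
              format(sum(vapply(object$net$params, length, 1L)),
                     big.mark = ",")))
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' @export
coef.gaze_decoder <- function(object, ...) {
  object$net$params
}

#' Decode gaze from new volumes
#'
#' @param object a fitted [gaze_decoder()].
#' @param newdata a [volume_series()] (raw if the model was fitted with
#'   `normalize = TRUE`), or a `V x N` matrix of already-prepared inputs.
#' @param apply_center_offset subtract the screen-center offset estimated
#'   from the training labels.
#' @param ... unused.
#' @return list with `gaze` (array `n_sub x 2 x n_tr` of sub-TR coordinates),
#'   `path` (matrix `n_tr x 2` per-TR median gaze), and `pe` (per-TR
#'   predicted error).
#' @export
predict.gaze_decoder <- function(object, newdata,
                                 apply_center_offset = FALSE, ...) {
  if (inherits(newdata, "volume_series")) {
    if (object$normalize) newdata <- normalize_series(newdata)
    d <- dim(newdata$data)
    x <- matrix(newdata$data, prod(d[1:3]), d[4])
  } else x <- newdata
  pr <- net_predict(object$net, x)
  if (object$config$target == "closure")
    return(list(closure = drop(pr$gaze)))
  if (apply_center_offset) {
    pr$gaze[, 1, ] <- pr$gaze[, 1, ] - object$center_offset[1]
    pr$gaze[, 2, ] <- pr$gaze[, 2, ] - object$center_offset[2]
  }
  list(gaze = pr$gaze, path = decoded_median_path(pr$gaze), pe = pr$pe)
}

#' Plot decoder training history or decoded paths
#'
#' @param x a fitted [gaze_decoder()].
#' @param which `"history"` (loss per epoch) or `"path"` (decoded vs true).
#' @param truth,decoded for `which = "path"`: `n_tr x 2` matrices.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.gaze_decoder <- function(x, which = c("history", "path"),
                              truth = NULL, decoded = NULL, ...) {
  which <- match.arg(which)
  if (which == "history") {
    plot(x$history$epoch, x$history$l_ed, type = "b", pch = 16,
         xlab = "epoch", ylab = "Euclidean loss (deg)",
         main = "Training history", ...)
  } else {
    if (is.null(truth) || is.null(decoded))
      stop("path plot needs truth and decoded matrices")
    plot(truth[, 1], truth[, 2], type = "l", col = "grey40",
         xlab = "x (deg)", ylab = "y (deg)", main = "Decoded gaze path", ...)
    graphics::lines(decoded[, 1], decoded[, 2], col = "firebrick")
    graphics::legend("topright", legend = c("true", "decoded"),
                     col = c("grey40", "firebrick"), lty = 1, bty = "n")
  }
  invisible(x)
}
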
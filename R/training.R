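#' Cross-validation fold plans
#'
#' Builds one of the three decoding schemes:
#' * `across_participant` — participants are shuffled into `k` equally sized
#'   partitions; each fold trains on `k - 1` partitions (80% at `k = 5`) and
#'   tests on the held-out one, until every participant was tested once.
#' * `within_participant` — the data of each participant are split into two
#'   equally sized contiguous halves; two folds train on one half of every
#'   participant and test on the other.
#' * `across_dataset` — leave-one-dataset-out: one fold per dataset, training
#'   on all other datasets.
#'
#' @param participants character or integer vector of participant ids.
#' @param scheme one of `"across_participant"`, `"within_participant"`,
#'   `"across_dataset"`.
#' @param datasets for `across_dataset`: dataset id per participant.
#' @param k partitions for the across-participant scheme.
#' @param seed shuffle seed.
#' @return an object of class `fold_plan`: list of folds, each with `train`
#'   and `test` data.frames (columns `participant`, `part` where `part` is
#'   `"all"`, `"first"` or `"second"`).
#' @export
make_folds <- function(participants,
                       scheme = c("across_participant", "within_participant",
                                  "across_dataset"),
                       datasets = NULL, k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(participants)
  folds <- list()
  if (scheme == "across_participant") {
    if (n < k) stop("need at least k = ", k, " participants")
    set.seed(seed)
    perm <- sample(participants)
    # assign contiguous chunks of the shuffled order to partitions
    sizes <- rep(n %/% k, k)
    if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    assign <- rep(seq_len(k), times = sizes)
    for (i in seq_len(k)) {
      test_ids <- perm[assign == i]
      train_ids <- setdiff(perm, test_ids)
      folds[[i]] <- list(
        train = data.frame(participant = train_ids, part = "all",
                           stringsAsFactors = FALSE),
        test = data.frame(participant = test_ids, part = "all",
                          stringsAsFactors = FALSE))
    }
  } else if (scheme == "within_participant") {
    halves <- c("first", "second")
    for (i in 1:2) {
      folds[[i]] <- list(
        train = data.frame(participant = participants, part = halves[i],
                           stringsAsFactors = FALSE),
        test = data.frame(participant = participants, part = halves[3 - i],
                          stringsAsFactors = FALSE))
    }
  } else {
    if (is.null(datasets) || length(datasets) != n)
      stop("across_dataset needs one dataset id per participant")
    uds <- unique(datasets)
    if (length(uds) < 2L) stop("across_dataset needs >= 2 datasets")
    for (i in seq_along(uds)) {
      test_ids <- participants[datasets == uds[i]]
      train_ids <- participants[datasets != uds[i]]
      folds[[i]] <- list(
        train = data.frame(participant = train_ids, part = "all",
                           stringsAsFactors = FALSE),
        test = data.frame(participant = test_ids, part = "all",
                          stringsAsFactors = FALSE),
        held_out_dataset = uds[i])
    }
  }
  plan <- structure(list(scheme = scheme, folds = folds,
                         participants = participants),
                    class = "fold_plan")
  validate_fold_plan(plan)
  plan
}

validate_fold_plan <- function(plan) {
  tested <- unlist(lapply(plan$folds, function(f) unique(f$test$participant)))
  if (plan$scheme == "within_participant") {
    # every participant tested exactly once per half; overall twice
    if (!all(table(tested) == 2L))
      stop("within-participant plan must test every participant in both folds")
  } else if (!setequal(tested, plan$participants) ||
             any(table(tested) != 1L)) {
    stop("fold plan must test every participant exactly once")
  }
  for (f in plan$folds) {
    overlap <- merge(f$train, f$test, by = c("participant", "part"))
    if (nrow(overlap))
      stop("train/test overlap within a fold")
  }
  invisible(plan)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("%s fold plan: %d fold(s), %d participants\n", x$scheme,
              length(x$folds), length(x$participants)))
  for (i in seq_along(x$folds))
    cat(sprintf("  fold %d: %d train / %d test\n", i,
                nrow(x$folds[[i]]$train), nrow(x$folds[[i]]$test)))
  invisible(x)
}

#' Epoch rule for small training sets
#'
#' `e = 2 + N` epochs for a training set of `N` participants; used to avoid
#' overfitting when subsampling the training set.
#'
#' @param N number of training participants (>= 1).
#' @return integer epoch count.
#' @export
epochs_for <- function(N) {
  if (N < 1) stop("N must be >= 1")
  as.integer(2L + N)
}

#' Training schedule
#'
#' @param epochs epoch count; `NULL` applies the small-set rule
#'   [epochs_for()] to the training pool size at fit time.
#' @param steps_per_epoch gradient steps per epoch (default 1,500; an epoch
#'   then passes `steps_per_epoch * batch_size` samples through the network).
#' @param batch_size samples per gradient step (default 8).
#' @param learning_rate Adam learning rate; `NULL` uses the model config's.
#' @param seed RNG seed covering batch mixing, augmentation and dropout.
#' @return an object of class `training_schedule`.
#' @export
training_schedule <- function(epochs = NULL, steps_per_epoch = 1500L,
                              batch_size = 8L, learning_rate = NULL,
                              seed = 1L) {
  structure(list(epochs = epochs,
                 steps_per_epoch = as.integer(steps_per_epoch),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "training_schedule")
}

#' Augmentation configuration
#'
#' Random affine input augmentations — intensity-preserving spatial scaling,
#' per-axis translations and 3D rotations (azimuth, pitch, roll) — applied to
#' each training sample. Ranges are symmetric about the identity. Gaze labels
#' are left unchanged: the transforms emulate residual co-registration error,
#' under which the true gaze is unaltered.
#'
#' @param scale_range multiplicative spatial scale range, e.g. `c(0.9, 1.1)`.
#' @param translation_range max |translation| in voxels per axis.
#' @param rotation_range_deg max |rotation| per axis in degrees
#'   (azimuth, pitch, roll).
#' @param prob per-sample application probability.
#' @return an object of class `augmentation_config`.
#' @export
augmentation_config <- function(scale_range = c(0.9, 1.1),
                                translation_range = 2,
                                rotation_range_deg = c(10, 10, 10),
                                prob = 1) {
  if (abs(log(scale_range[1]) + log(scale_range[2])) > 1e-6 &&
      abs(scale_range[1] + scale_range[2] - 2) > 1e-6)
    stop("scale_range must be symmetric about 1")
  structure(list(scale_range = scale_range,
                 translation_range = translation_range,
                 rotation_range_deg = rep(rotation_range_deg, length.out = 3),
                 prob = prob),
            class = "augmentation_config")
}

rotation_matrix <- function(az, pitch, roll) {
  cz <- cos(az); sz <- sin(az)
  cy <- cos(pitch); sy <- sin(pitch)
  cx <- cos(roll); sx <- sin(roll)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

trilinear_sample <- function(vol, coords) {
  d <- dim(vol)
  f <- floor(coords)
  w <- coords - f
  out <- numeric(nrow(coords))
  for (k in 0:7) {
    ox <- k %% 2; oy <- (k %/% 2) %% 2; oz <- k %/% 4
    cx <- f[, 1] + ox; cy <- f[, 2] + oy; cz <- f[, 3] + oz
    wt <- (if (ox) w[, 1] else 1 - w[, 1]) *
          (if (oy) w[, 2] else 1 - w[, 2]) *
          (if (oz) w[, 3] else 1 - w[, 3])
    ok <- cx >= 1 & cx <= d[1] & cy >= 1 & cy <= d[2] & cz >= 1 & cz <= d[3] &
          wt > 0
    if (any(ok)) {
      lin <- (cz[ok] - 1) * d[1] * d[2] + (cy[ok] - 1) * d[1] + cx[ok]
      out[ok] <- out[ok] + wt[ok] * vol[lin]
    }
  }
  out
}

#' Apply a random affine augmentation to one volume
#'
#' @param volume 3D array (or V-vector with a `dims` attribute).
#' @param cfg an [augmentation_config()]; all-zero ranges give the identity.
#' @param dims volume dimensions if `volume` is a flat vector.
#' @return augmented volume, same shape as the input.
#' @export
augment <- function(volume, cfg = augmentation_config(), dims = NULL) {
  flat <- is.null(dim(volume)) || length(dim(volume)) == 1L
  if (flat) volume <- array(volume, dims)
  d <- dim(volume)
  if (cfg$prob < 1 && stats::runif(1) >= cfg$prob)
    return(if (flat) as.vector(volume) else volume)
  s <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
  tr <- stats::runif(3, -cfg$translation_range, cfg$translation_range)
  ang <- stats::runif(3, -cfg$rotation_range_deg, cfg$rotation_range_deg) *
    pi / 180
  if (s == 1 && all(tr == 0) && all(ang == 0))
    return(if (flat) as.vector(volume) else volume)
  Rm <- rotation_matrix(ang[1], ang[2], ang[3])
  ctr <- (d + 1) / 2
  p <- arrayInd(seq_len(prod(d)), d)
  src <- sweep(p, 2, ctr + tr) %*% Rm / s
  src <- sweep(src, 2, ctr, "+")
  out <- array(trilinear_sample(volume, src), d)
  if (flat) as.vector(out) else out
}

#' Draw mixed training batches
#'
#' Returns the (participant, TR) index pairs for `n_steps` batches. Whenever
#' the pool has more than one participant, every batch mixes samples from at
#' least two of them.
#'
#' @param pool a training pool (see [training_pool()]).
#' @param n_steps number of batches.
#' @param batch_size samples per batch.
#' @param seed shuffle seed.
#' @return list of `n_steps` matrices `batch_size x 2` (participant, TR).
#' @export
make_batches <- function(pool, n_steps, batch_size = 8L, seed = 1L) {
  np <- length(pool)
  if (!np) stop("empty training pool")
  set.seed(seed)
  lapply(seq_len(n_steps), function(s) {
    ps <- sample.int(np, batch_size, replace = TRUE)
    if (np >= 2L && length(unique(ps)) == 1L)
      ps[1] <- sample(setdiff(seq_len(np), ps[1]), 1L)
    trs <- vapply(ps, function(p) sample.int(ncol(pool[[p]]$x), 1L), 1L)
    cbind(participant = ps, tr = trs)
  })
}

#' Assemble a training pool
#'
#' Pairs normalized volume series with their gaze (or closure) labels in the
#' flat form the optimizer consumes.
#'
#' @param series_list list of normalized [volume_series()].
#' @param labels_list list of matching [gaze_labels()].
#' @param target `"gaze"` (sub-TR coordinate targets) or `"closure"`
#'   (per-TR closed fraction).
#' @return list of per-participant entries with fields `x`
#'   (voxels x TR matrix), `targets`, `id`, `n_tr`.
#' @export
training_pool <- function(series_list, labels_list,
                          target = c("gaze", "closure")) {
  target <- match.arg(target)
  stopifnot(length(series_list) == length(labels_list))
  lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    l <- labels_list[[i]]
    d <- dim(s$data)
    n_tr <- d[4]
    if (dim(l$coords)[1] != n_tr)
      stop("series and labels disagree on TR count for participant ", i)
    x <- matrix(s$data, prod(d[1:3]), n_tr)
    if (target == "gaze") {
      targets <- aperm(l$coords, c(2, 3, 1))   # n_sub x 2 x n_tr
    } else {
      if (is.null(l$closed))
        stop("closure target requested but labels carry no closure series")
      targets <- l$closed
    }
    list(x = x, targets = targets, id = s$participant_id, n_tr = n_tr,
         labels = l)
  })
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a decoder network
#'
#' Adam optimization of the combined loss over seeded mixed batches, with
#' optional per-sample affine augmentation.
#'
#' @param net a [build_network()] result.
#' @param pool a [training_pool()].
#' @param schedule a [training_schedule()].
#' @param augmentation an [augmentation_config()] or `NULL`.
#' @param verbose print per-epoch losses.
#' @return list with `net` (trained), `history` (data.frame epoch, l, l_ed,
#'   l_mse, samples), `samples_per_epoch`.
#' @export
train_network <- function(net, pool, schedule = training_schedule(),
                          augmentation = NULL, verbose = FALSE) {
  if (!length(pool)) stop("training pool is empty")
  cfg <- net$cfg
  epochs <- schedule$epochs
  if (is.null(epochs)) epochs <- epochs_for(length(pool))
  lr <- schedule$learning_rate
  if (is.null(lr)) lr <- cfg$learning_rate
  state <- adam_init(net$params)
  history <- data.frame()
  set.seed(schedule$seed)
  dims <- cfg$input_dims
  for (e in seq_len(epochs)) {
    batches <- make_batches(pool, schedule$steps_per_epoch,
                            schedule$batch_size,
                            seed = schedule$seed + e)
    acc <- c(l = 0, l_ed = 0, l_mse = 0)
    for (b in batches) {
      N <- nrow(b)
      X <- matrix(0, prod(dims), N)
      if (cfg$target == "gaze") {
        targets <- array(0, c(cfg$n_sub, 2L, N))
      } else targets <- numeric(N)
      for (j in seq_len(N)) {
        xv <- pool[[b[j, 1]]]$x[, b[j, 2]]
        if (!is.null(augmentation))
          xv <- augment(xv, augmentation, dims = dims)
        X[, j] <- xv
        if (cfg$target == "gaze")
          targets[, , j] <- pool[[b[j, 1]]]$targets[, , b[j, 2]]
        else targets[j] <- pool[[b[j, 1]]]$targets[b[j, 2]]
      }
      res <- net_loss_grad(net, X, targets, training = TRUE)
      if (!is.finite(res$loss$l))
        stop(sprintf("non-finite loss at epoch %d: l_ed=%g l_mse=%g",
                     e, res$loss$l_ed, res$loss$l_mse))
      upd <- adam_step(net$params, res$grads, state, lr)
      net$params <- upd$params
      state <- upd$state
      acc <- acc + c(res$loss$l, res$loss$l_ed, res$loss$l_mse)
    }
    acc <- acc / length(batches)
    history <- rbind(history, data.frame(
      epoch = e, l = acc[1], l_ed = acc[2], l_mse = acc[3],
      samples = schedule$steps_per_epoch * schedule$batch_size))
    if (verbose)
      message(sprintf("epoch %d/%d: l=%.4f l_ed=%.4f l_mse=%.4f",
                      e, epochs, acc[1], acc[2], acc[3]))
  }
  rownames(history) <- NULL
  list(net = net, history = history,
       samples_per_epoch = schedule$steps_per_epoch * schedule$batch_size)
}

#' Subsample a training pool
#'
#' Reduces the pool to `n_participants` randomly drawn participants and, within
#' each, a contiguous fraction of TRs (emulating shorter acquisitions).
#'
#' @param pool a [training_pool()].
#' @param n_participants participants to keep.
#' @param fraction_per_participant fraction of each participant's TRs, (0, 1].
#' @param seed draw seed.
#' @return the reduced pool.
#' @export
subsample_training <- function(pool, n_participants = length(pool),
                               fraction_per_participant = 1, seed = 1L) {
  if (n_participants > length(pool)) stop("n_participants exceeds pool size")
  if (fraction_per_participant <= 0 || fraction_per_participant > 1)
    stop("fraction_per_participant must be in (0, 1]")
  set.seed(seed)
  keep <- sort(sample.int(length(pool), n_participants))
  out <- lapply(pool[keep], function(p) {
    n_keep <- max(1L, round(p$n_tr * fraction_per_participant))
    if (n_keep < p$n_tr) {
      start <- sample.int(p$n_tr - n_keep + 1L, 1L)
      idx <- start:(start + n_keep - 1L)
      p$x <- p$x[, idx, drop = FALSE]
      if (is.array(p$targets) && length(dim(p$targets)) == 3L)
        p$targets <- p$targets[, , idx, drop = FALSE]
      else p$targets <- p$targets[idx]
      p$n_tr <- n_keep
    }
    p
  })
  if (!length(out)) stop("subsampling produced an empty pool")
  out
}

#' Shift gaze labels relative to the imaging series
#'
#' Pairs volume `t` with label `t - shift_tr`; overhanging TRs are dropped so
#' the pairing respects the run boundary. Used to test whether decoding is
#' instantaneous or improves at a hemodynamic delay.
#'
#' @param series a [volume_series()].
#' @param labels a matching [gaze_labels()].
#' @param shift_tr nonnegative integer shift in TRs (< run length).
#' @return list with shifted `series` and `labels` of equal length.
#' @export
time_shift <- function(series, labels, shift_tr) {
  n_tr <- dim(series$data)[4]
  shift_tr <- as.integer(shift_tr)
  if (shift_tr < 0L) stop("shift_tr must be >= 0")
  if (shift_tr >= n_tr)
    stop("shift_tr must be smaller than the run length (", n_tr, " TRs)")
  if (shift_tr == 0L) return(list(series = series, labels = labels))
  vol_idx <- (1L + shift_tr):n_tr
  lab_idx <- 1L:(n_tr - shift_tr)
  series$data <- series$data[, , , vol_idx, drop = FALSE]
  labels$coords <- labels$coords[lab_idx, , , drop = FALSE]
  if (!is.null(labels$closed)) labels$closed <- labels$closed[lab_idx]
  list(series = series, labels = labels)
}

#' Export a fold plan as JSON / a training history as TSV
#'
#' @param plan a [make_folds()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(list(scheme = plan$scheme, folds = plan$folds),
                       path, auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_fold_plan
#' @param history the `history` data.frame from [train_network()].
#' @export
write_history <- function(history, path) {
  utils::write.table(history, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
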
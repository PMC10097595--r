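#' Phantom configuration
#'
#' Parameters of the synthetic eyeball phantom: a pair of spherical "eyeballs"
#' whose voxel pattern is a deterministic function of on-screen gaze. Each
#' eyeball is a sphere of baseline intensity carrying a gaze-oriented
#' hypointense lobe: the intensity deficit at a voxel is proportional to the
#' (clipped) cosine similarity between the voxel's direction from the eyeball
#' centre and the current gaze vector. Both eyes move conjugately.
#'
#' @param grid_dims integer(3), voxel counts per axis (anterior-posterior,
#'   left-right, inferior-superior). All dims must be even and >= 8; the
#'   left-right axis holds both eyes.
#' @param eyeball_radius sphere radius in voxels.
#' @param lobe_contrast dimensionless intensity of the gaze-oriented dark lobe.
#' @param gaze_gain degrees of eyeball rotation per degree of on-screen gaze.
#'   The default 2 maps paper-scale screen windows onto a rotation range wide
#'   enough that the coarse phantom grid resolves neighbouring gaze targets.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param participant_gain_range,offset_range ranges of the per-participant
#'   multiplicative gain and additive offset.
#' @param n_sub number of sub-TR gaze positions averaged into each volume.
#' @param lid_intensity intensity of the anterior eyelid band added in
#'   proportion to the eyes-closed fraction.
#' @param subtr_weights optional numeric(n_sub) of nonnegative blur weights for
#'   the within-TR average (normalised internally). `NULL` means the uniform
#'   arithmetic mean. An increasing profile emulates the acquisition-order
#'   asymmetry (slice timing) that makes within-TR gaze order identifiable.
#' @param seed integer seed used by generators that draw participants.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_dims = c(16L, 32L, 16L),
                           eyeball_radius = 5,
                           lobe_contrast = 0.7,
                           gaze_gain = 2,
                           noise_sd = 0.05,
                           participant_gain_range = c(0.9, 1.1),
                           offset_range = c(-0.1, 0.1),
                           n_sub = 10L,
                           lid_intensity = 0.8,
                           subtr_weights = NULL,
                           seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L)
  if (any(grid_dims < 8L) || any(grid_dims %% 2L != 0L))
    stop("grid_dims must all be >= 8 and even")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_sub <- as.integer(n_sub)
  if (n_sub < 1L) stop("n_sub must be >= 1")
  if (lobe_contrast < 0) stop("lobe_contrast must be >= 0")
  if (gaze_gain <= 0) stop("gaze_gain must be > 0")
  if (!is.null(subtr_weights)) {
    if (length(subtr_weights) != n_sub || any(subtr_weights < 0) ||
        sum(subtr_weights) <= 0)
      stop("subtr_weights must be ", n_sub, " nonnegative weights")
    subtr_weights <- subtr_weights / sum(subtr_weights)
  }
  cfg <- structure(list(
    grid_dims = grid_dims,
    eyeball_radius = eyeball_radius,
    lobe_contrast = lobe_contrast,
    gaze_gain = gaze_gain,
    noise_sd = noise_sd,
    participant_gain_range = participant_gain_range,
    offset_range = offset_range,
    n_sub = n_sub,
    lid_intensity = lid_intensity,
    subtr_weights = subtr_weights,
    seed = as.integer(seed)
  ), class = "phantom_config")
  # two eyeballs must fit inside the grid without overlap
  geo <- phantom_geometry(cfg)
  sep <- abs(geo$centers[1, 2] - geo$centers[2, 2])
  if (sep <= 2 * eyeball_radius)
    stop("eyeballs overlap: reduce eyeball_radius or enlarge grid_dims[2]")
  if (eyeball_radius >= grid_dims[1] / 2 || eyeball_radius >= grid_dims[3] / 2)
    stop("eyeball does not fit inside the grid")
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("Eyeball phantom configuration\n")
  cat(sprintf("  grid: %s voxels, eyeball radius %.1f\n",
              paste(x$grid_dims, collapse = "x"), x$eyeball_radius))
  cat(sprintf("  lobe contrast %.2f, gaze gain %.1f deg/deg, noise sd %.3f\n",
              x$lobe_contrast, x$gaze_gain, x$noise_sd))
  cat(sprintf("  %d sub-TR positions per volume (%s blur weights)\n", x$n_sub,
              if (is.null(x$subtr_weights)) "uniform" else "custom"))
  invisible(x)
}

# Eyeball centres (1-based voxel-centre coordinates) and per-voxel geometry.
# The mid-sagittal plane lies at grid_dims[2]/2 + 0.5, halfway between the two
# eyes, so the phantom is mirror-symmetric by construction.
phantom_geometry <- function(cfg) {
  d <- cfg$grid_dims
  cx <- (d[1] + 1) / 2
  cz <- (d[3] + 1) / 2
  sep <- d[2] / 4
  centers <- rbind(c(cx, d[2] / 2 + 0.5 - sep, cz),
                   c(cx, d[2] / 2 + 0.5 + sep, cz))
  list(centers = centers, anterior = c(1, 0, 0))
}

# Per-eye static index/direction tables, computed once per config.
phantom_tables <- function(cfg) {
  d <- cfg$grid_dims
  geo <- phantom_geometry(cfg)
  coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                  z = seq_len(d[3])))
  r <- cfg$eyeball_radius
  eyes <- lapply(1:2, function(e) {
    rel <- sweep(coords, 2, geo$centers[e, ])
    dist <- sqrt(rowSums(rel^2))
    inside <- which(dist <= r)
    dirs <- rel[inside, , drop = FALSE] / pmax(dist[inside], 1e-9)
    # anterior eyelid band: a shell just outside the sphere on the anterior side
    band <- which(dist > r & dist <= r + 1.5 & rel[, 1] < -0.5 * r)
    list(inside = inside, dirs = dirs, band = band)
  })
  list(eyes = eyes, dims = d)
}

# Unit gaze direction in grid space for an on-screen position (degrees).
# Azimuth (about the superior axis) follows horizontal gaze, elevation follows
# vertical gaze; the anterior axis is -x so the lobe faces the "screen".
gaze_direction <- function(gaze_xy, cfg) {
  a <- cfg$gaze_gain * gaze_xy[1] * pi / 180
  e <- cfg$gaze_gain * gaze_xy[2] * pi / 180
  c(-cos(e) * cos(a), cos(e) * sin(a), sin(e))
}

check_gaze_range <- function(gaze_xy, cfg) {
  lim <- 90 / cfg$gaze_gain
  if (any(abs(gaze_xy) > lim + 1e-9))
    stop(sprintf(
      "gaze (%.2f, %.2f) deg exceeds the representable rotation range of +/-%.2f deg",
      gaze_xy[1], gaze_xy[2], lim))
}

#' Render one phantom volume for a single gaze position
#'
#' @param gaze_xy numeric(2) on-screen gaze in visual degrees (x right, y up).
#' @param participant a [phantom_participant()].
#' @param cfg a [phantom_config()].
#' @param closure eyes-closed fraction in `[0, 1]` for this volume. Scales the
#'   gaze lobe by `1 - closure` and adds an anterior eyelid band.
#' @param tables precomputed [phantom_tables()] (internal reuse).
#' @return 3D numeric array of `cfg$grid_dims`. Gaussian noise of sd
#'   `cfg$noise_sd` is drawn from the current RNG state; seed the caller for
#'   reproducibility.
#' @export
render_volume <- function(gaze_xy, participant = phantom_participant("p1"),
                          cfg = phantom_config(), closure = 0,
                          tables = NULL) {
  check_gaze_range(gaze_xy, cfg)
  vol <- render_noiseless(gaze_xy, participant, cfg, closure, tables)
  if (cfg$noise_sd > 0)
    vol <- vol + array(stats::rnorm(length(vol), sd = cfg$noise_sd), dim(vol))
  vol
}

render_noiseless <- function(gaze_xy, participant, cfg, closure = 0,
                             tables = NULL) {
  if (is.null(tables)) tables <- phantom_tables(cfg)
  vol <- array(0, cfg$grid_dims)
  g <- gaze_direction(gaze_xy, cfg)
  for (eye in tables$eyes) {
    cosim <- pmax(0, drop(eye$dirs %*% g))
    vol[eye$inside] <- 1 - (1 - closure) * cfg$lobe_contrast * cosim
    if (closure > 0)
      vol[eye$band] <- vol[eye$band] + closure * cfg$lid_intensity
  }
  vol <- participant$gain * vol + participant$offset
  if (any(participant$misalignment != 0L))
    vol <- shift_volume(vol, participant$misalignment)
  vol
}

#' Integer-voxel translation of a volume with zero fill
#' @param vol 3D array.
#' @param shift integer(3) translation in voxels.
#' @return shifted array of the same dimensions.
#' @export
shift_volume <- function(vol, shift) {
  shift <- as.integer(round(shift))
  if (all(shift == 0L)) return(vol)
  d <- dim(vol)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    if (s >= 0) { dst[[k]] <- (1 + s):d[k]; src[[k]] <- 1:(d[k] - s) }
    else       { dst[[k]] <- 1:(d[k] + s); src[[k]] <- (1 - s):d[k] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Phantom participant
#'
#' @param id participant identifier.
#' @param gain multiplicative intensity scalar (> 0).
#' @param offset additive intensity scalar.
#' @param misalignment integer(3) voxel translation applied to every volume
#'   (0 for clean participants); emulates residual co-registration error.
#' @param closure_series optional per-TR eyes-closed fraction in `[0, 1]`.
#' @return an object of class `phantom_participant`.
#' @export
phantom_participant <- function(id, gain = 1, offset = 0,
                                misalignment = c(0L, 0L, 0L),
                                closure_series = NULL) {
  if (gain <= 0) stop("gain must be > 0")
  misalignment <- as.integer(round(misalignment))
  stopifnot(length(misalignment) == 3L)
  if (!is.null(closure_series) &&
      (any(closure_series < 0) || any(closure_series > 1)))
    stop("closure_series must lie in [0, 1]")
  structure(list(id = id, gain = gain, offset = offset,
                 misalignment = misalignment,
                 closure_series = closure_series),
            class = "phantom_participant")
}

#' Screen sampling window
#'
#' Full sampling extent of gaze positions in visual degrees, centred at (0,0).
#' Its diagonal `sqrt(x_range^2 + y_range^2)` is the stimulus size used by the
#' fraction-of-stimulus-size (FoS) metric.
#'
#' @param x_range_deg,y_range_deg full extent (not half-width) in degrees.
#' @return an object of class `screen_window`.
#' @export
screen_window <- function(x_range_deg, y_range_deg = x_range_deg) {
  if (x_range_deg <= 0 || y_range_deg <= 0)
    stop("window ranges must be > 0")
  structure(list(x_range_deg = x_range_deg, y_range_deg = y_range_deg),
            class = "screen_window")
}

window_diag <- function(window) {
  sqrt(window$x_range_deg^2 + window$y_range_deg^2)
}

#' Trajectory specification
#'
#' Describes the viewing task a phantom participant performs. Three task
#' families mirror common fMRI eye-tracking designs: a fixation grid (a target
#' stepping through screen locations), a smooth-pursuit walk (piecewise-linear
#' target motion at fixed speed), and free viewing (a saccadic jump process
#' with within-fixation jitter).
#'
#' @param kind one of `"fixation_grid"`, `"pursuit_walk"`, `"free_view"`.
#' @param window a [screen_window()].
#' @param tr_s repetition time in seconds.
#' @param n_tr number of volumes.
#' @param n_points (fixation_grid) number of grid locations.
#' @param dwell_trs (fixation_grid) TRs spent at each location.
#' @param n_repeats (fixation_grid) times each location is visited.
#' @param speed_dps (pursuit_walk) target speed, degrees per second.
#' @param turn_every_trs (pursuit_walk) TRs between direction changes.
#' @param jump_rate_hz (free_view) expected saccade rate.
#' @param jitter_sd_deg (free_view) within-fixation positional jitter sd.
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(kind = c("fixation_grid", "pursuit_walk", "free_view"),
                            window = screen_window(10, 10),
                            tr_s = 1, n_tr = 100L,
                            n_points = 9L, dwell_trs = 4L, n_repeats = 2L,
                            speed_dps = 5, turn_every_trs = 2L,
                            jump_rate_hz = 3, jitter_sd_deg = 0.2) {
  kind <- match.arg(kind)
  n_tr <- as.integer(n_tr)
  if (n_tr < 1L) stop("n_tr must be >= 1")
  if (tr_s <= 0) stop("tr_s must be > 0")
  structure(list(kind = kind, window = window, tr_s = tr_s, n_tr = n_tr,
                 n_points = as.integer(n_points),
                 dwell_trs = as.integer(dwell_trs),
                 n_repeats = as.integer(n_repeats),
                 speed_dps = speed_dps,
                 turn_every_trs = as.integer(turn_every_trs),
                 jump_rate_hz = jump_rate_hz,
                 jitter_sd_deg = jitter_sd_deg),
            class = "trajectory_spec")
}

# Near-square grid of n points spanning the central 80% of the window.
grid_points <- function(n, window) {
  ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  xs <- seq(-0.4, 0.4, length.out = ncol) * window$x_range_deg
  ys <- seq(-0.4, 0.4, length.out = nrow) * window$y_range_deg
  pts <- as.matrix(expand.grid(x = xs, y = ys))[seq_len(n), , drop = FALSE]
  unname(pts)
}

#' Simulate a sub-TR gaze trajectory
#'
#' @param spec a [trajectory_spec()].
#' @param seed integer seed; the same seed reproduces the same path.
#' @return array `n_tr x n_sub x 2` of gaze coordinates in degrees, with
#'   attribute `"segments"` (per-sub-sample segment id) for fixation grids.
#' @param n_sub sub-TR positions per volume.
#' @export
simulate_trajectory <- function(spec, n_sub = 10L, seed = 1L) {
  if (!inherits(spec, "trajectory_spec")) stop("spec must be a trajectory_spec")
  n_sub <- as.integer(n_sub)
  half_x <- spec$window$x_range_deg / 2
  half_y <- spec$window$y_range_deg / 2
  n_steps <- spec$n_tr * n_sub
  path <- matrix(0, n_steps, 2)
  segments <- NULL
  if (spec$kind == "fixation_grid") {
    pts <- grid_points(spec$n_points, spec$window)
    set.seed(seed)
    order_idx <- as.vector(replicate(spec$n_repeats, sample.int(nrow(pts))))
    seg_len <- spec$dwell_trs * n_sub
    seg_of_step <- ((seq_len(n_steps) - 1) %/% seg_len) %% length(order_idx) + 1
    path <- pts[order_idx[seg_of_step], , drop = FALSE]
    segments <- seg_of_step
  } else if (spec$kind == "pursuit_walk") {
    set.seed(seed)
    step_len <- spec$speed_dps * spec$tr_s / n_sub
    pos <- c(0, 0)
    theta <- stats::runif(1, 0, 2 * pi)
    dir <- c(cos(theta), sin(theta))
    turn_steps <- spec$turn_every_trs * n_sub
    for (i in seq_len(n_steps)) {
      if (i > 1 && (i - 1) %% turn_steps == 0) {
        theta <- stats::runif(1, 0, 2 * pi)
        dir <- c(cos(theta), sin(theta))
      }
      nxt <- pos + dir * step_len
      # reflect at window bounds, preserving step magnitude
      if (nxt[1] > half_x || nxt[1] < -half_x) dir[1] <- -dir[1]
      if (nxt[2] > half_y || nxt[2] < -half_y) dir[2] <- -dir[2]
      pos <- pos + dir * step_len
      pos[1] <- min(max(pos[1], -half_x), half_x)
      pos[2] <- min(max(pos[2], -half_y), half_y)
      path[i, ] <- pos
    }
  } else if (spec$kind == "free_view") {
    set.seed(seed)
    p_jump <- min(1, spec$jump_rate_hz * spec$tr_s / n_sub)
    pos <- c(stats::runif(1, -half_x, half_x), stats::runif(1, -half_y, half_y))
    for (i in seq_len(n_steps)) {
      if (stats::runif(1) < p_jump) {
        pos <- c(stats::runif(1, -half_x, half_x),
                 stats::runif(1, -half_y, half_y))
      } else {
        pos <- pos + stats::rnorm(2, sd = spec$jitter_sd_deg)
        pos[1] <- min(max(pos[1], -half_x), half_x)
        pos[2] <- min(max(pos[2], -half_y), half_y)
      }
      path[i, ] <- pos
    }
  } else stop("unknown trajectory kind: ", spec$kind)
  out <- array(0, c(spec$n_tr, n_sub, 2))
  out[, , 1] <- matrix(path[, 1], spec$n_tr, n_sub, byrow = TRUE)
  out[, , 2] <- matrix(path[, 2], spec$n_tr, n_sub, byrow = TRUE)
  attr(out, "segments") <- segments
  out
}

#' Gaze labels container
#'
#' Per-TR ordered lists of `n_sub` on-screen gaze coordinates (visual degrees)
#' plus an optional per-TR eyes-closed fraction.
#'
#' @param coords array `n_tr x n_sub x 2`.
#' @param window a [screen_window()].
#' @param tr_s repetition time in seconds.
#' @param closed optional numeric(n_tr) closed fraction in `[0, 1]`.
#' @return an object of class `gaze_labels`.
#' @export
gaze_labels <- function(coords, window, tr_s = 1, closed = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 2L)
  if (any(!is.finite(coords))) stop("gaze coordinates must be finite")
  if (!is.null(closed)) {
    stopifnot(length(closed) == dim(coords)[1])
    if (any(closed < 0 | closed > 1)) stop("closed_fraction must lie in [0, 1]")
  }
  structure(list(coords = coords, window = window, tr_s = tr_s,
                 closed = closed, n_sub = dim(coords)[2]),
            class = "gaze_labels")
}

#' @export
print.gaze_labels <- function(x, ...) {
  cat(sprintf("Gaze labels: %d TRs x %d sub-TR samples, window %gx%g deg%s\n",
              dim(x$coords)[1], x$n_sub, x$window$x_range_deg,
              x$window$y_range_deg,
              if (is.null(x$closed)) "" else ", with closure series"))
  invisible(x)
}

#' Generate one phantom participant's volumes and labels
#'
#' Each per-TR volume is the (optionally weighted) average of noiseless renders
#' at that TR's `n_sub` sub-positions — a motion-blur model — plus one draw of
#' Gaussian acquisition noise per volume. Misalignment is applied as an integer
#' translation of every volume.
#'
#' @param spec a [trajectory_spec()].
#' @param participant a [phantom_participant()].
#' @param cfg a [phantom_config()].
#' @param seed integer seed (trajectory and noise).
#' @return list with `volumes` (4D array, grid dims x n_tr) and `labels`
#'   (a [gaze_labels()]).
#' @export
generate_participant <- function(spec, participant, cfg = phantom_config(),
                                 seed = 1L) {
  traj <- simulate_trajectory(spec, n_sub = cfg$n_sub, seed = seed)
  n_tr <- spec$n_tr
  tables <- phantom_tables(cfg)
  w <- cfg$subtr_weights
  if (is.null(w)) w <- rep(1 / cfg$n_sub, cfg$n_sub)
  closed <- participant$closure_series
  if (!is.null(closed) && length(closed) != n_tr)
    stop("closure_series length must equal n_tr")
  vols <- array(0, c(cfg$grid_dims, n_tr))
  set.seed(seed + 1L)
  unshifted <- phantom_participant(participant$id, participant$gain,
                                   participant$offset)
  for (t in seq_len(n_tr)) {
    cl <- if (is.null(closed)) 0 else closed[t]
    acc <- array(0, cfg$grid_dims)
    for (k in seq_len(cfg$n_sub)) {
      acc <- acc + w[k] * render_noiseless(traj[t, k, ], unshifted, cfg,
                                           closure = cl, tables = tables)
    }
    if (cfg$noise_sd > 0)
      acc <- acc + array(stats::rnorm(length(acc), sd = cfg$noise_sd),
                         dim(acc))
    if (any(participant$misalignment != 0L))
      acc <- shift_volume(acc, participant$misalignment)
    vols[, , , t] <- acc
  }
  window <- spec$window
  labels <- gaze_labels(traj, window, tr_s = spec$tr_s, closed = closed)
  list(volumes = vols, labels = labels, participant = participant)
}

#' Generate a phantom dataset of several participants
#'
#' Per-participant gains and offsets are drawn from the configured ranges;
#' participants listed in `outlier_ids` receive a nonzero mask misalignment.
#'
#' @param n_participants number of participants (>= 1).
#' @param spec a [trajectory_spec()].
#' @param cfg a [phantom_config()].
#' @param outlier_ids integer indices of misaligned participants.
#' @param misalignments integer matrix (length(outlier_ids) x 3) or single
#'   integer(3) recycled; default a 3-voxel anterior shift.
#' @param closure_series optional per-TR closure fractions shared by all
#'   participants, or a list per participant.
#' @param seed integer seed; everything is deterministic given (seed, cfg).
#' @return list of per-participant results as in [generate_participant()].
#' @export
generate_dataset <- function(n_participants, spec, cfg = phantom_config(),
                             outlier_ids = integer(0),
                             misalignments = c(0L, 3L, 0L),
                             closure_series = NULL,
                             seed = cfg$seed) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  outlier_ids <- as.integer(outlier_ids)
  if (length(outlier_ids) && (any(outlier_ids < 1) ||
                              any(outlier_ids > n_participants)))
    stop("outlier_ids must be a subset of 1..n_participants")
  if (is.matrix(misalignments)) {
    if (nrow(misalignments) != length(outlier_ids))
      stop("misalignments must have one row per outlier id")
  } else {
    misalignments <- matrix(rep(as.integer(misalignments),
                                length.out = 3 * max(1L, length(outlier_ids))),
                            ncol = 3, byrow = TRUE)
  }
  if (length(outlier_ids) &&
      any(sweep(abs(misalignments), 2, cfg$grid_dims / 4, ">")))
    stop("misalignment exceeds grid_dims/4")
  set.seed(seed)
  gains <- stats::runif(n_participants, cfg$participant_gain_range[1],
                        cfg$participant_gain_range[2])
  offsets <- stats::runif(n_participants, cfg$offset_range[1],
                          cfg$offset_range[2])
  pseeds <- sample.int(1e6, n_participants)
  lapply(seq_len(n_participants), function(i) {
    mis <- c(0L, 0L, 0L)
    oi <- match(i, outlier_ids)
    if (!is.na(oi)) mis <- misalignments[oi, ]
    cl <- if (is.list(closure_series)) closure_series[[i]] else closure_series
    p <- phantom_participant(paste0("sub-", sprintf("%02d", i)),
                             gain = gains[i], offset = offsets[i],
                             misalignment = mis, closure_series = cl)
    generate_participant(spec, p, cfg, seed = pseeds[i])
  })
}

#' Phantom eye mask
#'
#' Boolean mask of the two eyeball spheres plus a small shell (the anterior
#' eyelid band), analogous to a manually delineated eye mask.
#'
#' @param cfg a [phantom_config()].
#' @return an [eye_mask()] on the phantom grid.
#' @export
phantom_mask <- function(cfg = phantom_config()) {
  d <- cfg$grid_dims
  geo <- phantom_geometry(cfg)
  coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                  z = seq_len(d[3])))
  m <- rep(FALSE, nrow(coords))
  for (e in 1:2) {
    rel <- sweep(coords, 2, geo$centers[e, ])
    m <- m | sqrt(rowSums(rel^2)) <= cfg$eyeball_radius + 1.5
  }
  eye_mask(array(m, d), voxel_size_mm = c(2, 2, 2))
}

#' Logical array marking voxels inside the eyeball spheres
#' @param cfg a [phantom_config()].
#' @return logical 3D array.
#' @export
eyeball_voxels <- function(cfg = phantom_config()) {
  tab <- phantom_tables(cfg)
  out <- array(FALSE, cfg$grid_dims)
  for (eye in tab$eyes) out[eye$inside] <- TRUE
  out
}

#' Write phantom output to disk
#'
#' Volumes go to one 4D NIfTI per participant, labels (and closure) to a
#' tab-separated table with columns tr_index, sub_index, x_deg, y_deg
#' `[, closed_fraction]`, and the phantom mask to a 3D NIfTI of 0/1.
#'
#' @param dataset result of [generate_dataset()].
#' @param cfg the [phantom_config()] used.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_phantom <- function(dataset, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask <- phantom_mask(cfg)
  mask_path <- file.path(dir, "phantom_mask.nii")
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask$grid),
                                           dim(mask$grid))), mask_path)
  paths <- c(mask_path)
  for (p in dataset) {
    id <- p$participant$id
    vp <- file.path(dir, paste0(id, "_bold.nii"))
    RNifti::writeNifti(RNifti::asNifti(p$volumes), vp)
    lp <- file.path(dir, paste0(id, "_gaze.tsv"))
    write_gaze_tsv(p$labels, lp)
    paths <- c(paths, vp, lp)
  }
  invisible(paths)
}

#' Simulate phantom datasets from a configuration
#'
#' [stats::simulate()] method: draws `nsim` independent phantom datasets.
#'
#' @param object a [phantom_config()].
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param spec a [trajectory_spec()].
#' @param n_participants participants per dataset.
#' @param ... passed to [generate_dataset()].
#' @return list of `nsim` datasets (each as from [generate_dataset()]).
#' @export
simulate.phantom_config <- function(object, nsim = 1, seed = object$seed,
                                    spec = trajectory_spec(), 
                                    n_participants = 1, ...) {
  lapply(seq_len(nsim), function(i)
    generate_dataset(n_participants, spec, object, seed = seed + i - 1L, ...))
}
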
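test_that("central gaze yields a mirror-symmetric volume and lateral gazes mirror each other", {
  cfg <- small_phantom_config(noise_sd = 0)
  p <- phantom_participant("p1")
  flip2 <- function(v) v[, rev(seq_len(dim(v)[2])), , drop = FALSE]
  v0 <- render_volume(c(0, 0), p, cfg)
  expect_equal(v0, flip2(v0), tolerance = 1e-12)
  vl <- render_volume(c(-4, 0), p, cfg)
  vr <- render_volume(c(4, 0), p, cfg)
  expect_equal(vr, flip2(vl), tolerance = 1e-12)
  # vertical gaze is mirror-symmetric too (conjugate eyes)
  vu <- render_volume(c(0, 3), p, cfg)
  expect_equal(vu, flip2(vu), tolerance = 1e-12)
})

test_that("rendered noise matches its nominal standard deviation", {
  cfg <- phantom_config(grid_dims = c(16, 32, 32), eyeball_radius = 5,
                        noise_sd = 0)
  cfg_n <- phantom_config(grid_dims = c(16, 32, 32), eyeball_radius = 5,
                          noise_sd = 0.3)
  p <- phantom_participant("p1")
  clean <- render_volume(c(2, -1), p, cfg)
  set.seed(99)
  noisy <- render_volume(c(2, -1), p, cfg_n)
  resid <- as.vector(noisy - clean)
  expect_gte(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.3) / 0.3, 0.05)
})

test_that("gaze outside the representable rotation range is rejected", {
  cfg <- small_phantom_config()  # gaze_gain 2 -> limit 45 deg
  expect_error(render_volume(c(50, 0), phantom_participant("p"), cfg),
               "exceeds the representable rotation")
})

test_that("fixation grid visits every location the configured number of times", {
  spec <- trajectory_spec("fixation_grid", window = screen_window(19, 15),
                          tr_s = 1, n_tr = 27 * 2 * 2,
                          n_points = 27L, dwell_trs = 2L, n_repeats = 2L)
  traj <- simulate_trajectory(spec, n_sub = 10L, seed = 3)
  segs <- attr(traj, "segments")
  expect_equal(length(unique(segs)), 54L)  # 27 locations x 2 visits
  # dwell: position constant within a segment
  flat_x <- as.vector(t(traj[, , 1]))
  expect_true(all(tapply(flat_x, segs, function(v) diff(range(v))) == 0))
})

test_that("pursuit sub-TR displacements equal speed * tr / n_sub within segments", {
  spec <- trajectory_spec("pursuit_walk", window = screen_window(20, 20),
                          tr_s = 2, n_tr = 30L, speed_dps = 3,
                          turn_every_trs = 5L)
  traj <- simulate_trajectory(spec, n_sub = 10L, seed = 8)
  pts <- cbind(as.vector(t(traj[, , 1])), as.vector(t(traj[, , 2])))
  step <- sqrt(rowSums(diff(pts)^2))
  expect_equal(unname(step), rep(3 * 2 / 10, length(step)), tolerance = 1e-9)
})

test_that("trajectories are seeded, reproducible and window-bounded", {
  for (kind in c("fixation_grid", "pursuit_walk", "free_view")) {
    spec <- trajectory_spec(kind, window = screen_window(10, 10),
                            tr_s = 1, n_tr = 20L, speed_dps = 8)
    a <- simulate_trajectory(spec, seed = 5)
    b <- simulate_trajectory(spec, seed = 5)
    expect_identical(a, b)
    d <- simulate_trajectory(spec, seed = 6)
    if (kind != "fixation_grid") expect_false(identical(a, d))
    expect_true(all(abs(a[, , 1]) <= 5 + 1e-9))
    expect_true(all(abs(a[, , 2]) <= 5 + 1e-9))
  }
  expect_error(trajectory_spec("spiral"), "arg")
})

test_that("motion blur averages renders; identical sub-positions reduce to one render", {
  cfg <- small_phantom_config(noise_sd = 0)
  p <- phantom_participant("p1")
  spec <- trajectory_spec("fixation_grid", window = screen_window(8, 8),
                          tr_s = 1, n_tr = 4L, n_points = 4L, dwell_trs = 1L)
  out <- generate_participant(spec, p, cfg, seed = 2)
  for (t in 1:2) {
    g <- out$labels$coords[t, 1, ]
    expect_true(all(out$labels$coords[t, , 1] == g[1]))  # constant within TR
    expect_equal(out$volumes[, , , t], render_volume(g, p, cfg),
                 tolerance = 1e-12)
  }
})

test_that("within-TR spread changes the blurred volume even at equal medians", {
  cfg <- small_phantom_config(noise_sd = 0, n_sub = 2L)
  p <- phantom_participant("p1")
  tab <- NULL
  still <- (render_volume(c(-8, 0), p, cfg) + render_volume(c(8, 0), p, cfg)) / 2
  centred <- render_volume(c(0, 0), p, cfg)
  # same median gaze (0,0), different spread -> numerically different volumes
  expect_gt(max(abs(still - centred)), 0.01)
})

test_that("zero misalignment equals clean generation; nonzero shifts the volume", {
  cfg <- small_phantom_config()
  spec <- small_pursuit_spec(n_tr = 5L)
  clean <- generate_participant(spec, phantom_participant("a"), cfg, seed = 4)
  same <- generate_participant(spec,
                               phantom_participant("a",
                                                   misalignment = c(0, 0, 0)),
                               cfg, seed = 4)
  expect_identical(clean$volumes, same$volumes)
  shifted <- generate_participant(spec,
                                  phantom_participant("a",
                                                      misalignment = c(0, 2, 0)),
                                  cfg, seed = 4)
  expect_equal(shifted$volumes[, 3:16, , ], clean$volumes[, 1:14, , ],
               tolerance = 1e-12)
})

test_that("dataset generation draws gains in range, is seeded, and validates outliers", {
  cfg <- small_phantom_config(participant_gain_range = c(0.8, 1.2))
  spec <- small_pursuit_spec(n_tr = 2L)
  ds <- generate_dataset(10, spec, cfg, outlier_ids = 10,
                         misalignments = c(0L, 3L, 0L), seed = 1)
  gains <- vapply(ds, function(p) p$participant$gain, 1)
  expect_true(all(gains >= 0.8 & gains <= 1.2))
  expect_equal(sum(vapply(ds, function(p)
    any(p$participant$misalignment != 0L), TRUE)), 1L)
  ds2 <- generate_dataset(10, spec, cfg, seed = 2)
  expect_false(identical(gains, vapply(ds2, function(p) p$participant$gain, 1)))
  expect_error(generate_dataset(3, spec, cfg, outlier_ids = 4),
               "subset")
  # 100 draws stay within the configured range
  ds3 <- generate_dataset(100, small_pursuit_spec(n_tr = 1L), cfg, seed = 3)
  g3 <- vapply(ds3, function(p) p$participant$gain, 1)
  expect_true(all(g3 >= 0.8 & g3 <= 1.2))
})

test_that("noiseless volumes distinguish grid gazes across the sampled window", {
  cfg <- small_phantom_config(noise_sd = 0)
  p <- phantom_participant("p1")
  gz <- expand.grid(x = seq(-8, 8, length.out = 5),
                    y = seq(-8, 8, length.out = 5))
  vols <- lapply(seq_len(nrow(gz)), function(i)
    render_volume(c(gz$x[i], gz$y[i]), p, cfg))
  worst <- Inf
  for (i in seq_len(nrow(gz) - 1)) for (j in (i + 1):nrow(gz)) {
    sep <- sqrt((gz$x[i] - gz$x[j])^2 + (gz$y[i] - gz$y[j])^2)
    if (sep >= 1) worst <- min(worst, max(abs(vols[[i]] - vols[[j]])))
  }
  expect_gt(worst, 0.1 * cfg$lobe_contrast)
})

test_that("fully closed eyes hide gaze and add an eyelid band", {
  cfg <- small_phantom_config(noise_sd = 0)
  p <- phantom_participant("p1")
  a <- render_volume(c(-4, 2), p, cfg, closure = 1)
  b <- render_volume(c(4, -3), p, cfg, closure = 1)
  expect_equal(a, b, tolerance = 1e-12)
  open_v <- render_volume(c(0, 0), p, cfg, closure = 0)
  expect_gt(sum(a > open_v + 0.1), 0)  # lid band appears
})

test_that("phantom generation is bit-reproducible under (seed, config)", {
  cfg <- small_phantom_config()
  spec <- small_pursuit_spec(n_tr = 6L)
  a <- generate_dataset(3, spec, cfg, seed = 9)
  b <- generate_dataset(3, spec, cfg, seed = 9)
  expect_identical(a, b)
})

test_that("phantom mask has two components and round-trips through NIfTI with labels", {
  cfg <- small_phantom_config()
  mask <- phantom_mask(cfg)
  expect_lte(gazemri:::count_components(mask$grid), 4L)
  spec <- small_pursuit_spec(n_tr = 4L)
  ds <- generate_dataset(1, spec, cfg, seed = 2)
  dir <- tempfile("phantom")
  paths <- write_phantom(ds, cfg, dir)
  m2 <- load_mask(file.path(dir, "phantom_mask.nii"))
  expect_equal(m2$grid, mask$grid)
  s2 <- load_series(file.path(dir, "sub-01_bold.nii"), m2, tr_s = 1,
                    pad_multiple = 8L)
  in_mem <- volume_series(ds[[1]]$volumes, mask, tr_s = 1, pad_multiple = 8L)
  expect_equal(s2$data, in_mem$data, tolerance = 1e-6)
  l2 <- read_gaze_tsv(file.path(dir, "sub-01_gaze.tsv"),
                      window = spec$window, tr_s = 1)
  expect_equal(l2$coords, ds[[1]]$labels$coords, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(grid_dims = c(7, 16, 8)), "even")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
  expect_error(phantom_config(grid_dims = c(16, 16, 16), eyeball_radius = 4.5),
               "overlap")
  expect_error(phantom_config(n_sub = 0), "n_sub")
})
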
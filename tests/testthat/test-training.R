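test_that("across-participant folds hold out every participant exactly once", {
  plan <- make_folds(1:10, "across_participant", k = 5, seed = 2)
  expect_length(plan$folds, 5L)
  for (f in plan$folds) {
    expect_equal(nrow(f$train), 8L)
    expect_equal(nrow(f$test), 2L)
    expect_length(intersect(f$train$participant, f$test$participant), 0L)
  }
  tested <- unlist(lapply(plan$folds, function(f) f$test$participant))
  expect_setequal(tested, 1:10)
  expect_equal(anyDuplicated(tested), 0L)
  expect_error(make_folds(1:4, "across_participant", k = 5), "at least")
})

test_that("within-participant folds use both contiguous halves of everyone", {
  plan <- make_folds(c("a", "b", "c"), "within_participant")
  expect_length(plan$folds, 2L)
  f1 <- plan$folds[[1]]
  expect_setequal(f1$train$participant, c("a", "b", "c"))
  expect_setequal(f1$test$participant, c("a", "b", "c"))
  expect_true(all(f1$train$part != f1$test$part[match(f1$train$participant,
                                                      f1$test$participant)]))
  expect_equal(plan$folds[[2]]$train$part[1], plan$folds[[1]]$test$part[1])
})

test_that("leave-one-dataset-out folds train on the other datasets", {
  datasets <- c("A", "A", "B", "B", "C", "C")
  plan <- make_folds(1:6, "across_dataset", datasets = datasets)
  expect_length(plan$folds, 3L)
  for (f in plan$folds) {
    expect_equal(nrow(f$test), 2L)
    expect_equal(nrow(f$train), 4L)
    expect_false(f$held_out_dataset %in%
                   datasets[match(f$train$participant, 1:6)])
  }
  expect_error(make_folds(1:4, "across_dataset", datasets = rep("A", 4)),
               ">= 2 datasets")
})

test_that("fold exhaustiveness and exclusivity hold over random cohort sizes", {
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(5:50, 1)
    plan <- make_folds(seq_len(n), "across_participant", k = 5,
                       seed = rep)
    tested <- unlist(lapply(plan$folds, function(f) f$test$participant))
    expect_setequal(tested, seq_len(n))
    expect_equal(anyDuplicated(tested), 0L)
    sizes <- vapply(plan$folds, function(f) nrow(f$test), 1L)
    expect_lte(diff(range(sizes)), 1L)
  }
})

test_that("the small-set epoch rule is e = 2 + N", {
  expect_equal(epochs_for(1), 3L)
  expect_equal(epochs_for(10), 12L)
  expect_equal(epochs_for(21), 23L)
  expect_error(epochs_for(0), ">= 1")
})

test_that("augmentation with zero ranges is the identity and integer shifts invert", {
  set.seed(20)
  vol <- array(rnorm(8 * 16 * 8), c(8, 16, 8))
  ident <- augmentation_config(scale_range = c(1, 1), translation_range = 0,
                               rotation_range_deg = c(0, 0, 0))
  expect_equal(augment(vol, ident), vol, tolerance = 1e-12)
  # integer translation then its inverse restores interior content exactly
  inner <- array(0, c(8, 16, 8))
  inner[3:6, 5:12, 3:6] <- rnorm(4 * 8 * 4)
  shifted <- shift_volume(inner, c(1, 2, -1))
  back <- shift_volume(shifted, -c(1, 2, -1))
  expect_equal(back, inner, tolerance = 1e-12)
})

test_that("augmented volumes keep their intensity statistics on average", {
  cfg <- augmentation_config(scale_range = c(0.95, 1.05),
                             translation_range = 1,
                             rotation_range_deg = c(3, 3, 3))
  vol <- array(0, c(8, 16, 8))
  vol[3:6, 5:12, 3:6] <- 1
  set.seed(21)
  means <- replicate(100, mean(augment(vol, cfg)))
  expect_lt(abs(mean(means) - mean(vol)) / mean(vol), 0.1)
})

test_that("batches mix participants and are reproducible under a seed", {
  pool <- lapply(1:8, function(i)
    list(x = matrix(0, 4, 20), targets = numeric(20), id = i, n_tr = 20L))
  b1 <- make_batches(pool, n_steps = 100, batch_size = 8, seed = 3)
  b2 <- make_batches(pool, n_steps = 100, batch_size = 8, seed = 3)
  expect_identical(b1, b2)
  multi <- vapply(b1, function(b) length(unique(b[, 1])) >= 2L, TRUE)
  expect_true(all(multi))
  # single-participant pools are allowed (the constraint is vacuous)
  b3 <- make_batches(pool[1], n_steps = 5, batch_size = 8, seed = 1)
  expect_true(all(vapply(b3, function(b) all(b[, 1] == 1L), TRUE)))
})

test_that("a zero learning rate leaves the weights unchanged", {
  cfg_ph <- small_phantom_config()
  pp <- phantom_pool(2, small_pursuit_spec(n_tr = 10L), cfg_ph, seed = 15)
  cfg <- tiny_model_config()
  cfg$input_dims <- c(8L, 16L, 8L)
  cfg <- model_config(input_dims = c(8, 16, 8), base_filters = 4,
                      filter_multiplier = 2, n_residual_blocks = 3,
                      groups = 2, dropout = 0, n_sub = 10, dense_units = 8)
  net <- build_network(cfg, seed = 1)
  sch <- training_schedule(epochs = 1, steps_per_epoch = 3, batch_size = 4,
                           learning_rate = 0, seed = 2)
  fit <- train_network(net, pp$pool, sch)
  expect_equal(fit$net$params, net$params, tolerance = 1e-15)
})

test_that("seeded training reruns reproduce the loss history", {
  cfg_ph <- small_phantom_config()
  pp <- phantom_pool(2, small_pursuit_spec(n_tr = 10L), cfg_ph, seed = 16)
  cfg <- model_config(input_dims = c(8, 16, 8), base_filters = 4,
                      filter_multiplier = 2, n_residual_blocks = 3,
                      groups = 2, dropout = 0.1, n_sub = 10, dense_units = 8,
                      learning_rate = 1e-3)
  run <- function() {
    net <- build_network(cfg, seed = 1)
    train_network(net, pp$pool,
                  training_schedule(epochs = 2, steps_per_epoch = 4,
                                    batch_size = 4, seed = 9),
                  augmentation = augmentation_config())$history
  }
  h1 <- run()
  h2 <- run()
  expect_equal(h1$l, h2$l, tolerance = 1e-4)
  expect_equal(h1$samples, rep(16, 2))
})

test_that("per-epoch sample counts equal steps x batch size", {
  sch <- training_schedule()
  expect_equal(sch$steps_per_epoch * sch$batch_size, 12000L)
})

test_that("training-set subsampling keeps contiguous fractions and fixed tests", {
  pool <- lapply(1:6, function(i)
    list(x = matrix(seq_len(3 * 100), 3), targets = array(0, c(10, 2, 100)),
         id = i, n_tr = 100L))
  full <- subsample_training(pool, 6, 1, seed = 1)
  expect_equal(vapply(full, function(p) p$n_tr, 1L), rep(100L, 6))
  sub <- subsample_training(pool, 3, 0.2, seed = 2)
  expect_length(sub, 3L)
  for (p in sub) {
    expect_equal(p$n_tr, 20L)
    cols <- p$x[1, ]
    expect_equal(diff(cols), rep(3, 19))  # contiguous TR window
  }
  sub2 <- subsample_training(pool, 3, 0.2, seed = 3)
  expect_false(identical(vapply(sub, function(p) p$id, 1L),
                         vapply(sub2, function(p) p$id, 1L)))
  expect_error(subsample_training(pool, 9, 1), "exceeds")
  expect_error(subsample_training(pool, 3, 0), "fraction")
})

test_that("label time-shifting drops overhanging TRs and round-trips", {
  cfg_ph <- small_phantom_config()
  pp <- phantom_pool(1, small_pursuit_spec(n_tr = 100L), cfg_ph, seed = 17)
  s <- volume_series(array(seq_len(8 * 16 * 8 * 100), c(8, 16, 8, 100)),
                     phantom_mask(cfg_ph), pad_multiple = 8L)
  lab <- pp$labels[[1]]
  sh0 <- time_shift(s, lab, 0)
  expect_identical(sh0$series$data, s$data)
  sh3 <- time_shift(s, lab, 3)
  expect_equal(dim(sh3$series$data)[4], 97L)
  expect_equal(dim(sh3$labels$coords)[1], 97L)
  expect_equal(sh3$series$data[, , , 1], s$data[, , , 4])
  expect_equal(sh3$labels$coords[1, , ], lab$coords[1, , ])
  expect_error(time_shift(s, lab, 100), "smaller")
  expect_error(time_shift(s, lab, -1), ">= 0")
})

test_that("the fitted decoder object exposes the standard methods", {
  cfg_ph <- small_phantom_config()
  spec <- small_pursuit_spec(n_tr = 16L)
  ds <- generate_dataset(2, spec, cfg_ph, seed = 19)
  mask <- phantom_mask(cfg_ph)
  series <- lapply(ds, function(p)
    volume_series(p$volumes, mask, tr_s = 1, pad_multiple = 8L))
  labels <- lapply(ds, function(p) p$labels)
  cfg <- model_config(input_dims = c(8, 16, 8), base_filters = 4,
                      filter_multiplier = 2, n_residual_blocks = 3,
                      groups = 2, dropout = 0, n_sub = 10, dense_units = 8,
                      learning_rate = 1e-3)
  fit <- gaze_decoder(series, labels, cfg,
                      training_schedule(epochs = 1, steps_per_epoch = 3,
                                        batch_size = 4, seed = 2),
                      augmentation = NULL, seed = 1)
  expect_s3_class(fit, "gaze_decoder")
  expect_output(print(fit), "gaze decoder")
  expect_output(summary(fit), "Bottleneck")
  expect_type(coef(fit), "list")
  pr <- predict(fit, series[[1]])
  expect_equal(dim(pr$gaze), c(10, 2, 16))
  expect_equal(dim(pr$path), c(16, 2))
  expect_length(pr$pe, 16)
  pdf(NULL)
  plot(fit)
  plot(fit, "path", truth = median_gaze(labels[[1]]), decoded = pr$path)
  dev.off()
})
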
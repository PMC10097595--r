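# Shared small phantom/network fixtures. Heavy trained models are built once
# per session and cached in this environment so several tests can reuse them.

.cache <- new.env(parent = emptyenv())

small_phantom_config <- function(...) {
  args <- utils::modifyList(
    list(grid_dims = c(8L, 16L, 8L), eyeball_radius = 2.5,
         noise_sd = 0.05, seed = 7),
    list(...))
  do.call(phantom_config, args)
}

small_pursuit_spec <- function(n_tr = 40L, window = screen_window(10, 10),
                               speed = 4, turn = 3L) {
  trajectory_spec("pursuit_walk", window = window, tr_s = 1, n_tr = n_tr,
                  speed_dps = speed, turn_every_trs = turn)
}

reduced_model_config <- function(...) {
  model_config(input_dims = c(8L, 16L, 8L), base_filters = 8L,
               filter_multiplier = 2, n_residual_blocks = 6L, groups = 8L,
               dropout = 0.1, n_sub = 10L, dense_units = 64L,
               learning_rate = 1e-3, ...)
}

tiny_model_config <- function(...) {
  model_config(input_dims = c(8L, 8L, 8L), base_filters = 4L,
               filter_multiplier = 2, n_residual_blocks = 3L, groups = 2L,
               dropout = 0, n_sub = 2L, dense_units = 6L, ...)
}

# normalized series + labels for a small phantom dataset
phantom_pool <- function(n_participants, spec, cfg_ph, seed = 11, ...) {
  ds <- generate_dataset(n_participants, spec, cfg_ph, seed = seed, ...)
  mask <- phantom_mask(cfg_ph)
  series <- lapply(ds, function(p)
    normalize_series(volume_series(p$volumes, mask, tr_s = spec$tr_s,
                                   participant_id = p$participant$id,
                                   pad_multiple = 8L)))
  labels <- lapply(ds, function(p) p$labels)
  list(pool = training_pool(series, labels), labels = labels, ds = ds,
       mask = mask)
}

# The across-participant reference run shared by several acceptance checks:
# 10 pursuit participants (2 of the 8 training ones misaligned, mirroring
# imperfect co-registration in real cohorts), reduced network, e = 2 + N
# epochs. Cached after the first call.
trained_reference_model <- function() {
  if (!is.null(.cache$ref)) return(.cache$ref)
  cfg_ph <- small_phantom_config()
  spec <- small_pursuit_spec(n_tr = 200L)
  ds <- generate_dataset(10, spec, cfg_ph,
                         outlier_ids = c(1, 2),
                         misalignments = rbind(c(0L, 2L, 0L), c(0L, 3L, 0L)),
                         seed = 11)
  mask <- phantom_mask(cfg_ph)
  series <- lapply(ds, function(p)
    normalize_series(volume_series(p$volumes, mask, tr_s = 1,
                                   participant_id = p$participant$id,
                                   pad_multiple = 8L)))
  labels <- lapply(ds, function(p) p$labels)
  pool <- training_pool(series, labels)
  cfg <- reduced_model_config()
  sch <- training_schedule(epochs = epochs_for(8), steps_per_epoch = 80L,
                           batch_size = 8L, seed = 5)
  aug <- augmentation_config(scale_range = c(0.97, 1.03),
                             translation_range = 1,
                             rotation_range_deg = c(1, 1, 1), prob = 0.3)
  net <- build_network(cfg, seed = 1)
  fit <- train_network(net, pool[1:8], sch, augmentation = aug)
  .cache$ref <- list(fit = fit, pool = pool, labels = labels, mask = mask,
                     cfg_ph = cfg_ph, spec = spec,
                     train_ids = 1:8, test_ids = 9:10)
  .cache$ref
}

decode_participant <- function(net, x, labels) {
  pr <- net_predict(net, x)
  list(path = decoded_median_path(pr$gaze), pe = pr$pe,
       truth = median_gaze(labels))
}
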
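# Independent symbolic shape oracle: propagates dims/channels through the
# architecture rules without touching the package's network_shape().
oracle_shape <- function(dims, base, mult, R, n_sub, out_dim, use_pe) {
  dims <- dims / 2                        # downsample block pool
  chans <- round(base * mult)
  for (i in seq_len(R)) {
    chans <- round(base * mult^((i + 1) %/% 2))
    if (i %in% c(2, 4)) dims <- dims / 2
  }
  list(bottleneck = prod(dims) * chans,
       n_outputs = out_dim * n_sub + as.integer(use_pe))
}

test_that("mish matches its definition and limits", {
  expect_equal(mish(0), 0)
  expect_equal(mish(20), 20, tolerance = 1e-7)
  # high-precision reference values (arbitrary-precision evaluation)
  expect_equal(mish(-1), -0.30340146137410891807, tolerance = 1e-14)
  expect_equal(mish(-0.5), -0.22074377465172999682, tolerance = 1e-14)
  expect_equal(mish(2), 1.9439589595339945203, tolerance = 1e-14)
  # numerically stable far into the tails
  expect_equal(mish(100), 100)
  expect_equal(mish(-100), 0, tolerance = 1e-12)
})

test_that("the default full-scale configuration yields the 7,680-unit bottleneck", {
  cfg <- model_config()
  sh <- network_shape(cfg)
  expect_equal(sh$bottleneck_units, 7680L)
  expect_equal(sh$n_outputs, 2L * 10L + 1L)
  orc <- oracle_shape(c(16, 32, 16), 60, 2, 6, 10, 2, TRUE)
  expect_equal(sh$bottleneck_units, orc$bottleneck)
  expect_equal(sh$n_outputs, orc$n_outputs)
})

test_that("shape propagation matches the symbolic oracle for random valid configs", {
  set.seed(10)
  tried <- 0
  while (tried < 10) {
    base <- sample(c(8, 16, 32), 1)
    mult <- sample(c(1, 2), 1)
    groups <- sample(c(4, 8), 1)
    n_sub <- sample(1:10, 1)
    dims <- sample(c(8, 16), 3, replace = TRUE)
    cfg <- try(model_config(input_dims = dims, base_filters = base,
                            filter_multiplier = mult, n_residual_blocks = 6,
                            groups = groups, n_sub = n_sub,
                            dense_units = 16), silent = TRUE)
    if (inherits(cfg, "try-error")) next
    tried <- tried + 1
    sh <- network_shape(cfg)
    orc <- oracle_shape(dims, base, mult, 6, n_sub, 2, TRUE)
    expect_equal(sh$bottleneck_units, orc$bottleneck)
    expect_equal(sh$n_outputs, orc$n_outputs)
  }
  # the reduced harness geometry: 8x16x8 with base 8 -> 1x2x1 x 64 = 128
  expect_equal(network_shape(reduced_model_config())$bottleneck_units, 128L)
})

test_that("invalid configurations fail before any training", {
  expect_error(model_config(input_dims = c(12, 32, 16)), "divisible")
  expect_error(model_config(base_filters = 10, groups = 8), "divide")
  expect_error(model_config(dropout = 1), "dropout")
})

test_that("losses match their closed forms and brute-force oracles", {
  expect_equal(euclidean_loss(matrix(c(3, 4), 1), matrix(c(0, 0), 1)), 5)
  p <- matrix(rnorm(20), 10)
  expect_equal(euclidean_loss(p, p), 0)
  expect_error(euclidean_loss(matrix(0, 2, 2), matrix(0, 3, 2)), "mismatch")
  set.seed(6)
  pred <- array(rnorm(10 * 2 * 4), c(10, 2, 4))
  true <- array(rnorm(10 * 2 * 4), c(10, 2, 4))
  brute <- mean(sapply(1:4, function(n)
    mean(sapply(1:10, function(h)
      sqrt(sum((pred[h, , n] - true[h, , n])^2))))))
  expect_equal(euclidean_loss(pred, true), brute, tolerance = 1e-12)

  expect_equal(pe_loss(0.5, 1.0), 0.25)
  expect_equal(pe_loss(c(1, 2), c(1, 2)), 0)
  a <- runif(8); b <- runif(8)
  expect_equal(pe_loss(a, b), mean((a - b)^2), tolerance = 1e-12)

  lb <- combined_loss(1, 0.25)
  expect_equal(lb$l, 1.025)
  expect_equal(combined_loss(0, 0)$l, 0)
  expect_error(combined_loss(-1, 0), "nonnegative")
  # monotone nondecreasing in each argument
  expect_gte(combined_loss(1.1, 0.25)$l, lb$l)
  expect_gte(combined_loss(1, 0.3)$l, lb$l)
})

test_that("inference is deterministic, batch-consistent and dimension-checked", {
  cfg <- tiny_model_config()
  net <- build_network(cfg, seed = 2)
  set.seed(7)
  X <- matrix(rnorm(prod(cfg$input_dims) * 5), ncol = 5)
  X[, 3] <- X[, 1]  # duplicate volume
  pr <- net_predict(net, X)
  expect_equal(pr$gaze[, , 3], pr$gaze[, , 1], tolerance = 1e-12)
  expect_true(all(is.finite(pr$gaze)) && all(is.finite(pr$pe)))
  expect_true(all(pr$pe >= 0))  # softplus output
  # batch vs one-by-one within 1e-5
  single <- sapply(1:5, function(j)
    net_predict(net, X[, j, drop = FALSE])$gaze[1, 1, 1])
  expect_equal(single, pr$gaze[1, 1, ], tolerance = 1e-5)
  expect_error(net_predict(net, X[1:10, , drop = FALSE]), "expects")
  # zeroed output layers force zero gaze predictions
  net0 <- net
  for (h in 1:cfg$n_sub) {
    net0$params[[paste0("head", h, ".W2")]][] <- 0
    net0$params[[paste0("head", h, ".b2")]][] <- 0
  }
  expect_true(all(net_predict(net0, X)$gaze == 0))
})

test_that("analytic gradients match finite differences (detached PE semantics)", {
  cfg <- tiny_model_config()
  net <- build_network(cfg, seed = 3)
  set.seed(42)
  N <- 2
  X <- matrix(rnorm(prod(cfg$input_dims) * N), ncol = N)
  targets <- array(rnorm(cfg$n_sub * 2 * N), c(cfg$n_sub, 2, N))
  res <- net_loss_grad(net, X, targets, training = FALSE)
  ee0 <- res$ee
  loss_at <- function(net2) {
    fw <- net_forward(net2, X, training = FALSE, keep_cache = TRUE)
    dists <- sapply(seq_len(N), function(n)
      sapply(seq_len(cfg$n_sub), function(h)
        sqrt(sum((fw$heads[[h]][, n] - targets[h, , n])^2))))
    # PE head reads the bottleneck of the *base* network (stop-gradient input)
    Z0 <- res_Z
    P1 <- gazemri:::mish(crossprod(net2$params$pe.W1, Z0) + net2$params$pe.b1)
    pe <- gazemri:::softplus(drop(crossprod(net2$params$pe.W2, P1) +
                                  net2$params$pe.b2))
    mean(colMeans(matrix(dists, cfg$n_sub))) + 0.1 * mean((pe - ee0)^2)
  }
  fw0 <- net_forward(net, X, training = FALSE, keep_cache = TRUE)
  res_Z <- fw0$caches$Z
  eps <- 1e-6
  set.seed(8)
  worst <- 0
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      n2 <- net
      n2$params[[nm]][i] <- p[i] + eps
      lp <- loss_at(n2)
      n2$params[[nm]][i] <- p[i] - eps
      lm <- loss_at(n2)
      num <- (lp - lm) / (2 * eps)
      ana <- res$grads[[nm]][i]
      worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the combined loss decreases when overfitting a small phantom batch", {
  cfg_ph <- small_phantom_config()
  spec <- small_pursuit_spec(n_tr = 20L)
  pp <- phantom_pool(2, spec, cfg_ph, seed = 13)
  cfg <- reduced_model_config()
  cfg$dropout <- 0
  net <- build_network(cfg, seed = 1)
  sch <- training_schedule(epochs = 5, steps_per_epoch = 10, batch_size = 8,
                           learning_rate = 1e-3, seed = 4)
  fit <- train_network(net, pp$pool, sch)
  expect_lt(fit$history$l_ed[5], fit$history$l_ed[1] * 0.8)
  expect_true(all(is.finite(fit$history$l)))
})

test_that("training only the PE head leaves the gaze loss unchanged", {
  cfg <- tiny_model_config()
  net <- build_network(cfg, seed = 5)
  set.seed(11)
  N <- 6
  X <- matrix(rnorm(prod(cfg$input_dims) * N), ncol = N)
  targets <- array(rnorm(cfg$n_sub * 2 * N), c(cfg$n_sub, 2, N))
  l_ed_of <- function(net) {
    fw <- net_forward(net, X)
    mean(sapply(seq_len(N), function(n)
      mean(sapply(seq_len(cfg$n_sub), function(h)
        sqrt(sum((fw$heads[[h]][, n] - targets[h, , n])^2))))))
  }
  before <- l_ed_of(net)
  # 20 PE-only optimization steps: all other parameters frozen
  state <- gazemri:::adam_init(net$params)
  for (s in 1:20) {
    res <- net_loss_grad(net, X, targets, training = FALSE)
    g <- res$grads
    g <- g[grep("^pe\\.", names(g), value = TRUE)]
    upd <- gazemri:::adam_step(net$params, g, state, 1e-2)
    net$params <- upd$params
    state <- upd$state
  }
  expect_equal(l_ed_of(net), before, tolerance = 1e-12)
  # and the PE gradient into the trunk is exactly zero by design: gaze-head
  # gradients of the PE loss vanish when gaze targets are met exactly
  res <- net_loss_grad(net, X, targets, training = FALSE)
  expect_true(all(c("pe.W1", "pe.W2") %in% names(res$grads)))
})
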
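#' Decoder network configuration
#'
#' Architecture hyperparameters of the 3D convolutional gaze decoder: a stem
#' convolution (kernel 3, stride 1), dropout, a downsampling block (convolution
#' + 2x2x2 average pooling), then residual blocks — each with a convolutional
#' skip path and a (GroupNorm -> mish -> conv) x 2 main path — with two further
#' average-pooling stages after residual blocks 2 and 4. The flattened
#' bottleneck feeds `n_sub` unshared dense heads (one (x, y) pair per sub-TR
#' label) and one dense predicted-error (PE) head whose output passes through
#' softplus. The PE head reads a stop-gradient copy of the bottleneck so that
#' confidence training cannot alter the gaze pathway.
#'
#' @param input_dims integer(3), each divisible by the total pooling factor
#'   (8 with the default three pooling stages).
#' @param base_filters stem filter count (search range 16-64; default 60
#'   reproduces the full-scale 7,680-unit bottleneck).
#' @param filter_multiplier channel growth per stage (range 1-2).
#' @param n_residual_blocks number of residual blocks (range 3-6).
#' @param groups group-normalization groups; must divide all stage channel
#'   counts.
#' @param dropout dropout rate after the stem (0.5 for cross-behaviour
#'   generalization settings).
#' @param n_sub number of sub-TR gaze heads.
#' @param dense_units units in each head's hidden dense layer (range 128-1024).
#' @param learning_rate Adam learning rate (search range 1e-3 to 1e-5).
#' @param target `"gaze"` (2D coordinates per head + PE) or `"closure"`
#'   (single head, one eyes-closed fraction per volume, MSE loss, no PE).
#' @return an object of class `model_config`.
#' @export
model_config <- function(input_dims = c(16L, 32L, 16L),
                         base_filters = 60L,
                         filter_multiplier = 2,
                         n_residual_blocks = 6L,
                         groups = 8L,
                         dropout = 0.1,
                         n_sub = 10L,
                         dense_units = 128L,
                         learning_rate = 1e-4,
                         target = c("gaze", "closure")) {
  target <- match.arg(target)
  input_dims <- as.integer(input_dims)
  n_residual_blocks <- as.integer(n_residual_blocks)
  if (n_residual_blocks < 1L) stop("need at least one residual block")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (target == "closure") n_sub <- 1L
  cfg <- structure(list(
    input_dims = input_dims, base_filters = as.integer(base_filters),
    filter_multiplier = filter_multiplier,
    n_residual_blocks = n_residual_blocks, groups = as.integer(groups),
    dropout = dropout, n_sub = as.integer(n_sub),
    dense_units = as.integer(dense_units), learning_rate = learning_rate,
    target = target,
    out_dim = if (target == "gaze") 2L else 1L,
    use_pe = target == "gaze"
  ), class = "model_config")
  network_shape(cfg)  # validates divisibility and group constraints
  cfg
}

#' Symbolic shape propagation for a decoder configuration
#'
#' Computes, without allocating any weights, the spatial dimensions and channel
#' counts at every stage, the flattened bottleneck width and the output arity.
#' Serves as the configuration validator and as the reference the architecture
#' tests compare a built network against.
#'
#' @param cfg a [model_config()].
#' @return list with `stages` (data.frame: name, dims, channels), `pools`,
#'   `bottleneck_units`, `n_outputs`.
#' @export
network_shape <- function(cfg) {
  R <- cfg$n_residual_blocks
  pools_after <- intersect(c(2L, 4L), seq_len(R))
  n_pools <- 1L + length(pools_after)
  div <- 2L^n_pools
  if (any(cfg$input_dims %% div != 0L))
    stop(sprintf("input_dims %s must be divisible by %d (%d pooling stages)",
                 paste(cfg$input_dims, collapse = "x"), div, n_pools))
  chan_stage <- function(s) as.integer(round(cfg$base_filters *
                                             cfg$filter_multiplier^s))
  dims <- cfg$input_dims
  stages <- data.frame(name = "stem", dims = paste(dims, collapse = "x"),
                       channels = cfg$base_filters,
                       stringsAsFactors = FALSE)
  c_cur <- chan_stage(1L)
  dims <- dims %/% 2L
  stages <- rbind(stages, data.frame(name = "down+pool",
                                     dims = paste(dims, collapse = "x"),
                                     channels = c_cur))
  gn_channels <- integer(0)
  prev <- c_cur
  for (i in seq_len(R)) {
    cout <- chan_stage((i + 1L) %/% 2L)
    gn_channels <- c(gn_channels, prev, cout)
    prev <- cout
    if (i %in% pools_after) dims <- dims %/% 2L
    stages <- rbind(stages, data.frame(
      name = paste0("res", i, if (i %in% pools_after) "+pool" else ""),
      dims = paste(dims, collapse = "x"), channels = cout))
  }
  bad <- unique(gn_channels[gn_channels %% cfg$groups != 0L])
  if (length(bad))
    stop("groups = ", cfg$groups, " does not divide channel count(s) ",
         paste(bad, collapse = ", "))
  bottleneck <- prod(dims) * prev
  n_outputs <- cfg$out_dim * cfg$n_sub + as.integer(cfg$use_pe)
  list(stages = stages, pools_after = pools_after,
       final_dims = dims, final_channels = prev,
       bottleneck_units = as.integer(bottleneck),
       n_outputs = as.integer(n_outputs))
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build a gaze decoder network
#'
#' Allocates and initialises all weights for a [model_config()] and precomputes
#' the convolution/pooling index tables.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `gaze_network`.
#' @export
build_network <- function(cfg, seed = 1L) {
  shape <- network_shape(cfg)
  set.seed(seed)
  R <- cfg$n_residual_blocks
  chan <- function(s) as.integer(round(cfg$base_filters *
                                       cfg$filter_multiplier^s))
  p <- list()
  p$stem.W <- he_init(27L, cfg$base_filters, 27)
  p$stem.b <- numeric(cfg$base_filters)
  c1 <- chan(1L)
  p$down.W <- he_init(27L * cfg$base_filters, c1, 27 * cfg$base_filters)
  p$down.b <- numeric(c1)
  prev <- c1
  blocks <- list()
  dims <- cfg$input_dims %/% 2L
  level_dims <- list(cfg$input_dims, dims)
  for (i in seq_len(R)) {
    cout <- chan((i + 1L) %/% 2L)
    pre <- paste0("res", i)
    p[[paste0(pre, ".gn1.gamma")]] <- rep(1, prev)
    p[[paste0(pre, ".gn1.beta")]] <- numeric(prev)
    p[[paste0(pre, ".conv1.W")]] <- he_init(27L * prev, cout, 27 * prev)
    p[[paste0(pre, ".conv1.b")]] <- numeric(cout)
    p[[paste0(pre, ".gn2.gamma")]] <- rep(1, cout)
    p[[paste0(pre, ".gn2.beta")]] <- numeric(cout)
    p[[paste0(pre, ".conv2.W")]] <- he_init(27L * cout, cout, 27 * cout)
    p[[paste0(pre, ".conv2.b")]] <- numeric(cout)
    p[[paste0(pre, ".skip.W")]] <- he_init(27L * prev, cout, 27 * prev)
    p[[paste0(pre, ".skip.b")]] <- numeric(cout)
    blocks[[i]] <- list(prefix = pre, cin = prev, cout = cout,
                        pool_after = i %in% shape$pools_after)
    prev <- cout
    if (i %in% shape$pools_after) {
      dims <- dims %/% 2L
      level_dims[[length(level_dims) + 1L]] <- dims
    }
  }
  Fb <- shape$bottleneck_units
  U <- cfg$dense_units
  for (h in seq_len(cfg$n_sub)) {
    pre <- paste0("head", h)
    p[[paste0(pre, ".W1")]] <- he_init(Fb, U, Fb)
    p[[paste0(pre, ".b1")]] <- numeric(U)
    p[[paste0(pre, ".W2")]] <- matrix(stats::rnorm(U * cfg$out_dim,
                                                   sd = sqrt(1 / U)),
                                      U, cfg$out_dim)
    p[[paste0(pre, ".b2")]] <- numeric(cfg$out_dim)
  }
  if (cfg$use_pe) {
    p$pe.W1 <- he_init(Fb, U, Fb)
    p$pe.b1 <- numeric(U)
    p$pe.W2 <- matrix(stats::rnorm(U, sd = sqrt(1 / U)), U, 1L)
    p$pe.b2 <- 0
  }
  # convolution index tables per resolution level actually convolved at
  conv_idx <- list(conv_indices(cfg$input_dims))
  for (ld in level_dims[-1]) conv_idx[[length(conv_idx) + 1L]] <- conv_indices(ld)
  pool_idx <- list(pool_indices(cfg$input_dims))
  k <- 2L
  for (i in seq_len(R)) {
    if (blocks[[i]]$pool_after) {
      pool_idx[[length(pool_idx) + 1L]] <- pool_indices(level_dims[[k]])
      k <- k + 1L
    }
  }
  structure(list(cfg = cfg, params = p, blocks = blocks, shape = shape,
                 conv_idx = conv_idx, pool_idx = pool_idx,
                 level_dims = level_dims),
            class = "gaze_network")
}

#' @export
print.gaze_network <- function(x, ...) {
  cat("3D convolutional gaze decoder\n")
  print(x$shape$stages, row.names = FALSE)
  cat(sprintf("  bottleneck: %d units; outputs: %d (%d head(s) x %d + %s PE)\n",
              x$shape$bottleneck_units, x$shape$n_outputs, x$cfg$n_sub,
              x$cfg$out_dim, if (x$cfg$use_pe) "1" else "no"))
  cat(sprintf("  parameters: %s\n",
              format(sum(vapply(x$params, length, 1L)), big.mark = ",")))
  invisible(x)
}

res_fwd <- function(X, blk, p, idx, groups, N) {
  pre <- blk$prefix
  g1 <- gn_fwd(X, p[[paste0(pre, ".gn1.gamma")]],
               p[[paste0(pre, ".gn1.beta")]], groups, N)
  a1 <- mish(g1$Y)
  cv1 <- conv_fwd(a1, p[[paste0(pre, ".conv1.W")]],
                  p[[paste0(pre, ".conv1.b")]], idx, N)
  g2 <- gn_fwd(cv1$Y, p[[paste0(pre, ".gn2.gamma")]],
               p[[paste0(pre, ".gn2.beta")]], groups, N)
  a2 <- mish(g2$Y)
  cv2 <- conv_fwd(a2, p[[paste0(pre, ".conv2.W")]],
                  p[[paste0(pre, ".conv2.b")]], idx, N)
  sk <- conv_fwd(X, p[[paste0(pre, ".skip.W")]],
                 p[[paste0(pre, ".skip.b")]], idx, N)
  list(Y = cv2$Y + sk$Y,
       cache = list(g1 = g1, g1Y = g1$Y, cv1 = cv1, g2 = g2, g2Y = g2$Y,
                    cv2 = cv2, sk = sk))
}

res_bwd <- function(dY, blk, cache, p, N, grads) {
  pre <- blk$prefix
  b2 <- conv_bwd(dY, cache$cv2, p[[paste0(pre, ".conv2.W")]])
  grads[[paste0(pre, ".conv2.W")]] <- b2$dW
  grads[[paste0(pre, ".conv2.b")]] <- b2$db
  dg2 <- b2$dX * mish_grad(cache$g2Y)
  gb2 <- gn_bwd(dg2, cache$g2, p[[paste0(pre, ".gn2.gamma")]], N)
  grads[[paste0(pre, ".gn2.gamma")]] <- gb2$dgamma
  grads[[paste0(pre, ".gn2.beta")]] <- gb2$dbeta
  b1 <- conv_bwd(gb2$dX, cache$cv1, p[[paste0(pre, ".conv1.W")]])
  grads[[paste0(pre, ".conv1.W")]] <- b1$dW
  grads[[paste0(pre, ".conv1.b")]] <- b1$db
  dg1 <- b1$dX * mish_grad(cache$g1Y)
  gb1 <- gn_bwd(dg1, cache$g1, p[[paste0(pre, ".gn1.gamma")]], N)
  grads[[paste0(pre, ".gn1.gamma")]] <- gb1$dgamma
  grads[[paste0(pre, ".gn1.beta")]] <- gb1$dbeta
  bs <- conv_bwd(dY, cache$sk, p[[paste0(pre, ".skip.W")]])
  grads[[paste0(pre, ".skip.W")]] <- bs$dW
  grads[[paste0(pre, ".skip.b")]] <- bs$db
  list(dX = gb1$dX + bs$dX, grads = grads)
}

# Full forward pass. X: V x N matrix of single-channel input volumes
# (column-major voxels). Returns head outputs, PE and (if keep_cache) the
# intermediate activations needed for backprop.
net_forward <- function(net, X, training = FALSE, keep_cache = FALSE) {
  cfg <- net$cfg
  p <- net$params
  N <- ncol(X)
  caches <- list()
  cv <- conv_fwd(X, p$stem.W, p$stem.b, net$conv_idx[[1]], N)
  caches$stem <- if (keep_cache) cv else NULL
  Y <- cv$Y
  dmask <- NULL
  if (training && cfg$dropout > 0) {
    dmask <- dropout_mask(nrow(Y), ncol(Y), cfg$dropout)
    Y <- Y * dmask
  }
  caches$dmask <- dmask
  dv <- conv_fwd(Y, p$down.W, p$down.b, net$conv_idx[[1]], N)
  caches$down <- if (keep_cache) dv else NULL
  Y <- pool_fwd(dv$Y, net$pool_idx[[1]])
  level <- 2L
  pool_k <- 2L
  res_caches <- list()
  for (i in seq_along(net$blocks)) {
    blk <- net$blocks[[i]]
    rf <- res_fwd(Y, blk, p, net$conv_idx[[level]], cfg$groups, N)
    res_caches[[i]] <- if (keep_cache) rf$cache else NULL
    Y <- rf$Y
    if (blk$pool_after) {
      Y <- pool_fwd(Y, net$pool_idx[[pool_k]])
      pool_k <- pool_k + 1L
      level <- level + 1L
    }
  }
  caches$res <- res_caches
  Vf <- nrow(Y)
  Cf <- ncol(Y) %/% N
  Z <- matrix(0, Vf * Cf, N)
  for (n in seq_len(N))
    Z[, n] <- as.vector(Y[, ((n - 1) * Cf + 1):(n * Cf)])
  caches$Z <- Z
  caches$final_VC <- c(Vf, Cf)
  heads <- vector("list", cfg$n_sub)
  head_caches <- vector("list", cfg$n_sub)
  for (h in seq_len(cfg$n_sub)) {
    pre <- paste0("head", h)
    H1pre <- dense_fwd(Z, p[[paste0(pre, ".W1")]], p[[paste0(pre, ".b1")]])
    H1 <- mish(H1pre)
    heads[[h]] <- dense_fwd(H1, p[[paste0(pre, ".W2")]], p[[paste0(pre, ".b2")]])
    head_caches[[h]] <- if (keep_cache) list(H1pre = H1pre, H1 = H1) else NULL
  }
  caches$heads <- head_caches
  pe <- NULL
  if (cfg$use_pe) {
    P1pre <- dense_fwd(Z, p$pe.W1, p$pe.b1)
    P1 <- mish(P1pre)
    z_pe <- drop(dense_fwd(P1, p$pe.W2, p$pe.b2))
    pe <- softplus(z_pe)
    caches$pe <- if (keep_cache) list(P1pre = P1pre, P1 = P1, z_pe = z_pe) else NULL
    caches$z_pe <- z_pe
  }
  list(heads = heads, pe = pe, caches = if (keep_cache) caches else NULL,
       N = N)
}

# Backward pass: d_heads is a list of out_dim x N gradients per head,
# dz_pe the gradient w.r.t. the PE pre-softplus output (or NULL).
net_backward <- function(net, fw, d_heads, dz_pe = NULL) {
  cfg <- net$cfg
  p <- net$params
  ca <- fw$caches
  N <- fw$N
  grads <- list()
  Z <- ca$Z
  dZ <- matrix(0, nrow(Z), N)
  for (h in seq_len(cfg$n_sub)) {
    pre <- paste0("head", h)
    hc <- ca$heads[[h]]
    b2 <- dense_bwd(d_heads[[h]], hc$H1, p[[paste0(pre, ".W2")]])
    grads[[paste0(pre, ".W2")]] <- b2$dW
    grads[[paste0(pre, ".b2")]] <- b2$db
    dH1 <- b2$dZ * mish_grad(hc$H1pre)
    b1 <- dense_bwd(dH1, Z, p[[paste0(pre, ".W1")]])
    grads[[paste0(pre, ".W1")]] <- b1$dW
    grads[[paste0(pre, ".b1")]] <- b1$db
    dZ <- dZ + b1$dZ
  }
  if (cfg$use_pe && !is.null(dz_pe)) {
    pc <- ca$pe
    dzp <- matrix(dz_pe, 1L, N)
    b2 <- dense_bwd(dzp, pc$P1, p$pe.W2)
    grads$pe.W2 <- b2$dW
    grads$pe.b2 <- b2$db
    dP1 <- b2$dZ * mish_grad(pc$P1pre)
    b1 <- dense_bwd(dP1, Z, p$pe.W1)
    grads$pe.W1 <- b1$dW
    grads$pe.b1 <- b1$db
    # PE input is detached: no contribution to dZ
  }
  Vf <- ca$final_VC[1]
  Cf <- ca$final_VC[2]
  dY <- matrix(0, Vf, Cf * N)
  for (n in seq_len(N))
    dY[, ((n - 1) * Cf + 1):(n * Cf)] <- matrix(dZ[, n], Vf, Cf)
  level <- length(net$conv_idx)
  pool_k <- length(net$pool_idx)
  for (i in rev(seq_along(net$blocks))) {
    blk <- net$blocks[[i]]
    if (blk$pool_after) {
      dY <- pool_bwd(dY, net$pool_idx[[pool_k]])
      pool_k <- pool_k - 1L
      level <- level - 1L
    }
    rb <- res_bwd(dY, blk, ca$res[[i]], p, N, grads)
    grads <- rb$grads
    dY <- rb$dX
  }
  dY <- pool_bwd(dY, net$pool_idx[[1]])
  bd <- conv_bwd(dY, ca$down, p$down.W)
  grads$down.W <- bd$dW
  grads$down.b <- bd$db
  dY <- bd$dX
  if (!is.null(ca$dmask)) dY <- dY * ca$dmask
  bs <- conv_bwd(dY, ca$stem, p$stem.W)
  grads$stem.W <- bs$dW
  grads$stem.b <- bs$db
  grads$input <- bs$dX
  grads
}

#' Per-volume Euclidean (gaze) loss
#'
#' Mean over sub-TR labels of the 2D Euclidean distance between predicted and
#' true coordinates; the batch loss is the mean over volumes.
#'
#' @param pred,true numeric matrices `n_sub x 2` (one volume) or arrays
#'   `n_sub x 2 x N`.
#' @return scalar loss.
#' @export
euclidean_loss <- function(pred, true) {
  if (length(dim(pred)) == 2L) {
    pred <- array(pred, c(dim(pred), 1L))
    true <- array(true, c(dim(true), 1L))
  }
  if (!all(dim(pred) == dim(true)))
    stop(sprintf("shape mismatch: pred %s vs true %s",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(true), collapse = "x")))
  d <- sqrt((pred[, 1, , drop = FALSE] - true[, 1, , drop = FALSE])^2 +
            (pred[, 2, , drop = FALSE] - true[, 2, , drop = FALSE])^2)
  mean(apply(array(d, dim(d)[c(1, 3)]), 2, mean))
}

#' Predicted-error (PE) loss
#'
#' Mean squared error between the network's predicted EE and the realized EE
#' of the same volumes; the realized EE is treated as a constant target (no
#' gradient flows through it).
#'
#' @param predicted_pe numeric vector of predicted errors.
#' @param realized_ee numeric vector of realized per-volume Euclidean errors.
#' @return scalar loss.
#' @export
pe_loss <- function(predicted_pe, realized_ee) {
  mean((predicted_pe - realized_ee)^2)
}

#' Combined training loss
#'
#' `L = 0.1 * L_MSE + L_ED`: the Euclidean gaze loss plus one tenth of the
#' PE regression loss.
#'
#' @param l_ed Euclidean loss component (>= 0).
#' @param l_mse PE loss component (>= 0).
#' @return list of class `loss_breakdown` with `l_ed`, `l_mse`, `l`.
#' @export
combined_loss <- function(l_ed, l_mse) {
  if (l_ed < 0 || l_mse < 0)
    stop("loss components must be nonnegative (upstream bug?)")
  structure(list(l_ed = l_ed, l_mse = l_mse, l = 0.1 * l_mse + l_ed),
            class = "loss_breakdown")
}

# Loss + gradients for one batch.
# X: V x N inputs; targets: n_sub x out_dim x N array (gaze) or numeric N
# (closure). Returns loss breakdown, gradients and predictions.
net_loss_grad <- function(net, X, targets, training = TRUE) {
  cfg <- net$cfg
  fw <- net_forward(net, X, training = training, keep_cache = TRUE)
  N <- fw$N
  if (cfg$target == "gaze") {
    dists <- matrix(0, cfg$n_sub, N)
    d_heads <- vector("list", cfg$n_sub)
    for (h in seq_len(cfg$n_sub)) {
      D <- fw$heads[[h]] - rbind(targets[h, 1, ], targets[h, 2, ])
      dist <- sqrt(colSums(D^2))
      dists[h, ] <- dist
      d_heads[[h]] <- sweep(D, 2, pmax(dist, 1e-12), "/") / (cfg$n_sub * N)
    }
    ee <- colMeans(dists)
    l_ed <- mean(ee)
    l_mse <- pe_loss(fw$pe, ee)
    lb <- combined_loss(l_ed, l_mse)
    dpe <- 0.1 * 2 * (fw$pe - ee) / N
    dz_pe <- dpe * sigmoid(fw$caches$z_pe)
    grads <- net_backward(net, fw, d_heads, dz_pe)
    list(loss = lb, grads = grads, ee = ee, pe = fw$pe)
  } else {
    out <- drop(fw$heads[[1]])
    err <- out - targets
    l <- mean(err^2)
    d_heads <- list(matrix(2 * err / N, 1L, N))
    grads <- net_backward(net, fw, d_heads, NULL)
    list(loss = structure(list(l_ed = NA_real_, l_mse = l, l = l),
                          class = "loss_breakdown"),
         grads = grads, pred = out)
  }
}

#' Run the decoder on a batch of volumes
#'
#' Inference-mode forward pass (dropout off, deterministic).
#'
#' @param net a [build_network()] result.
#' @param X matrix `V x N` of flattened input volumes, or a 4D array
#'   (dims x N), or a single 3D volume.
#' @param chunk maximum volumes per internal forward pass.
#' @return list with `gaze` (array `n_sub x out_dim x N`) and `pe`
#'   (numeric N, `NULL` for closure models).
#' @export
net_predict <- function(net, X, chunk = 32L) {
  cfg <- net$cfg
  if (is.array(X) && length(dim(X)) == 4L)
    X <- matrix(X, prod(dim(X)[1:3]), dim(X)[4])
  if (is.array(X) && length(dim(X)) == 3L)
    X <- matrix(as.vector(X), ncol = 1L)
  if (nrow(X) != prod(cfg$input_dims))
    stop(sprintf("input has %d voxels; the network expects %s = %d",
                 nrow(X), paste(cfg$input_dims, collapse = "x"),
                 prod(cfg$input_dims)))
  N <- ncol(X)
  gaze <- array(0, c(cfg$n_sub, cfg$out_dim, N))
  pe <- if (cfg$use_pe) numeric(N) else NULL
  for (start in seq(1L, N, by = chunk)) {
    ix <- start:min(start + chunk - 1L, N)
    fw <- net_forward(net, X[, ix, drop = FALSE], training = FALSE)
    for (h in seq_len(cfg$n_sub))
      gaze[h, , ix] <- fw$heads[[h]]
    if (cfg$use_pe) pe[ix] <- fw$pe[seq_along(ix)]
  }
  list(gaze = gaze, pe = pe)
}
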
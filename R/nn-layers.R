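# Low-level 3D network layers.
#
# Feature maps are stored as V x (C*N) matrices: V voxels (column-major order
# of the 3D grid), C channels, N batch samples, with channels fastest along
# columns. Convolutions are implemented as im2col gathers followed by BLAS
# matrix multiplications; all layers have hand-derived backward passes that
# are verified against finite differences in the test suite.

# im2col index table for a 3x3x3 kernel with zero padding: row v, column k
# holds the (V+1)-padded row index of the k-th kernel tap around voxel v.
conv_indices <- function(dims) {
  V <- prod(dims)
  coord <- arrayInd(seq_len(V), dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  idx <- matrix(V + 1L, V, 27L)
  for (k in 1:27) {
    cc <- sweep(coord, 2, offs[k, ], "+")
    ok <- cc[, 1] >= 1 & cc[, 1] <= dims[1] &
          cc[, 2] >= 1 & cc[, 2] <= dims[2] &
          cc[, 3] >= 1 & cc[, 3] <= dims[3]
    lin <- (cc[, 3] - 1) * dims[1] * dims[2] + (cc[, 2] - 1) * dims[1] + cc[, 1]
    idx[ok, k] <- as.integer(lin[ok])
  }
  idx
}

# 2x2x2 average-pooling index tables: children (Vout x 8 input rows) and
# parent (length V, pooled row of each input voxel).
pool_indices <- function(dims) {
  stopifnot(all(dims %% 2L == 0L))
  dout <- dims %/% 2L
  Vout <- prod(dout)
  oc <- arrayInd(seq_len(Vout), dout)
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  children <- matrix(0L, Vout, 8L)
  for (k in 1:8) {
    cc <- sweep((oc - 1L) * 2L + 1L, 2, offs[k, ], "+")
    children[, k] <- as.integer((cc[, 3] - 1) * dims[1] * dims[2] +
                                (cc[, 2] - 1) * dims[1] + cc[, 1])
  }
  ic <- arrayInd(seq_len(prod(dims)), dims)
  pc <- (ic - 1L) %/% 2L + 1L
  parent <- as.integer((pc[, 3] - 1) * dout[1] * dout[2] +
                       (pc[, 2] - 1) * dout[1] + pc[, 1])
  list(children = children, parent = parent, dims_out = dout)
}

#' Mish activation
#'
#' `mish(x) = x * tanh(softplus(x))` with `softplus(x) = log(1 + exp(x))`,
#' evaluated in a numerically stable form for large `|x|`.
#'
#' @param x numeric vector/matrix.
#' @return mish of `x`, same shape.
#' @export
mish <- function(x) {
  x * tanh(softplus(x))
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

mish_grad <- function(x) {
  t <- tanh(softplus(x))
  t + x * (1 - t^2) * sigmoid(x)
}

# ---- convolution ----

conv_fwd <- function(X, W, b, idx, N) {
  V <- nrow(X)
  CN <- ncol(X)
  C <- CN %/% N
  Cout <- ncol(W)
  Xpad <- rbind(X, 0)
  P <- Xpad[as.vector(idx), , drop = FALSE]   # (V*27) x (C*N), v fastest
  Y <- matrix(0, V, Cout * N)
  Q <- vector("list", N)
  for (n in seq_len(N)) {
    Qn <- P[, ((n - 1) * C + 1):(n * C), drop = FALSE]
    dim(Qn) <- c(V, 27L * C)
    Y[, ((n - 1) * Cout + 1):(n * Cout)] <- Qn %*% W
    Q[[n]] <- Qn
  }
  Y <- Y + matrix(b, V, Cout * N, byrow = TRUE)
  list(Y = Y, Q = Q, C = C, Cout = Cout, idx = idx)
}

conv_bwd <- function(dY, cache, W) {
  V <- nrow(dY)
  N <- length(cache$Q)
  C <- cache$C
  Cout <- cache$Cout
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(Cout)
  dP <- matrix(0, V * 27L, C * N)
  for (n in seq_len(N)) {
    dYn <- dY[, ((n - 1) * Cout + 1):(n * Cout), drop = FALSE]
    dW <- dW + crossprod(cache$Q[[n]], dYn)
    db <- db + colSums(dYn)
    dQn <- tcrossprod(dYn, W)
    dim(dQn) <- c(V * 27L, C)
    dP[, ((n - 1) * C + 1):(n * C)] <- dQn
  }
  g <- rowsum(dP, group = as.vector(cache$idx))
  dX <- g[seq_len(V), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# ---- group normalization ----

gn_fwd <- function(X, gamma, beta, groups, N, eps = 1e-5) {
  V <- nrow(X)
  C <- ncol(X) %/% N
  Cg <- C %/% groups
  Xg <- X
  dim(Xg) <- c(V * Cg, groups * N)
  mu <- colMeans(Xg)
  xc <- sweep(Xg, 2, mu)
  istd <- 1 / sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2, istd, "*")
  dim(xhat) <- c(V, C * N)
  Y <- sweep(xhat, 2, rep(gamma, N), "*") +
       matrix(rep(beta, N), V, C * N, byrow = TRUE)
  list(Y = Y, xhat = xhat, istd = istd, C = C, groups = groups)
}

gn_bwd <- function(dY, cache, gamma, N) {
  V <- nrow(dY)
  C <- cache$C
  Cg <- C %/% cache$groups
  tmp <- colSums(dY * cache$xhat)
  dgamma <- rowSums(matrix(tmp, C, N))
  dbeta <- rowSums(matrix(colSums(dY), C, N))
  dxhat <- sweep(dY, 2, rep(gamma, N), "*")
  dim(dxhat) <- c(V * Cg, cache$groups * N)
  xhat_g <- cache$xhat
  dim(xhat_g) <- c(V * Cg, cache$groups * N)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat_g)
  dXg <- sweep(dxhat, 2, m1) - sweep(xhat_g, 2, m2, "*")
  dXg <- sweep(dXg, 2, cache$istd, "*")
  dim(dXg) <- c(V, C * N)
  list(dX = dXg, dgamma = dgamma, dbeta = dbeta)
}

# ---- average pooling ----

pool_fwd <- function(X, pidx) {
  Vout <- nrow(pidx$children)
  P <- X[as.vector(pidx$children), , drop = FALSE]
  Y <- rowsum(P, group = rep(seq_len(Vout), 8L)) / 8
  Y
}

pool_bwd <- function(dY, pidx) {
  dY[pidx$parent, , drop = FALSE] / 8
}

# ---- dense ----

dense_fwd <- function(Z, W, b) {
  crossprod(W, Z) + b
}

dense_bwd <- function(dY, Z, W) {
  list(dZ = W %*% dY, dW = Z %*% t(dY), db = rowSums(dY))
}

# ---- dropout ----

dropout_mask <- function(dim1, dim2, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(dim1 * dim2) >= p) / (1 - p), dim1, dim2)
}
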
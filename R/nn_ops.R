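# Low-level neural network operations.
#
# Feature maps are stored as dense matrices of shape (H*W*N) x C: rows run over
# spatial positions (row index fastest, then column, then image-in-batch),
# columns over channels. 3x3 convolutions are computed as nine shifted gathers
# followed by BLAS matrix multiplies, which keeps both the forward and the
# hand-derived backward passes fully vectorised. Backward passes are verified
# against finite differences in the test suite.

.idx_cache <- new.env(parent = emptyenv())

# Row-index vector implementing a (dh, dw) in-plane shift with zero padding:
# output row r reads input row idx[r]; out-of-plane reads map to the appended
# zero row (H*W*N + 1).
shift_rows <- function(H, W, N, dh, dw) {
  key <- paste(H, W, N, dh, dw, sep = "_")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  h <- rep.int(seq_len(H), W)
  w <- rep(seq_len(W), each = H)
  hs <- h + dh
  ws <- w + dw
  ok <- hs >= 1L & hs <= H & ws >= 1L & ws <= W
  base <- ifelse(ok, hs + (ws - 1L) * H, NA_integer_)
  HW <- H * W
  idx <- rep(base, N) + rep.int((seq_len(N) - 1L) * HW, rep.int(HW, N))
  idx[is.na(idx)] <- HW * N + 1L
  idx <- as.integer(idx)
  .idx_cache[[key]] <- idx
  idx
}

# Fixed offset enumeration for 3x3 kernels; offset k reversed is 10 - k.
conv_offsets <- function() {
  list(dh = rep(-1:1, times = 3), dw = rep(-1:1, each = 3))
}

# 3x3 conv weights are a single (9 * c_in) x c_out matrix whose row blocks
# correspond to the nine kernel offsets; the shifted-gather matrix ("im2col")
# then reduces the convolution to one BLAS multiply.
conv_init <- function(c_in, c_out, gain = 2) {
  sd <- sqrt(gain / (9 * c_in))
  list(W = matrix(stats::rnorm(9 * c_in * c_out, 0, sd), 9 * c_in),
       b = numeric(c_out))
}

conv1x1_init <- function(c_in, c_out, gain = 2) {
  list(W = matrix(stats::rnorm(c_in * c_out, 0, sqrt(gain / c_in)), c_in),
       b = numeric(c_out))
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Gather the nine shifted copies of X into one (H*W*N) x (9*c_in) matrix.
# Column r of the result is channel `(r-1) %/% 9 + 1` shifted by offset
# `(r-1) %% 9 + 1` (offset index runs fastest within each channel block);
# conv weight rows use the same layout.
im2col3 <- function(X, meta, reverse = FALSE) {
  n <- nrow(X)
  cn <- ncol(X)
  key <- paste("col", meta$H, meta$W, meta$N, cn, reverse, sep = "_")
  vec <- .idx_cache[[key]]
  if (is.null(vec)) {
    off <- conv_offsets()
    sgn <- if (reverse) -1L else 1L
    base <- unlist(lapply(1:9, function(k) {
      shift_rows(meta$H, meta$W, meta$N, sgn * off$dh[k], sgn * off$dw[k])
    }), use.names = FALSE)
    # linear index into rbind(X, 0) viewed as a vector, laid out so that the
    # result's column (c-1)*9 + k is channel c shifted by offset k
    vec <- rep(base, times = cn) +
      rep((seq_len(cn) - 1L) * (n + 1L), each = 9L * n)
    .idx_cache[[key]] <- vec
  }
  Xz <- rbind(X, 0)
  out <- Xz[vec]
  dim(out) <- c(n, 9L * cn)
  out
}

conv_fwd <- function(X, p, meta) {
  Xcat <- im2col3(X, meta)
  list(Y = add_bias(Xcat %*% p$W, p$b), Xcat = Xcat, c_in = ncol(X))
}

conv_bwd <- function(dY, p, cache, meta) {
  dW <- crossprod(cache$Xcat, dY)
  c_in <- cache$c_in
  c_out <- ncol(dY)
  # dX(q)[c] = sum_k sum_o dY(q - d_k)[o] * W[(c-1)*9 + k, o]: gather dY with
  # the reversed offsets and multiply by W transposed within offset slots.
  dYcat <- im2col3(dY, meta, reverse = TRUE)
  V <- matrix(aperm(array(p$W, c(9L, c_in, c_out)), c(1, 3, 2)),
              9L * c_out, c_in)
  list(dX = dYcat %*% V, grad = list(W = dW, b = colSums(dY)))
}

conv1x1_fwd <- function(X, p) list(Y = add_bias(X %*% p$W, p$b), X = X)

conv1x1_bwd <- function(dY, p, cache) {
  list(dX = dY %*% t(p$W),
       grad = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

bn_fwd <- function(X, p, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- .colMeans(X, nrow(X), ncol(X))
    v <- pmax(.colMeans(X * X, nrow(X), ncol(X)) - mu^2, 0)
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
    p$run_var <- (1 - momentum) * p$run_var + momentum * v
  } else {
    mu <- p$run_mean
    v <- p$run_var
  }
  inv <- 1 / sqrt(v + eps)
  n <- nrow(X)
  # y = a x + b with a, b folded per channel; xhat is reconstructed lazily in
  # the backward pass (the cache holds X by reference, no copy)
  a <- p$gamma * inv
  b <- p$beta - mu * a
  Y <- X * rep(a, each = n) + rep(b, each = n)
  list(Y = Y, cache = list(X = X, mu = mu, inv = inv, training = training),
       p = p)
}

bn_bwd <- function(dY, p, cache) {
  n <- nrow(dY)
  xhat <- (cache$X - rep(cache$mu, each = n)) * rep(cache$inv, each = n)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  g_inv <- rep(p$gamma * cache$inv, each = n)
  if (cache$training) {
    m1 <- rep(dbeta / n, each = n)
    m2 <- rep(dgamma / n, each = n)
    dX <- g_inv * (dY - m1 - xhat * m2)
  } else {
    dX <- g_inv * dY
  }
  list(dX = dX, grad = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(X) {
  m <- X > 0
  list(Y = X * m, mask = m)
}

relu_bwd <- function(dY, mask) dY * mask

# 2x2 max pooling, stride 2. Index sets i[[a]] (a = 1..4) give, for each coarse
# position, the fine row of the window corner; the four sets are disjoint and
# cover the fine grid.
pool_indices <- function(H, W, N) {
  key <- paste("pool", H, W, N, sep = "_")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  h2 <- rep.int(seq_len(H2), W2)
  w2 <- rep(seq_len(W2), each = H2)
  HW <- H * W
  res <- vector("list", 4)
  a <- 0L
  for (db in 0:1) for (da in 0:1) {
    a <- a + 1L
    base <- (2L * h2 - 1L + da) + (2L * w2 - 2L + db) * H
    res[[a]] <- as.integer(rep(base, N) +
      rep.int((seq_len(N) - 1L) * HW, rep.int(H2 * W2, N)))
  }
  .idx_cache[[key]] <- res
  res
}

maxpool_fwd <- function(X, meta) {
  idx <- pool_indices(meta$H, meta$W, meta$N)
  best <- X[idx[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(best), ncol(best))
  for (a in 2:4) {
    G <- X[idx[[a]], , drop = FALSE]
    m <- G > best
    best[m] <- G[m]
    arg[m] <- a
  }
  list(Y = best, cache = list(arg = arg, n_fine = nrow(X)))
}

maxpool_bwd <- function(dY, cache, meta) {
  idx <- pool_indices(meta$H, meta$W, meta$N)
  dX <- matrix(0, cache$n_fine, ncol(dY))
  for (a in 1:4) {
    dX[idx[[a]], ] <- dY * (cache$arg == a)
  }
  dX
}

# Nearest-neighbour 2x upsampling: each coarse value is copied into its 2x2
# fine window; backward sums the window.
upsample_fwd <- function(X, meta_coarse) {
  H2 <- meta_coarse$H
  W2 <- meta_coarse$W
  N <- meta_coarse$N
  idx <- pool_indices(2L * H2, 2L * W2, N)
  Y <- matrix(0, 4L * H2 * W2 * N, ncol(X))
  for (a in 1:4) Y[idx[[a]], ] <- X
  Y
}

upsample_bwd <- function(dY, meta_coarse) {
  idx <- pool_indices(2L * meta_coarse$H, 2L * meta_coarse$W, meta_coarse$N)
  dX <- dY[idx[[1]], , drop = FALSE]
  for (a in 2:4) dX <- dX + dY[idx[[a]], , drop = FALSE]
  dX
}

softmax_rows <- function(Z) {
  m <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - m)
  E / rowSums(E)
}

# Recursive SGD-with-momentum update over nested parameter lists. Running
# batch-norm statistics are state, not parameters, and are skipped.
sgd_update <- function(params, grads, vel, lr, momentum) {
  if (is.numeric(params)) {
    if (is.null(vel)) vel <- params * 0
    vel <- momentum * vel - lr * grads
    return(list(p = params + vel, v = vel))
  }
  if (is.null(vel)) vel <- vector("list", length(params))
  nms <- names(params)
  for (i in seq_along(params)) {
    if (!is.null(nms) && nms[i] %in% c("run_mean", "run_var")) next
    g <- if (!is.null(nms) && !is.null(names(grads))) grads[[nms[i]]] else grads[[i]]
    if (is.null(g)) next
    r <- sgd_update(params[[i]], g, vel[[i]], lr, momentum)
    params[[i]] <- r$p
    vel[[i]] <- r$v
  }
  list(p = params, v = vel)
}
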
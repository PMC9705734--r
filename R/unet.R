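#' Network configuration
#'
#' Architecture hyper-parameters of the 2D U-Net pixel classifier. The
#' production-scale configuration is `input_size = 128`, `input_channels = 2`
#' (PET, CT), `initial_features = 128`, `depth = 4` and `num_classes = 16`,
#' giving encoder spatial sizes 128, 64, 32, 16 and a bottleneck of 8 x 8 with
#' `initial_features * 2^depth = 2048` channels. Feature size doubles at each
#' down-sampling stage.
#'
#' @param input_size In-plane slice size (must be divisible by `2^depth`).
#' @param input_channels Input channel count (2: PET and CT).
#' @param initial_features Channels at the first encoder stage.
#' @param depth Number of down-sampling (and mirrored up-sampling) stages.
#' @param num_classes Output classes (16 tissue classes).
#' @return A `network_config` object.
#' @export
network_config <- function(input_size = 128L, input_channels = 2L,
                           initial_features = 128L, depth = 4L,
                           num_classes = 16L) {
  if (input_size %% (2^depth) != 0) {
    stop("`input_size` (", input_size, ") must be divisible by 2^depth (",
         2^depth, ")")
  }
  structure(list(input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 initial_features = as.integer(initial_features),
                 depth = as.integer(depth),
                 num_classes = as.integer(num_classes)),
            class = "network_config")
}

#' U-Net layer-graph descriptor
#'
#' Describes the stages of the encoder-decoder without instantiating weights:
#' per-stage spatial sizes and channel counts, the bottleneck, and the
#' classification head (1 x 1 convolution to `num_classes` features, batch
#' normalisation, softmax). Encoder blocks are double 3 x 3 convolutions each
#' followed by batch normalisation and ReLU; decoder stages upsample, halve
#' the features, concatenate the mirrored encoder skip, and apply another
#' double convolution.
#'
#' @param config A [network_config()].
#' @return A `unet_descriptor` with a `stages` data frame, bottleneck summary
#'   and head description.
#' @export
#' @examples
#' d <- build_unet(network_config())
#' d$bottleneck_channels  # 2048
#' d$bottleneck_spatial   # 8
build_unet <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  dpt <- config$depth
  f <- config$initial_features * 2^(0:dpt)
  spatial <- config$input_size / 2^(0:dpt)
  enc <- data.frame(
    stage = c(paste0("encoder_", 0:(dpt - 1)), "bottleneck"),
    spatial = spatial, channels = f
  )
  dec <- data.frame(
    stage = paste0("decoder_", (dpt - 1):0),
    spatial = spatial[dpt:1], channels = f[dpt:1]
  )
  structure(list(
    config = config,
    stages = rbind(enc, dec),
    bottleneck_channels = f[dpt + 1],
    bottleneck_spatial = spatial[dpt + 1],
    output_channels = config$num_classes,
    head = "1x1 conv -> batch norm -> softmax",
    skip_style = "concatenation",
    note = paste("reported bottleneck shape 8 x 8 x 2 x 2048 contains an",
                 "extra '2' of unclear meaning; descriptor records spatial",
                 "8 x 8 and 2048 channels")
  ), class = "unet_descriptor")
}

#' Initialise U-Net weights
#'
#' He-initialised weights for the architecture described by the configuration.
#' The full production configuration has on the order of 10^8 parameters; use
#' reduced `initial_features`/`depth` for desk-scale training.
#'
#' @param config A [network_config()].
#' @param seed RNG seed for reproducible initialisation.
#' @return A `unet_model`.
#' @export
unet_init <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  set.seed(seed)
  dpt <- config$depth
  f <- config$initial_features * 2^(0:dpt)
  enc <- vector("list", dpt)
  c_in <- config$input_channels
  for (i in seq_len(dpt)) {
    enc[[i]] <- list(conv1 = conv_init(c_in, f[i]), bn1 = bn_init(f[i]),
                     conv2 = conv_init(f[i], f[i]), bn2 = bn_init(f[i]))
    c_in <- f[i]
  }
  bott <- list(conv1 = conv_init(f[dpt], f[dpt + 1]), bn1 = bn_init(f[dpt + 1]),
               conv2 = conv_init(f[dpt + 1], f[dpt + 1]), bn2 = bn_init(f[dpt + 1]))
  dec <- vector("list", dpt)
  for (i in dpt:1) {   # dec[[i]] works at encoder stage i's resolution
    dec[[i]] <- list(
      upconv = conv_init(f[i + 1], f[i]), bnu = bn_init(f[i]),
      conv1 = conv_init(2L * f[i], f[i]), bn1 = bn_init(f[i]),
      conv2 = conv_init(f[i], f[i]), bn2 = bn_init(f[i])
    )
  }
  head <- list(conv = conv1x1_init(f[1], config$num_classes),
               bn = bn_init(config$num_classes))
  structure(list(config = config, enc = enc, bott = bott, dec = dec,
                 head = head), class = "unet_model")
}

dconv_fwd <- function(X, blk, meta, training) {
  c1 <- conv_fwd(X, blk$conv1, meta)
  b1 <- bn_fwd(c1$Y, blk$bn1, training)
  blk$bn1 <- b1$p
  r1 <- relu_fwd(b1$Y)
  c2 <- conv_fwd(r1$Y, blk$conv2, meta)
  b2 <- bn_fwd(c2$Y, blk$bn2, training)
  blk$bn2 <- b2$p
  r2 <- relu_fwd(b2$Y)
  list(Y = r2$Y, blk = blk,
       cache = list(c1 = c1, b1 = b1$cache, m1 = r1$mask,
                    c2 = c2, b2 = b2$cache, m2 = r2$mask))
}

dconv_bwd <- function(dY, blk, cache, meta) {
  d <- relu_bwd(dY, cache$m2)
  b2 <- bn_bwd(d, blk$bn2, cache$b2)
  c2 <- conv_bwd(b2$dX, blk$conv2, cache$c2, meta)
  d <- relu_bwd(c2$dX, cache$m1)
  b1 <- bn_bwd(d, blk$bn1, cache$b1)
  c1 <- conv_bwd(b1$dX, blk$conv1, cache$c1, meta)
  list(dX = c1$dX,
       grad = list(conv1 = c1$grad, bn1 = b1$grad,
                   conv2 = c2$grad, bn2 = b2$grad))
}

#' Low-level U-Net forward pass
#'
#' Runs a batch of slices through the network. `X` is a dense
#' `(H*W*N) x input_channels` matrix (rows over spatial positions, row index
#' fastest, then column, then image). Returns the per-pixel class posteriors,
#' the layer caches needed by [unet_backward()], and the model with updated
#' batch-normalisation running statistics.
#'
#' @param model A `unet_model` from [unet_init()].
#' @param X Input matrix.
#' @param n_images Number of images in the batch.
#' @param training Use batch statistics (TRUE) or running statistics (FALSE).
#' @return List with `probs`, `caches`, `model`.
#' @export
unet_forward <- function(model, X, n_images, training = FALSE) {
  cfg <- model$config
  dpt <- cfg$depth
  meta <- list(H = cfg$input_size, W = cfg$input_size, N = as.integer(n_images))
  caches <- list(enc = vector("list", dpt), dec = vector("list", dpt))
  skips <- vector("list", dpt)
  for (i in seq_len(dpt)) {
    r <- dconv_fwd(X, model$enc[[i]], meta, training)
    model$enc[[i]] <- r$blk
    skips[[i]] <- r$Y
    p <- maxpool_fwd(r$Y, meta)
    caches$enc[[i]] <- list(dc = r$cache, pool = p$cache, meta = meta)
    X <- p$Y
    meta <- list(H = meta$H %/% 2L, W = meta$W %/% 2L, N = meta$N)
  }
  r <- dconv_fwd(X, model$bott, meta, training)
  model$bott <- r$blk
  caches$bott <- list(dc = r$cache, meta = meta)
  X <- r$Y
  for (i in dpt:1) {
    meta_coarse <- meta
    X <- upsample_fwd(X, meta_coarse)
    meta <- list(H = 2L * meta$H, W = 2L * meta$W, N = meta$N)
    cu <- conv_fwd(X, model$dec[[i]]$upconv, meta)
    bu <- bn_fwd(cu$Y, model$dec[[i]]$bnu, training)
    model$dec[[i]]$bnu <- bu$p
    ru <- relu_fwd(bu$Y)
    Xcat <- cbind(ru$Y, skips[[i]])
    r <- dconv_fwd(Xcat, model$dec[[i]], meta, training)
    model$dec[[i]] <- r$blk
    caches$dec[[i]] <- list(cu = cu, bu = bu$cache, mu = ru$mask, dc = r$cache,
                            meta = meta, meta_coarse = meta_coarse,
                            n_up = ncol(ru$Y))
    X <- r$Y
  }
  ch <- conv1x1_fwd(X, model$head$conv)
  bh <- bn_fwd(ch$Y, model$head$bn, training)
  model$head$bn <- bh$p
  caches$head <- list(ch = ch, bh = bh$cache)
  list(probs = softmax_rows(bh$Y), caches = caches, model = model)
}

#' Low-level U-Net backward pass
#'
#' Backpropagates the loss gradient `dZ` (w.r.t. the softmax input, e.g. from
#' [wce_gradient()]) through the cached forward pass, returning gradients
#' that mirror the parameter tree.
#'
#' @param model A `unet_model`.
#' @param caches Layer caches from [unet_forward()] (run with
#'   `training = TRUE`).
#' @param dZ Gradient matrix (pixels x classes).
#' @return Nested list of parameter gradients.
#' @export
unet_backward <- function(model, caches, dZ) {
  dpt <- model$config$depth
  grads <- list(enc = vector("list", dpt), dec = vector("list", dpt))
  bh <- bn_bwd(dZ, model$head$bn, caches$head$bh)
  ch <- conv1x1_bwd(bh$dX, model$head$conv, caches$head$ch)
  grads$head <- list(conv = ch$grad, bn = bh$grad)
  dX <- ch$dX
  dskip <- vector("list", dpt)
  for (i in seq_len(dpt)) {
    cc <- caches$dec[[i]]
    r <- dconv_bwd(dX, model$dec[[i]], cc$dc, cc$meta)
    grads$dec[[i]] <- r$grad
    d_up <- r$dX[, seq_len(cc$n_up), drop = FALSE]
    dskip[[i]] <- r$dX[, -seq_len(cc$n_up), drop = FALSE]
    d_up <- relu_bwd(d_up, cc$mu)
    bu <- bn_bwd(d_up, model$dec[[i]]$bnu, cc$bu)
    cu <- conv_bwd(bu$dX, model$dec[[i]]$upconv, cc$cu, cc$meta)
    grads$dec[[i]]$bnu <- bu$grad
    grads$dec[[i]]$upconv <- cu$grad
    dX <- upsample_bwd(cu$dX, cc$meta_coarse)
  }
  r <- dconv_bwd(dX, model$bott, caches$bott$dc, caches$bott$meta)
  grads$bott <- r$grad
  dX <- r$dX
  for (i in dpt:1) {
    cc <- caches$enc[[i]]
    dX <- maxpool_bwd(dX, cc$pool, cc$meta)
    dX <- dX + dskip[[i]]
    r <- dconv_bwd(dX, model$enc[[i]], cc$dc, cc$meta)
    grads$enc[[i]] <- r$grad
    dX <- r$dX
  }
  grads
}

#' Class-weighted cross-entropy loss
#'
#' Weighted-mean reduction of the per-pixel cross-entropy: each pixel
#' contributes `-w[c(p)] * log posterior[c(p)]` and the sum is normalised by
#' the summed weights, so uniform weights reduce to the plain mean
#' cross-entropy. Posteriors are clamped at `eps` before the log.
#'
#' @param posteriors Matrix (pixels x classes) of per-pixel class posteriors
#'   (rows sum to 1).
#' @param truth Integer vector of zero-based true class indices per pixel.
#' @param weights Per-class positive weights (length = classes); default
#'   uniform.
#' @param eps Posterior clamp.
#' @return Scalar loss (>= 0; 0 iff the posteriors are one-hot correct).
#' @export
weighted_cross_entropy <- function(posteriors, truth,
                                   weights = rep(1, ncol(posteriors)),
                                   eps = 1e-12) {
  stopifnot(length(truth) == nrow(posteriors),
            length(weights) == ncol(posteriors))
  p_true <- posteriors[cbind(seq_along(truth), as.integer(truth) + 1L)]
  w <- weights[as.integer(truth) + 1L]
  if (sum(w) <= 0) stop("all pixel weights are zero")
  sum(-w * log(pmax(p_true, eps))) / sum(w)
}

#' Gradient of the weighted cross-entropy w.r.t. the softmax input
#'
#' @inheritParams weighted_cross_entropy
#' @return Matrix of the same shape as `posteriors`.
#' @export
wce_gradient <- function(posteriors, truth, weights) {
  n <- nrow(posteriors)
  w <- weights[as.integer(truth) + 1L]
  onehot <- matrix(0, n, ncol(posteriors))
  onehot[cbind(seq_len(n), as.integer(truth) + 1L)] <- 1
  (posteriors - onehot) * (w / sum(w))
}
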
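# Training strategy: study-level K-fold planning, per-epoch random affine
# augmentation, SGDM training loop, and volume prediction.

# Fixed input scaling applied to the integer-encoded channels before the
# network: PET/100 (back to SUL units), CT/1000 (HU offset in thousands).
# Keeps both channels at order-1 magnitude.
input_scale <- function() c(pet = 100, ct = 1000)

#' Study-level K-fold plan
#'
#' Shuffles the study ids with the given seed and partitions them into `2K`
#' near-equal groups; fold `i` uses group `i` as the test partition, group
#' `K + i` as validation, and the remaining `2K - 2` groups as training. With
#' 130 studies and K = 5 this yields 104/13/13 train/validation/test studies
#' per fold. Partitions are study-level, so slices of one study never appear
#' in two partitions of the same fold, and no study is tested in more than
#' one fold.
#'
#' @param study_ids Character or integer vector of unique study ids.
#' @param K Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return A `fold_plan`: list of `K` folds, each with `train`, `validation`,
#'   `test` id vectors.
#' @export
kfold_split <- function(study_ids, K = 5L, seed = 1L) {
  if (anyDuplicated(study_ids)) stop("duplicate study ids")
  n <- length(study_ids)
  if (n < 2L * K) stop("need at least 2K studies")
  set.seed(seed)
  shuffled <- sample(study_ids)
  group <- rep(seq_len(2L * K), length.out = n)  # round-robin -> near-equal
  folds <- lapply(seq_len(K), function(i) {
    test <- shuffled[group == i]
    validation <- shuffled[group == K + i]
    list(train = setdiff(shuffled, c(test, validation)),
         validation = validation, test = test)
  })
  structure(list(K = as.integer(K), folds = folds, study_ids = study_ids),
            class = "fold_plan")
}

#' Augmentation configuration
#'
#' Random in-plane affine augmentation drawn independently per image per
#' epoch: translation within +/- `translate_px` pixels, rotation within
#' +/- `rotate_deg` degrees, scaling within `scale_range` (50% to 200% of the
#' original size by default). The identical transform is applied to both
#' channels and the label slice, all with nearest-neighbour resampling so no
#' new label values appear.
#'
#' @param translate_px Max absolute translation (pixels).
#' @param rotate_deg Max absolute rotation (degrees).
#' @param scale_range Length-2 multiplicative scale range.
#' @return An `augmentation_config`.
#' @export
augmentation_config <- function(translate_px = 5, rotate_deg = 10,
                                scale_range = c(0.5, 2.0)) {
  stopifnot(translate_px >= 0, rotate_deg >= 0, length(scale_range) == 2,
            scale_range[1] <= scale_range[2], scale_range[1] > 0)
  structure(list(translate_px = translate_px, rotate_deg = rotate_deg,
                 scale_range = scale_range), class = "augmentation_config")
}

# Inverse-mapped nearest-neighbour affine about the image centre;
# out-of-frame pixels take `fill`.
affine_nearest <- function(mat, scale, theta_rad, tx, ty, fill = 0L) {
  H <- nrow(mat)
  W <- ncol(mat)
  cy <- (H + 1) / 2
  cx <- (W + 1) / 2
  r <- rep.int(seq_len(H), W) - cy
  c <- rep(seq_len(W), each = H) - cx
  ct <- cos(theta_rad)
  st <- sin(theta_rad)
  # inverse transform: undo translation, rotation, scale
  ry <- r - ty
  cxv <- c - tx
  sy <- ( ct * ry + st * cxv) / scale + cy
  sx <- (-st * ry + ct * cxv) / scale + cx
  si <- as.integer(round(sy))
  sj <- as.integer(round(sx))
  ok <- si >= 1L & si <= H & sj >= 1L & sj <= W
  out <- rep(fill, H * W)
  out[ok] <- mat[cbind(si[ok], sj[ok])]
  matrix(out, H, W)
}

#' Augment a training sample
#'
#' Draws one affine transform from the configuration using the current RNG
#' state and applies it identically to the PET channel, the CT channel and the
#' label slice. A configuration with zero ranges and unit scale returns the
#' sample bit-identically.
#'
#' @param sample A `training_sample`.
#' @param cfg An [augmentation_config()], or `NULL` for identity.
#' @return The augmented `training_sample`.
#' @export
augment_sample <- function(sample, cfg = augmentation_config()) {
  if (is.null(cfg)) return(sample)
  tx <- stats::runif(1, -cfg$translate_px, cfg$translate_px)
  ty <- stats::runif(1, -cfg$translate_px, cfg$translate_px)
  th <- stats::runif(1, -cfg$rotate_deg, cfg$rotate_deg) * pi / 180
  sc <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
  if (tx == 0 && ty == 0 && th == 0 && sc == 1) return(sample)
  sample$pet_channel <- affine_nearest(sample$pet_channel, sc, th, tx, ty, 0L)
  sample$ct_channel <- affine_nearest(sample$ct_channel, sc, th, tx, ty, 0L)
  sample$label_slice <- affine_nearest(sample$label_slice, sc, th, tx, ty,
                                       class_index("Background"))
  sample
}

#' Training configuration
#'
#' Solver settings for stochastic gradient descent with momentum (SGDM).
#'
#' @param learning_rate SGD learning rate (> 0).
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param batch_size Mini-batch size (images).
#' @param epochs Training epochs.
#' @param seed RNG seed covering shuffling and augmentation.
#' @param class_weights Per-class loss weights (see [class_weights()]);
#'   default uniform.
#' @param augmentation An [augmentation_config()] or `NULL` to disable.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         batch_size = 16L, epochs = 10L, seed = 1L,
                         class_weights = NULL, augmentation = NULL) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 class_weights = class_weights, augmentation = augmentation),
            class = "train_config")
}

samples_to_matrix <- function(samples) {
  sc <- input_scale()
  X <- do.call(rbind, lapply(samples, function(s) {
    cbind(as.numeric(s$pet_channel) / sc["pet"],
          as.numeric(s$ct_channel) / sc["ct"])
  }))
  truth <- unlist(lapply(samples, function(s) as.integer(s$label_slice)),
                  use.names = FALSE)
  list(X = X, truth = truth)
}

eval_loss <- function(model, samples, weights, batch = 16L) {
  tot <- 0
  n <- 0
  for (i in seq(1, length(samples), by = batch)) {
    sub <- samples[i:min(i + batch - 1L, length(samples))]
    d <- samples_to_matrix(sub)
    out <- unet_forward(model, d$X, length(sub), training = FALSE)
    tot <- tot + weighted_cross_entropy(out$probs, d$truth, weights) * length(sub)
    n <- n + length(sub)
  }
  tot / n
}

#' Train the U-Net on one fold
#'
#' SGDM training with per-epoch shuffling and (optionally) random affine
#' augmentation, class-weighted cross-entropy loss, per-epoch training and
#' validation loss logging, and retention of the best-validation checkpoint.
#' Deterministic given the seed.
#'
#' @param fold One fold of a [kfold_split()] plan (list with `train`,
#'   `validation` study-id vectors), or `NULL` to train on all samples with a
#'   validation split of none (validation loss then equals training loss).
#' @param samples List of `training_sample` objects (with `study_id` fields
#'   matching the fold ids).
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @return A `trained_unet`: `model` (best-validation weights), `final_model`,
#'   `history` (data frame epoch/train_loss/val_loss), `config`s.
#' @export
train_unet <- function(fold, samples, net_cfg, train_cfg = train_config()) {
  ids <- vapply(samples, `[[`, "", "study_id")
  if (is.null(fold)) {
    tr <- samples
    va <- samples
  } else {
    tr <- samples[ids %in% fold$train]
    va <- samples[ids %in% fold$validation]
  }
  if (length(tr) == 0L) stop("empty training partition")
  if (length(va) == 0L) stop("empty validation partition")
  ncls <- net_cfg$num_classes
  w <- train_cfg$class_weights
  if (is.null(w)) w <- rep(1, ncls)
  stopifnot(length(w) == ncls)
  present <- sort(unique(unlist(lapply(tr, function(s)
    unique(as.integer(s$label_slice))))))
  if (length(present) < 2L) stop("training samples must cover >= 2 classes")

  model <- unet_init(net_cfg, seed = train_cfg$seed)
  set.seed(train_cfg$seed + 1L)
  vel <- NULL
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, model = model)
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- sample(length(tr))
    ep_loss <- 0
    ep_n <- 0
    for (i in seq(1, length(tr), by = train_cfg$batch_size)) {
      sub <- tr[ord[i:min(i + train_cfg$batch_size - 1L, length(tr))]]
      if (!is.null(train_cfg$augmentation)) {
        sub <- lapply(sub, augment_sample, cfg = train_cfg$augmentation)
      }
      d <- samples_to_matrix(sub)
      out <- unet_forward(model, d$X, length(sub), training = TRUE)
      model <- out$model
      loss <- weighted_cross_entropy(out$probs, d$truth, w)
      dZ <- wce_gradient(out$probs, d$truth, w)
      grads <- unet_backward(model, out$caches, dZ)
      up <- sgd_update(model[c("enc", "bott", "dec", "head")], grads,
                       vel, train_cfg$learning_rate, train_cfg$momentum)
      model[c("enc", "bott", "dec", "head")] <- up$p
      vel <- up$v
      ep_loss <- ep_loss + loss * length(sub)
      ep_n <- ep_n + length(sub)
    }
    vl <- eval_loss(model, va, w, train_cfg$batch_size)
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                         val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, model = model)
  }
  structure(list(model = best$model, final_model = model, history = history,
                 net_config = net_cfg, train_config = train_cfg,
                 class_weights = w),
            class = "trained_unet")
}

#' Predict a label volume
#'
#' Runs every transaxial slice of a preprocessed PET/CT pair through the
#' network (inference mode), takes the per-pixel argmax over the class
#' posteriors, and restacks the slices into a label volume co-registered with
#' the input.
#'
#' @param trained A `trained_unet` (or bare `unet_model`).
#' @param pet,ct Preprocessed co-registered `scalar_volume`s whose in-plane
#'   size equals the network input size.
#' @param batch_size Slices per forward batch.
#' @return A `label_volume` of predicted tissue classes.
#' @export
predict_volume <- function(trained, pet, ct, batch_size = 16L) {
  model <- if (inherits(trained, "trained_unet")) trained$model else trained
  cfg <- model$config
  stopifnot_same_geometry(pet, ct, "PET and CT")
  d <- dim(pet$values)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop("in-plane size ", d[1], "x", d[2], " does not match network input ",
         cfg$input_size)
  }
  sc <- input_scale()
  out <- array(0L, d)
  for (i in seq(1, d[3], by = batch_size)) {
    ks <- i:min(i + batch_size - 1L, d[3])
    X <- do.call(rbind, lapply(ks, function(k) {
      enc <- encode_channels(pet$values[, , k], ct$values[, , k])
      cbind(as.numeric(enc$pet) / sc["pet"], as.numeric(enc$ct) / sc["ct"])
    }))
    fw <- unet_forward(model, X, length(ks), training = FALSE)
    pred <- max.col(fw$probs, ties.method = "first") - 1L
    out[, , ks] <- array(pred, c(d[1], d[2], length(ks)))
  }
  label_volume(out, pet$spacing, pet$origin)
}
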
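test_that("the default architecture reproduces the stated stage arithmetic", {
  d <- build_unet(network_config())
  expect_equal(d$bottleneck_channels, 2048)
  expect_equal(d$bottleneck_spatial, 8)
  expect_equal(d$output_channels, 16)
  enc <- d$stages[1:5, ]
  expect_equal(enc$spatial, c(128, 64, 32, 16, 8))
  expect_equal(enc$channels, c(128, 256, 512, 1024, 2048))
  # channels(d) = 128 * 2^d and spatial(d) = 128 / 2^d for every stage
  for (k in 0:4) {
    expect_equal(enc$channels[k + 1], 128 * 2^k)
    expect_equal(enc$spatial[k + 1], 128 / 2^k)
  }
  expect_error(network_config(input_size = 100L, depth = 4L), "divisible")
})

test_that("per-pixel class posteriors are normalised", {
  cfg <- network_config(16L, 2L, 4L, 2L, 16L)
  model <- unet_init(cfg, seed = 3)
  set.seed(4)
  X <- matrix(rnorm(16 * 16 * 3 * 2), ncol = 2)
  out <- unet_forward(model, X, 3, training = TRUE)
  expect_equal(dim(out$probs), c(16 * 16 * 3, 16))
  expect_true(all(abs(rowSums(out$probs) - 1) < 1e-6))
})

test_that("weighted cross-entropy reduces correctly", {
  # perfect one-hot prediction -> loss 0
  p <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(weighted_cross_entropy(p, c(0L, 1L)), 0, tolerance = 1e-9)
  # uniform weights equal the unweighted mean cross-entropy
  set.seed(9)
  q <- matrix(runif(40), 10)
  q <- q / rowSums(q)
  tr <- sample(0:3, 10, TRUE)
  expect_equal(weighted_cross_entropy(q, tr, rep(1, 4)),
               mean(-log(q[cbind(1:10, tr + 1)])))
  expect_equal(weighted_cross_entropy(q, tr, rep(7, 4)),
               weighted_cross_entropy(q, tr, rep(1, 4)))
  # single pixel, posterior 0.5 at truth, weight 2 -> log 2
  expect_equal(weighted_cross_entropy(matrix(c(0.5, 0.5), 1), 0L, c(2, 1)),
               log(2))
})

test_that("analytic gradients match finite differences through the whole net", {
  cfg <- network_config(8L, 2L, 3L, 2L, 4L)
  model <- unet_init(cfg, seed = 9)
  set.seed(5)
  X <- matrix(rnorm(8 * 8 * 2 * 2), ncol = 2)
  truth <- sample(0:3, 8 * 8 * 2, TRUE)
  w <- c(1, 2, 0.5, 1.5)
  loss_fn <- function(m) {
    weighted_cross_entropy(unet_forward(m, X, 2, training = TRUE)$probs,
                           truth, w)
  }
  out <- unet_forward(model, X, 2, training = TRUE)
  grads <- unet_backward(model, out$caches,
                         wce_gradient(out$probs, truth, w))
  probes <- list(
    list(c("enc", 1, "conv1", "W"), 7, 2),
    list(c("enc", 2, "conv2", "W"), 20, 3),
    list(c("bott", "conv1", "W"), 40, 5),
    list(c("dec", 2, "upconv", "W"), 11, 1),
    list(c("dec", 1, "conv1", "W"), 33, 2),
    list(c("dec", 1, "bn1", "gamma"), 2, NA),
    list(c("enc", 1, "bn2", "beta"), 1, NA),
    list(c("head", "conv", "W"), 2, 3),
    list(c("head", "bn", "gamma"), 4, NA)
  )
  eps <- 1e-6
  for (pr in probes) {
    path <- pr[[1]]
    getv <- function(tree) {
      for (p in path) tree <- tree[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
      if (is.na(pr[[3]])) tree[pr[[2]]] else tree[pr[[2]], pr[[3]]]
    }
    setv <- function(tree, val) {
      modify <- function(node, depth) {
        if (depth > length(path)) stop("bad path")
        key <- path[depth]
        key <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
        if (depth == length(path)) {
          if (is.na(pr[[3]])) node[[key]][pr[[2]]] <- val
          else node[[key]][pr[[2]], pr[[3]]] <- val
        } else {
          node[[key]] <- modify(node[[key]], depth + 1)
        }
        node
      }
      modify(tree, 1)
    }
    v0 <- getv(model)
    num <- (loss_fn(setv(model, v0 + eps)) - loss_fn(setv(model, v0 - eps))) /
      (2 * eps)
    ana <- getv(grads)
    expect_lt(abs(ana - num) / max(abs(num), 1e-6), 1e-4)
  }
})

test_that("study-level folds have the stated sizes and disjointness", {
  ids <- sprintf("study%03d", 1:130)
  plan <- kfold_split(ids, K = 5, seed = 7)
  tested <- character()
  for (f in plan$folds) {
    expect_length(f$train, 104)
    expect_length(f$validation, 13)
    expect_length(f$test, 13)
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$validation, f$test), 0)
    expect_setequal(c(f$train, f$validation, f$test), ids)
    tested <- c(tested, f$test)
  }
  # no study is tested in more than one fold
  expect_false(anyDuplicated(tested) > 0)
  expect_error(kfold_split(c("a", "a", "b"), K = 1), "duplicate")
  expect_error(kfold_split(letters[1:5], K = 5), "at least")
})

test_that("augmentation applies one shared transform and keeps the vocabulary", {
  s <- structure(list(
    pet_channel = matrix(sample(0:500, 32 * 32, TRUE), 32),
    ct_channel = matrix(sample(0:2000, 32 * 32, TRUE), 32),
    label_slice = matrix(sample(c(0L, 1L, 9L), 32 * 32, TRUE), 32),
    study_id = "s", slice_index = 1L), class = "training_sample")
  # degenerate config: identity
  idcfg <- augmentation_config(0, 0, c(1, 1))
  expect_identical(augment_sample(s, idcfg), s)
  expect_identical(augment_sample(s, NULL), s)
  # same seed -> same augmented output; labels keep their vocabulary
  set.seed(11)
  a1 <- augment_sample(s)
  set.seed(11)
  a2 <- augment_sample(s)
  expect_identical(a1, a2)
  expect_true(all(unique(as.integer(a1$label_slice)) %in% c(0L, 1L, 9L)))
  # geometry contract unchanged
  expect_identical(dim(a1$pet_channel), dim(s$pet_channel))
})

test_that("a tiny network learns and can overfit a handful of slices", {
  set.seed(13)
  # synthetic 16x16 two-class slices: bright square in a dark field
  mk <- function(i) {
    pet <- matrix(50L, 16, 16)
    lab <- matrix(0L, 16, 16)
    r <- 4:11 + (i %% 3)
    pet[r, r] <- 500L
    lab[r, r] <- 1L
    structure(list(pet_channel = pet, ct_channel = matrix(1024L, 16, 16),
                   label_slice = lab, study_id = paste0("s", i),
                   slice_index = 1L), class = "training_sample")
  }
  samples <- lapply(1:5, mk)
  cfg <- network_config(16L, 2L, 4L, 2L, 16L)
  tc <- train_config(learning_rate = 0.05, momentum = 0.9, batch_size = 5L,
                     epochs = 40L, seed = 17L)
  fit <- train_unet(NULL, samples, cfg, tc)
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
  # overfit sanity: training pixel accuracy above 0.99
  d <- do.call(rbind, lapply(samples, function(s)
    cbind(as.numeric(s$pet_channel) / 100, as.numeric(s$ct_channel) / 1000)))
  truth <- unlist(lapply(samples, function(s) as.integer(s$label_slice)))
  probs <- unet_forward(fit$model, d, 5, training = FALSE)$probs
  acc <- mean(max.col(probs) - 1L == truth)
  expect_gt(acc, 0.99)
})

test_that("training rejects degenerate partitions and one-class data", {
  s <- structure(list(pet_channel = matrix(0L, 16, 16),
                      ct_channel = matrix(0L, 16, 16),
                      label_slice = matrix(0L, 16, 16),
                      study_id = "a", slice_index = 1L),
                 class = "training_sample")
  cfg <- network_config(16L, 2L, 4L, 2L, 16L)
  fold <- list(train = "a", validation = "zzz", test = character())
  expect_error(train_unet(fold, list(s), cfg), "empty validation")
  expect_error(train_unet(NULL, list(s), cfg), ">= 2 classes")
})

test_that("volume prediction restacks slices on the input geometry", {
  cfg <- network_config(16L, 2L, 4L, 2L, 16L)
  model <- unet_init(cfg, seed = 23)
  pet <- volume_with(c(16, 16, 5), base = 1, spacing = c(3.5, 3.5, 3.5))
  ct <- scalar_volume(array(0, c(16, 16, 5)), c(3.5, 3.5, 3.5), units = "HU")
  pred <- predict_volume(model, pet, ct)
  expect_s3_class(pred, "label_volume")
  expect_equal(dim(pred$labels), c(16, 16, 5))
  expect_true(all(pred$labels >= 0 & pred$labels <= 15))
  expect_equal(pred$spacing, pet$spacing)
  bad <- scalar_volume(array(0, c(16, 16, 4)), c(3.5, 3.5, 3.5), units = "HU")
  expect_error(predict_volume(model, pet, bad), "co-registered")
  wrong <- volume_with(c(20, 20, 3), base = 1)
  expect_error(predict_volume(model, wrong,
                              scalar_volume(array(0, c(20, 20, 3)), c(1, 1, 1),
                                            units = "HU")),
               "does not match network input")
})
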
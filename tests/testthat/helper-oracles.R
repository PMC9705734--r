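# Independent brute-force oracles. These deliberately use literal per-voxel
# loops (no shared code with the package implementations).

# Literal step simulator for Round-Robin growth: (a) annex every pool voxel
# face-adjacent to a grow-class region (the neighbour with the highest PET
# wins contention, ties to the lower class index), then (b) erode the pool by
# one voxel (a voxel survives only if all six face neighbours exist and are in
# the pool); repeat until an annexation step does nothing.
oracle_rr_grow <- function(labels, pet, threshold, grow_idx,
                           nominal = class_index("Nominal")) {
  d <- dim(labels)
  nb6 <- function(i, j, k) {
    out <- list()
    if (i > 1) out[[length(out) + 1]] <- c(i - 1, j, k)
    if (i < d[1]) out[[length(out) + 1]] <- c(i + 1, j, k)
    if (j > 1) out[[length(out) + 1]] <- c(i, j - 1, k)
    if (j < d[2]) out[[length(out) + 1]] <- c(i, j + 1, k)
    if (k > 1) out[[length(out) + 1]] <- c(i, j, k - 1)
    if (k < d[3]) out[[length(out) + 1]] <- c(i, j, k + 1)
    out
  }
  pool <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    pool[i, j, k] <- labels[i, j, k] == nominal && pet[i, j, k] >= threshold
  }
  repeat {
    annex <- list()
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (!pool[i, j, k]) next
      best_val <- -Inf
      best_cls <- Inf
      for (nb in nb6(i, j, k)) {
        cl <- labels[nb[1], nb[2], nb[3]]
        if (!(cl %in% grow_idx)) next
        pv <- pet[nb[1], nb[2], nb[3]]
        if (pv > best_val || (pv == best_val && cl < best_cls)) {
          best_val <- pv
          best_cls <- cl
        }
      }
      if (is.finite(best_val)) {
        annex[[length(annex) + 1]] <- c(i, j, k, best_cls)
      }
    }
    if (length(annex) == 0) break
    for (a in annex) {
      labels[a[1], a[2], a[3]] <- a[4]
      pool[a[1], a[2], a[3]] <- FALSE
    }
    new_pool <- array(FALSE, d)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (!pool[i, j, k]) next
      nbs <- nb6(i, j, k)
      if (length(nbs) < 6) next  # grid boundary: erosion removes it
      keep <- TRUE
      for (nb in nbs) {
        if (!pool[nb[1], nb[2], nb[3]]) { keep <- FALSE; break }
      }
      new_pool[i, j, k] <- keep
    }
    pool <- new_pool
  }
  labels
}

# Brute-force one-vs-rest voxel counting.
oracle_class_counts <- function(pred, truth, cls) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == cls
    t <- truth[i] == cls
    if (p && t) tp <- tp + 1
    else if (p && !t) fp <- fp + 1
    else if (!p && t) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force Dice/Jaccard on two masks.
oracle_overlap <- function(a, b) {
  inter <- sum(a & b)
  list(dice = 2 * inter / (sum(a) + sum(b)),
       jaccard = inter / sum(a | b))
}

# Brute-force enumeration of voxel offsets inside a sphere of radius r (mm).
oracle_kernel_size <- function(radius_mm, spacing) {
  count <- 0
  r <- ceiling(radius_mm / min(spacing))
  for (i in -r:r) for (j in -r:r) for (k in -r:r) {
    if ((i * spacing[1])^2 + (j * spacing[2])^2 + (k * spacing[3])^2 <=
        radius_mm^2) {
      count <- count + 1
    }
  }
  count
}

# Random label/PET fields with seeded grow-class regions, for the Round-Robin
# equivalence property.
random_growth_case <- function(dim, n_seeds = 2, seed = 1) {
  set.seed(seed)
  pet <- array(runif(prod(dim), 0, 4), dim)
  labels <- array(class_index("Nominal"), dim)
  grow_classes <- sample(tissue_class_names(), n_seeds)
  for (cls in grow_classes) {
    ctr <- sapply(dim, function(n) sample(seq_len(n), 1))
    labels[ctr[1], ctr[2], ctr[3]] <- class_index(cls)
  }
  # scatter some Background to exercise non-growable labels
  bg <- sample(prod(dim), max(1, prod(dim) %/% 20))
  bg <- bg[labels[bg] == class_index("Nominal")]
  labels[bg] <- class_index("Background")
  list(labels = labels, pet = pet,
       threshold = runif(1, 0.5, 3.0),
       grow_classes = unique(grow_classes))
}
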
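#' Threshold-based candidate segmentation
#'
#' Segments all 6-connected clusters of voxels at or above the threshold and
#' retains those with at least `min_size` voxels (the workflow's >= 7-voxel
#' rule). Candidates are returned sorted by descending peak SUL.
#'
#' @param pet `scalar_volume` in SUL.
#' @param threshold Segmentation threshold in SUL (> 0), typically the PERCIST
#'   baseline assessment threshold.
#' @param min_size Minimum cluster size in voxels (default 7).
#' @return List of `candidate_component` objects, each with `voxels` (linear
#'   indices into the volume), `size`, `peak_sul` and `assigned_class`
#'   (initially `NA`; set by classification).
#' @export
segment_candidates <- function(pet, threshold, min_size = 7L) {
  stopifnot(inherits(pet, "scalar_volume"), pet$units == "SUL")
  if (!is.finite(threshold) || threshold <= 0) stop("`threshold` must be > 0")
  comp <- connected_components(pet$values >= threshold)
  k <- max(comp)
  if (k == 0L) return(list())
  sizes <- tabulate(comp[comp > 0L], nbins = k)
  keep <- which(sizes >= min_size)
  out <- lapply(keep, function(i) {
    vox <- which(comp == i)
    structure(list(id = NA_integer_, voxels = vox, size = length(vox),
                   peak_sul = max(pet$values[vox]),
                   assigned_class = NA_character_),
              class = "candidate_component")
  })
  out <- out[order(vapply(out, `[[`, 0, "peak_sul"), decreasing = TRUE)]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Assign tissue classes to candidate components
#'
#' In the production workflow the CNN classifies tissue; for training-data
#' preparation the class of each candidate is supplied externally (standing in
#' for expert reader classification), either as a data frame / CSV of
#' `(component, class)` pairs or derived from a reference label volume by
#' majority overlap.
#'
#' @param components List from [segment_candidates()].
#' @param assignments Data frame with columns `component` (id) and `class`
#'   (vocabulary name).
#' @return The component list with `assigned_class` filled in.
#' @export
assign_classes <- function(components, assignments) {
  stopifnot(is.data.frame(assignments),
            all(c("component", "class") %in% names(assignments)))
  class_index(assignments$class)  # validates names
  for (i in seq_along(components)) {
    j <- match(components[[i]]$id, assignments$component)
    if (is.na(j)) stop("no class assignment for component ", components[[i]]$id)
    components[[i]]$assigned_class <- assignments$class[j]
  }
  components
}

#' @rdname assign_classes
#' @param truth A reference `label_volume`; each candidate receives the
#'   majority class of its voxels there (majority `Background`/`Nominal`
#'   voxels fall back to the most frequent non-trivial class if one covers at
#'   least a quarter of the component, else `Not_Significant`).
#' @export
assign_classes_from_truth <- function(components, truth) {
  stopifnot(inherits(truth, "label_volume"))
  trivial <- class_index(c("Background", "Nominal"), truth$vocabulary)
  for (i in seq_along(components)) {
    labs <- truth$labels[components[[i]]$voxels]
    tab <- sort(table(labs), decreasing = TRUE)
    top <- as.integer(names(tab))
    cls <- top[1]
    if (cls %in% trivial) {
      nt <- top[!(top %in% trivial)]
      cls <- if (length(nt) > 0 &&
                 tab[as.character(nt[1])] >= components[[i]]$size / 4) {
        nt[1]
      } else {
        class_index("Not_Significant", truth$vocabulary)
      }
    }
    components[[i]]$assigned_class <- class_name(cls, truth$vocabulary)
  }
  components
}

#' Assemble the initial label map
#'
#' Builds a complete voxel partition: `Background` outside the body contour,
#' `Nominal` inside, the liver reference VOI as `Reference`, and each
#' classified candidate component with its assigned class. Overlap between
#' components, or between a component and the reference VOI, is an error.
#'
#' @param pet `scalar_volume` in SUL (supplies geometry).
#' @param body Logical body mask.
#' @param reference_voi [sphere_voi()] of the liver reference.
#' @param components Classified candidate list (all `assigned_class` set).
#' @return A `label_volume` partitioning every voxel.
#' @export
assemble_label_map <- function(pet, body, reference_voi, components = list()) {
  stopifnot(inherits(pet, "scalar_volume"))
  labs <- array(class_index("Background"), dim(pet$values))
  labs[body] <- class_index("Nominal")
  ref <- which(sphere_mask(pet, reference_voi))
  seen <- integer(0)
  for (cmp in components) {
    if (is.na(cmp$assigned_class)) {
      stop("component ", cmp$id, " has no assigned class")
    }
    if (length(intersect(cmp$voxels, ref)) > 0) {
      stop("component ", cmp$id, " overlaps the Reference VOI")
    }
    if (length(intersect(cmp$voxels, seen)) > 0) {
      stop("components overlap: component ", cmp$id,
           " shares voxels with an earlier component")
    }
    seen <- c(seen, cmp$voxels)
    labs[cmp$voxels] <- class_index(cmp$assigned_class)
  }
  labs[ref] <- class_index("Reference")
  label_volume(labs, pet$spacing, pet$origin)
}

#' Round-Robin constrained region growing
#'
#' The workflow's self-limiting growth scheme. The eligible pool starts as all
#' `Nominal` voxels with PET at or above the growth threshold. Each cycle:
#' (a) every pool voxel face-adjacent to a grow-class region is annexed by
#' that region (contention between classes is resolved in favour of the class
#' whose adjacent frontier voxel has the higher PET value; ties go to the
#' lower vocabulary index); (b) the pool is then eroded by one voxel (its
#' 6-connectivity boundary layer removed), constraining the next cycle.
#' Growth stops when a cycle annexes nothing; the pool strictly shrinks, so
#' the algorithm always terminates. Only `Nominal` voxels ever change class.
#'
#' @param labels `label_volume`.
#' @param pet Co-registered `scalar_volume` in SUL.
#' @param growth_threshold Eligibility threshold in SUL.
#' @param grow_classes Character vector of class names allowed to grow (must
#'   exclude `Background` and `Nominal`).
#' @return The grown `label_volume`.
#' @export
round_robin_grow <- function(labels, pet, growth_threshold, grow_classes) {
  stopifnot(inherits(labels, "label_volume"), inherits(pet, "scalar_volume"))
  stopifnot_same_geometry(labels, pet)
  if (any(grow_classes %in% c("Background", "Nominal"))) {
    stop("`grow_classes` may not include Background or Nominal")
  }
  grow_idx <- class_index(grow_classes, labels$vocabulary)
  lab <- labels$labels
  nominal <- class_index("Nominal", labels$vocabulary)
  pool <- (lab == nominal) & (pet$values >= growth_threshold)
  off <- face_offsets()
  repeat {
    best_val <- array(-Inf, dim(lab))
    best_cls <- array(.Machine$integer.max, dim(lab))
    for (i in seq_len(nrow(off))) {
      nb_lab <- shift3(lab, off[i, ], fill = -1L)
      nb_pet <- shift3(pet$values, off[i, ], fill = -Inf)
      cand <- pool & (nb_lab %in% grow_idx)
      if (!any(cand)) next
      better <- cand & ((nb_pet > best_val) |
                        (nb_pet == best_val & nb_lab < best_cls))
      best_val[better] <- nb_pet[better]
      best_cls[better] <- nb_lab[better]
    }
    annexed <- is.finite(best_val)
    if (!any(annexed)) break
    lab[annexed] <- best_cls[annexed]
    pool[annexed] <- FALSE
    pool <- erode6(pool)
  }
  label_volume(lab, labels$spacing, labels$origin, labels$vocabulary)
}

#' Grow and re-measure the liver Reference region
#'
#' Round-Robin growth of the `Reference` region into adjacent eligible
#' `Nominal` voxels at or above the reference threshold (liver mean - 2 SD),
#' letting the reference sample expand into a more anatomically representative
#' configuration; then re-measures the liver statistics over the grown region
#' and derives a fresh threshold set (the follow-up threshold is used for the
#' subsequent tissue-class growth).
#'
#' @param labels `label_volume` containing a `Reference` region.
#' @param pet Co-registered `scalar_volume` in SUL.
#' @param stats Initial `liver_stats`; if `NULL`, measured from the current
#'   `Reference` voxels.
#' @return List with `labels` (grown), `stats` (re-measured `liver_stats`) and
#'   `thresholds` (new `threshold_set`).
#' @export
refine_reference <- function(labels, pet, stats = NULL) {
  ref_idx <- class_index("Reference", labels$vocabulary)
  ref0 <- labels$labels == ref_idx
  if (!any(ref0)) stop("Reference region absent from labels")
  if (is.null(stats)) {
    x <- pet$values[ref0]
    stats <- liver_stats(mean(x), sqrt(mean((x - mean(x))^2)), length(x))
  }
  thr <- percist_thresholds(stats)
  grown <- round_robin_grow(labels, pet, thr$reference, "Reference")
  x <- pet$values[grown$labels == ref_idx]
  new_stats <- liver_stats(mean(x), sqrt(mean((x - mean(x))^2)), length(x))
  list(labels = grown, stats = new_stats,
       thresholds = percist_thresholds(new_stats))
}

#' Grow tissue classes at the follow-up threshold
#'
#' Round-Robin growth of every organ and lesion class (all classes except
#' `Background`, `Nominal` and `Reference`) into eligible adjacent `Nominal`
#' voxels at or above the follow-up assessment threshold — a slightly lower
#' threshold than the baseline one used for the initial segmentation, letting
#' avidity-based segmentations fill out their anatomy.
#'
#' @param labels `label_volume`.
#' @param pet Co-registered `scalar_volume` in SUL.
#' @param followup_threshold Follow-up assessment threshold in SUL.
#' @return The grown `label_volume`.
#' @export
grow_tissue_classes <- function(labels, pet, followup_threshold) {
  round_robin_grow(labels, pet, followup_threshold,
                   tissue_class_names(labels$vocabulary))
}

#' Class weights from training label volumes
#'
#' Voxel counts per class are accumulated over the training set; weights are
#' the reciprocal class frequencies, normalised so that the present classes
#' have mean weight 1 (a uniformly distributed vocabulary would give every
#' class weight 1). Classes absent from the training set get weight 0 so they
#' cannot dominate the loss.
#'
#' @param label_volumes A `label_volume`, or a list of them (or of plain
#'   integer arrays/matrices of vocabulary indices).
#' @param vocabulary Class vocabulary (default standard 16).
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(label_volumes, vocabulary = class_vocabulary()) {
  if (inherits(label_volumes, "label_volume")) label_volumes <- list(label_volumes)
  nc <- length(vocabulary)
  counts <- numeric(nc)
  total <- 0
  for (lv in label_volumes) {
    labs <- if (inherits(lv, "label_volume")) lv$labels else lv
    counts <- counts + tabulate(as.integer(labs) + 1L, nbins = nc)
    total <- total + length(labs)
  }
  if (total == 0) stop("no voxels in training set")
  w <- numeric(nc)
  present <- counts > 0
  raw <- 1 / counts[present]
  w[present] <- raw * sum(present) / sum(raw)
  names(w) <- vocabulary
  w
}
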
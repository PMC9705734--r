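#' Refine raw network predictions with the follow-up threshold
#'
#' The predicted `Reference` voxels are projected onto the PET data to
#' re-measure the liver mean and SD; the follow-up assessment threshold
#' (mean + 2 SD) is computed, and every voxel of every tissue class (all
#' classes except `Background`, `Nominal` and `Reference`) whose PET value
#' falls below that threshold is reassigned to `Nominal`. `Reference` and
#' `Background` are untouched: the reference is a reference, not a finding.
#' The operation is idempotent. Optionally, tissue components smaller than
#' `min_component_size` voxels after clearing are also reassigned to
#' `Nominal` (re-applying the candidate minimum-cluster rule).
#'
#' @param pred Predicted `label_volume` (must contain `Reference` voxels).
#' @param pet Co-registered `scalar_volume` in SUL.
#' @param min_component_size Minimum surviving component size in voxels
#'   (0 disables; 7 re-applies the candidate rule).
#' @return List with `labels` (refined `label_volume`), `stats`
#'   (`liver_stats` from the predicted Reference) and `thresholds`
#'   (`threshold_set`).
#' @export
refine_predictions <- function(pred, pet, min_component_size = 0L) {
  stopifnot(inherits(pred, "label_volume"), inherits(pet, "scalar_volume"))
  stopifnot_same_geometry(pred, pet)
  ref_idx <- class_index("Reference", pred$vocabulary)
  ref <- pred$labels == ref_idx
  if (!any(ref)) stop("reference not detected in predictions")
  x <- pet$values[ref]
  stats <- liver_stats(mean(x), sqrt(mean((x - mean(x))^2)), length(x))
  thr <- percist_thresholds(stats)
  tissue_idx <- class_index(tissue_class_names(pred$vocabulary),
                            pred$vocabulary)
  labs <- pred$labels
  nominal <- class_index("Nominal", pred$vocabulary)
  clear <- (labs %in% tissue_idx) & (pet$values < thr$followup)
  labs[clear] <- nominal
  if (min_component_size > 0L) {
    for (ci in tissue_idx) {
      m <- labs == ci
      if (!any(m)) next
      comp <- connected_components(m)
      sizes <- tabulate(comp[comp > 0L])
      drop <- which(sizes < min_component_size)
      if (length(drop) > 0) labs[comp %in% drop] <- nominal
    }
  }
  list(labels = label_volume(labs, pred$spacing, pred$origin, pred$vocabulary),
       stats = stats, thresholds = thr)
}

#' Extract quantified VOIs from refined labels
#'
#' One VOI per 6-connected component per annotated class (everything except
#' `Background` and `Nominal`), with volume in mL, SUL-Max, SUL-Mean and
#' SUL-Peak (mean over a 1 cm^3 sphere centred on the hottest voxel, clipped
#' to the grid).
#'
#' @param labels Refined `label_volume`.
#' @param pet Co-registered `scalar_volume` in SUL.
#' @return Data frame with columns `class`, `component`, `n_voxels`,
#'   `volume_ml`, `sul_max`, `sul_mean`, `sul_peak` (empty if nothing is
#'   annotated).
#' @export
extract_vois <- function(labels, pet) {
  stopifnot_same_geometry(labels, pet)
  voxel_ml <- prod(labels$spacing) / 1000
  peak_r <- sphere_radius_mm(1)
  rows <- list()
  for (cls in setdiff(labels$vocabulary, c("Background", "Nominal"))) {
    m <- labels$labels == class_index(cls, labels$vocabulary)
    if (!any(m)) next
    comp <- connected_components(m)
    for (i in seq_len(max(comp))) {
      vox <- which(comp == i)
      vals <- pet$values[vox]
      hot <- vox[which.max(vals)]
      center <- labels$origin + (arrayInd(hot, dim(labels$labels)) - 1) *
        labels$spacing
      peak_mask <- sphere_mask(pet, sphere_voi(as.numeric(center), peak_r))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, component = i, n_voxels = length(vox),
        volume_ml = length(vox) * voxel_ml,
        sul_max = max(vals), sul_mean = mean(vals),
        sul_peak = mean(pet$values[peak_mask])
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(class = character(), component = integer(),
                      n_voxels = integer(), volume_ml = numeric(),
                      sul_max = numeric(), sul_mean = numeric(),
                      sul_peak = numeric()))
  }
  do.call(rbind, rows)
}
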
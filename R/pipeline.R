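#' Threshold-based annotation of one study
#'
#' The full semi-automated training-annotation pipeline on a SUL PET volume:
#' body contour (0.1 SUL), automatic liver reference VOI (3 cm^3), PERCIST
#' baseline threshold, candidate segmentation (>= 7 connected voxels),
#' external class assignment, label-map assembly, Round-Robin growth and
#' re-measurement of the Reference region at the reference threshold, and
#' Round-Robin growth of the tissue classes at the follow-up threshold.
#'
#' @param pet `scalar_volume` in SUL (already preprocessed if the workflow
#'   calls for it).
#' @param classify Function `(components) -> components` filling
#'   `assigned_class` — e.g. `function(x) assign_classes(x, table)` for a CSV
#'   assignment table, or `function(x) assign_classes_from_truth(x, truth)`
#'   standing in for expert review on phantoms.
#' @param liver_center_mm Optional manual liver VOI centre override.
#' @param grow Run the two Round-Robin growth passes (default TRUE).
#' @return List with `labels` (final `label_volume`), `body`, `voi`,
#'   `initial_stats`, `stats` (post-growth), `thresholds` (post-growth
#'   `threshold_set`), and `components` (classified candidates).
#' @export
annotate_study <- function(pet, classify, liver_center_mm = NULL,
                           grow = TRUE) {
  body <- body_contour(pet)
  voi <- locate_liver_voi(pet, body, center_mm = liver_center_mm)
  stats0 <- liver_statistics(pet, voi)
  thr0 <- percist_thresholds(stats0)
  comps <- segment_candidates(pet, thr0$baseline)
  comps <- classify(comps)
  labels <- assemble_label_map(pet, body, voi, comps)
  if (!grow) {
    return(list(labels = labels, body = body, voi = voi,
                initial_stats = stats0, stats = stats0, thresholds = thr0,
                components = comps))
  }
  ref <- refine_reference(labels, pet, stats0)
  grown <- grow_tissue_classes(ref$labels, pet, ref$thresholds$followup)
  list(labels = grown, body = body, voi = voi, initial_stats = stats0,
       stats = ref$stats, thresholds = ref$thresholds, components = comps)
}

#' Prepare one study for network training
#'
#' The complete training-data path: threshold-based annotation on the native
#' grid (body contour, liver VOI, baseline segmentation, classification,
#' label-map assembly), geometric preprocessing of PET, CT and labels
#' (isotropic resampling, centre crop, PET spherical smoothing), then the two
#' Round-Robin growth passes on the cleaned data — Reference re-measurement at
#' the reference threshold followed by tissue-class growth at the follow-up
#' threshold — and finally slicing into integer-encoded training samples.
#'
#' @param pet `scalar_volume` in SUL.
#' @param ct Co-registered `scalar_volume` in HU.
#' @param classify Component classifier, as in [annotate_study()].
#' @param study_id Study identifier attached to the samples.
#' @param target_spacing_mm,crop_size,kernel_volume_cm3 Preprocessing
#'   parameters (see [preprocess_study()]).
#' @return List with `samples` (training samples), `processed` (preprocessed
#'   volumes including grown `labels`), `stats`, `thresholds`.
#' @export
prepare_training_study <- function(pet, ct, classify, study_id,
                                   target_spacing_mm = 3.5, crop_size = 128L,
                                   kernel_volume_cm3 = 1.0) {
  ann <- annotate_study(pet, classify, grow = FALSE)
  pp <- preprocess_study(pet, ct, ann$labels,
                         target_spacing_mm = target_spacing_mm,
                         crop_size = crop_size,
                         kernel_volume_cm3 = kernel_volume_cm3)
  ref <- refine_reference(pp$labels, pp$pet)
  grown <- grow_tissue_classes(ref$labels, pp$pet, ref$thresholds$followup)
  pp$labels <- grown
  list(samples = study_to_samples(pp, study_id), processed = pp,
       stats = ref$stats, thresholds = ref$thresholds)
}
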
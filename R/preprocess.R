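# Resampling, cropping, smoothing and integer channel encoding: the fixed
# geometry pipeline that turns co-registered volumes into 2-channel training
# slices.

# Trilinear / nearest resampling of a 3D array defined on (spacing, origin)
# onto target axis coordinate vectors (mm). Coordinates are clamped to the
# source grid so edge queries replicate border values.
resample_array <- function(values, spacing, origin, target_coords,
                           mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(values)
  nd <- vapply(target_coords, length, 1L)
  t_ax <- lapply(1:3, function(k) {
    t <- (target_coords[[k]] - origin[k]) / spacing[k]
    pmin(pmax(t, 0), d[k] - 1)
  })
  if (mode == "nearest") {
    idx <- lapply(1:3, function(k) as.integer(round(t_ax[[k]])) + 1L)
    return(array(values[as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))],
                 dim = nd))
  }
  i0 <- lapply(1:3, function(k) {
    if (d[k] == 1L) rep(0L, nd[k]) else pmin(as.integer(floor(t_ax[[k]])), d[k] - 2L)
  })
  fr <- lapply(1:3, function(k) t_ax[[k]] - i0[[k]])
  # expand per-axis vectors to the full target grid (row fastest)
  er <- function(v) rep(v, times = nd[2] * nd[3])
  ec <- function(v) rep(rep(v, each = nd[1]), times = nd[3])
  es <- function(v) rep(v, each = nd[1] * nd[2])
  I1 <- er(i0[[1]]); I2 <- ec(i0[[2]]); I3 <- es(i0[[3]])
  F1 <- er(fr[[1]]); F2 <- ec(fr[[2]]); F3 <- es(fr[[3]])
  base <- 1 + I1 + I2 * d[1] + I3 * (d[1] * d[2])
  s1 <- if (d[1] == 1L) 0L else 1L
  s2 <- if (d[2] == 1L) 0L else d[1]
  s3 <- if (d[3] == 1L) 0L else d[1] * d[2]
  out <-
    values[base]                * (1 - F1) * (1 - F2) * (1 - F3) +
    values[base + s1]           * F1 * (1 - F2) * (1 - F3) +
    values[base + s2]           * (1 - F1) * F2 * (1 - F3) +
    values[base + s1 + s2]      * F1 * F2 * (1 - F3) +
    values[base + s3]           * (1 - F1) * (1 - F2) * F3 +
    values[base + s1 + s3]      * F1 * (1 - F2) * F3 +
    values[base + s2 + s3]      * (1 - F1) * F2 * F3 +
    values[base + s1 + s2 + s3] * F1 * F2 * F3
  array(out, dim = nd)
}

#' Resample a volume to isotropic voxels
#'
#' Resamples to a given isotropic spacing (default 3.5 mm), preserving the
#' physical extent within one voxel and keeping the extent centred. Scalar
#' volumes are interpolated trilinearly; label volumes use nearest-neighbour
#' (no new label values are introduced). A volume already at the target
#' spacing is returned unchanged.
#'
#' @param vol `scalar_volume` or `label_volume`.
#' @param target_spacing_mm Isotropic target spacing in mm.
#' @return Volume of the same class on the isotropic grid.
#' @export
resample_isotropic <- function(vol, target_spacing_mm = 3.5) {
  is_label <- inherits(vol, "label_volume")
  values <- if (is_label) vol$labels else vol$values
  d <- dim(values)
  if (all(abs(vol$spacing - target_spacing_mm) < 1e-9)) return(vol)
  extent <- d * vol$spacing
  nd <- pmax(as.integer(round(extent / target_spacing_mm)), 1L)
  # keep the physical region centred: region start -> first new voxel centre
  start <- (vol$origin - vol$spacing / 2) + (extent - nd * target_spacing_mm) / 2
  new_origin <- start + target_spacing_mm / 2
  tc <- lapply(1:3, function(k) new_origin[k] + (seq_len(nd[k]) - 1) * target_spacing_mm)
  out <- resample_array(values, vol$spacing, vol$origin, tc,
                        mode = if (is_label) "nearest" else "linear")
  if (is_label) {
    label_volume(out, rep(target_spacing_mm, 3), new_origin, vol$vocabulary)
  } else {
    if (vol$units == "SUL") out <- pmax(out, 0)
    scalar_volume(out, rep(target_spacing_mm, 3), new_origin, vol$units)
  }
}

#' Resample a CT volume onto a PET grid
#'
#' Trilinear interpolation of the CT values at the PET voxel centres; the
#' output geometry equals the PET geometry exactly. A CT already on the PET
#' grid is returned value-identical.
#'
#' @param ct `scalar_volume` in HU.
#' @param pet `scalar_volume` defining the target grid.
#' @return `scalar_volume` in HU on the PET grid.
#' @export
resample_ct_to_pet <- function(ct, pet) {
  stopifnot(inherits(ct, "scalar_volume"), inherits(pet, "scalar_volume"))
  if (same_geometry(ct, pet)) {
    return(scalar_volume(ct$values, pet$spacing, pet$origin, ct$units))
  }
  # require spatial overlap of the two bounding boxes
  for (k in 1:3) {
    ct_lo <- ct$origin[k] - ct$spacing[k] / 2
    ct_hi <- ct$origin[k] + (dim(ct$values)[k] - 0.5) * ct$spacing[k]
    pet_lo <- pet$origin[k] - pet$spacing[k] / 2
    pet_hi <- pet$origin[k] + (dim(pet$values)[k] - 0.5) * pet$spacing[k]
    if (ct_hi < pet_lo || pet_hi < ct_lo) {
      stop("CT and PET volumes do not overlap in space")
    }
  }
  tc <- axis_coords(pet)
  out <- resample_array(ct$values, ct$spacing, ct$origin, tc, mode = "linear")
  scalar_volume(out, pet$spacing, pet$origin, ct$units)
}

#' Centre-crop (or pad) the transaxial plane
#'
#' Crops the in-plane (row, column) dimensions to `size` x `size`, centred.
#' Inputs smaller than `size` are padded symmetrically with zeros (i.e.
#' `Background` for label volumes); odd remainders put the extra cropped or
#' padded voxel on the high-index side. The slice axis is untouched.
#'
#' @param vol `scalar_volume` or `label_volume`.
#' @param size Target in-plane size in voxels (default 128).
#' @return Cropped/padded volume of the same class.
#' @export
center_crop <- function(vol, size = 128L) {
  is_label <- inherits(vol, "label_volume")
  values <- if (is_label) vol$labels else vol$values
  d <- dim(values)
  origin <- vol$origin
  out <- values
  for (ax in 1:2) {
    n <- dim(out)[ax]
    if (n == size) next
    if (n > size) {
      lo <- (n - size) %/% 2          # removed on the low side; extra high
      idx <- seq_len(size) + lo
      out <- if (ax == 1) out[idx, , , drop = FALSE] else out[, idx, , drop = FALSE]
      origin[ax] <- origin[ax] + lo * vol$spacing[ax]
    } else {
      lo <- (size - n) %/% 2          # padded low; extra voxel on high side
      dd <- dim(out)
      dd[ax] <- size
      pad <- array(if (is_label) 0L else 0, dd)
      if (ax == 1) pad[seq_len(n) + lo, , ] <- out else pad[, seq_len(n) + lo, ] <- out
      out <- pad
      origin[ax] <- origin[ax] - lo * vol$spacing[ax]
    }
  }
  if (is_label) {
    label_volume(out, vol$spacing, origin, vol$vocabulary)
  } else {
    scalar_volume(out, vol$spacing, origin, vol$units)
  }
}

#' Spherical mean smoothing filter
#'
#' Mean filter over all voxels whose centres lie within a sphere of the given
#' volume (default 1 cm^3, radius 6.203 mm) centred on each voxel. Near the
#' grid edge the mean is taken over the in-bounds kernel voxels, so constant
#' volumes are unchanged everywhere.
#'
#' @param pet `scalar_volume` (typically isotropic SUL).
#' @param kernel_volume_cm3 Kernel sphere volume in cm^3.
#' @return Smoothed `scalar_volume`.
#' @export
smooth_spherical <- function(pet, kernel_volume_cm3 = 1.0) {
  stopifnot(inherits(pet, "scalar_volume"))
  r <- sphere_radius_mm(kernel_volume_cm3)
  off <- ball_offsets(r, pet$spacing)
  d <- dim(pet$values)
  s <- array(0, d)
  n <- array(0, d)
  ones <- array(1, d)
  for (i in seq_len(nrow(off))) {
    s <- s + shift3(pet$values, off[i, ], fill = 0)
    n <- n + shift3(ones, off[i, ], fill = 0)
  }
  scalar_volume(s / n, pet$spacing, pet$origin, pet$units)
}

#' Integer channel encoding for training export
#'
#' PET is exported in SUL units multiplied by 100 (e.g. a voxel of 3.27 SUL is
#' stored as 327), rounded half away from zero. CT is exported in HU offset by
#' +1024 so the base value is 0 (air at -1024 HU encodes as 0); values below
#' the offset clip to 0. Both channels are clipped to the signed 16-bit range.
#'
#' @param pet_sul 2D numeric matrix of SUL values (>= 0).
#' @param ct_hu 2D numeric matrix of HU values.
#' @return List with integer matrices `pet` and `ct`.
#' @export
#' @examples
#' encode_channels(matrix(3.27), matrix(0))  # pet 327, ct 1024
encode_channels <- function(pet_sul, ct_hu) {
  if (any(pet_sul < 0)) stop("SUL values must be >= 0")
  if (!identical(dim(pet_sul), dim(ct_hu))) stop("channel shape mismatch")
  pet <- as.integer(pmin(floor(pet_sul * 100 + 0.5), 32767))
  ct <- as.integer(pmin(pmax(round(ct_hu) + 1024, 0), 32767))
  list(pet = matrix(pet, nrow(pet_sul)), ct = matrix(ct, nrow(ct_hu)))
}

#' Full study preprocessing
#'
#' The fixed study-level geometry pipeline: resample everything to isotropic
#' voxels, centre-crop the transaxial plane, then smooth the PET with the
#' spherical filter (set `smooth_first = TRUE` to smooth before resampling for
#' sensitivity testing). Identical geometric parameters are applied to PET, CT
#' and labels, preserving co-registration; re-running on identical input is
#' bit-identical.
#'
#' @param pet `scalar_volume` in SUL.
#' @param ct `scalar_volume` in HU (resampled to the PET grid first if
#'   needed).
#' @param labels Optional co-registered `label_volume`.
#' @param target_spacing_mm Isotropic spacing (default 3.5 mm).
#' @param crop_size In-plane size (default 128).
#' @param kernel_volume_cm3 PET smoothing kernel volume (default 1 cm^3; 0
#'   disables smoothing).
#' @param smooth_first Smooth before resampling instead of after cropping.
#' @return List with processed `pet`, `ct` and (if given) `labels`.
#' @export
preprocess_study <- function(pet, ct, labels = NULL, target_spacing_mm = 3.5,
                             crop_size = 128L, kernel_volume_cm3 = 1.0,
                             smooth_first = FALSE) {
  ct <- resample_ct_to_pet(ct, pet)
  if (smooth_first && kernel_volume_cm3 > 0) pet <- smooth_spherical(pet, kernel_volume_cm3)
  pet <- center_crop(resample_isotropic(pet, target_spacing_mm), crop_size)
  ct <- center_crop(resample_isotropic(ct, target_spacing_mm), crop_size)
  if (!smooth_first && kernel_volume_cm3 > 0) pet <- smooth_spherical(pet, kernel_volume_cm3)
  out <- list(pet = pet, ct = ct)
  if (!is.null(labels)) {
    out$labels <- center_crop(resample_isotropic(labels, target_spacing_mm),
                              crop_size)
  }
  out
}

#' Extract training samples from a preprocessed study
#'
#' Slices the preprocessed volumes transaxially and integer-encodes the
#' channels, producing one `training_sample` per slice.
#'
#' @param processed List from [preprocess_study()] including `labels`.
#' @param study_id Study identifier attached to every sample.
#' @return List of `training_sample` objects (`pet_channel`, `ct_channel`,
#'   `label_slice`, `study_id`, `slice_index`).
#' @export
study_to_samples <- function(processed, study_id) {
  stopifnot(!is.null(processed$labels))
  ns <- dim(processed$pet$values)[3]
  lapply(seq_len(ns), function(k) {
    enc <- encode_channels(processed$pet$values[, , k], processed$ct$values[, , k])
    structure(list(pet_channel = enc$pet, ct_channel = enc$ct,
                   label_slice = processed$labels$labels[, , k],
                   study_id = study_id, slice_index = k),
              class = "training_sample")
  })
}
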
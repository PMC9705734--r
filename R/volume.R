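#' Scalar volume
#'
#' A 3D scalar grid (PET in SUL or activity concentration, or CT in Hounsfield
#' units) with voxel spacing and a patient-space origin. Arrays are stored in
#' R's column-major order as `(row, column, slice)`, where the third axis is the
#' transaxial (cranio-caudal) direction. The physical centre of voxel
#' `[i, j, k]` (1-based) is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values 3D numeric array.
#' @param spacing Per-axis voxel spacing in mm (length 3, all > 0).
#' @param origin Patient-space position (mm) of the centre of voxel
#'   `[1, 1, 1]`.
#' @param units One of `"SUL"`, `"HU"`, `"BQML"` (activity concentration,
#'   Bq/mL). SUL volumes must be non-negative.
#' @return A `scalar_volume` object.
#' @export
scalar_volume <- function(values, spacing, origin = c(0, 0, 0),
                          units = c("SUL", "HU", "BQML")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite values (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)")
  }
  if (units == "SUL" && any(values < 0, na.rm = TRUE)) {
    stop("SUL volumes must be non-negative")
  }
  structure(
    list(values = values, spacing = spacing, origin = origin, units = units),
    class = "scalar_volume"
  )
}

#' Label volume
#'
#' A 3D integer grid over a fixed tissue-class vocabulary, co-registered with a
#' scalar volume (same geometry conventions as [scalar_volume()]).
#'
#' @param labels 3D integer array of zero-based vocabulary indices.
#' @param spacing,origin Geometry, as for [scalar_volume()].
#' @param vocabulary Ordered class names; defaults to the standard 16-entry
#'   vocabulary.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0),
                         vocabulary = class_vocabulary()) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array")
  }
  if (anyDuplicated(vocabulary)) stop("vocabulary names must be unique")
  storage.mode(labels) <- "integer"
  rng <- range(labels)
  if (rng[1] < 0L || rng[2] >= length(vocabulary)) {
    stop("labels out of vocabulary range 0..", length(vocabulary) - 1L)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive values (mm)")
  }
  structure(
    list(labels = labels, spacing = spacing, origin = origin,
         vocabulary = vocabulary),
    class = "label_volume"
  )
}

#' Spherical volume of interest
#'
#' @param center_mm Patient-space centre (mm), length 3.
#' @param radius_mm Sphere radius in mm (> 0).
#' @return A `sphere_voi` object.
#' @export
sphere_voi <- function(center_mm, radius_mm) {
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L) stop("`center_mm` must have length 3")
  if (!is.finite(radius_mm) || radius_mm <= 0) stop("`radius_mm` must be > 0")
  structure(list(center_mm = center_mm, radius_mm = radius_mm),
            class = "sphere_voi")
}

#' Radius of a sphere of given volume
#'
#' @param volume_cm3 Sphere volume in cm^3.
#' @return Radius in mm: `(3 V / 4 pi)^(1/3)` with V in mm^3.
#' @export
#' @examples
#' sphere_radius_mm(3)  # 3 cm^3 liver reference VOI -> 8.947 mm
sphere_radius_mm <- function(volume_cm3) {
  (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume [%s]> %s voxels, spacing %s mm\n", x$units,
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d classes, spacing %s mm\n",
              paste(dim(x$labels), collapse = "x"), length(x$vocabulary),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
print.sphere_voi <- function(x, ...) {
  cat(sprintf("<sphere_voi> centre (%s) mm, radius %.3f mm\n",
              paste(format(x$center_mm), collapse = ", "), x$radius_mm))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "label_volume")) dim(a$labels) else dim(a$values)
  db <- if (inherits(b, "label_volume")) dim(b$labels) else dim(b$values)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b)) stop(what, " are not co-registered (geometry mismatch)")
  invisible(TRUE)
}

# Per-axis physical coordinates (mm) of voxel centres.
axis_coords <- function(vol) {
  d <- if (inherits(vol, "label_volume")) dim(vol$labels) else dim(vol$values)
  lapply(1:3, function(k) vol$origin[k] + (seq_len(d[k]) - 1) * vol$spacing[k])
}

# Boolean array of voxels whose centres lie inside a sphere.
sphere_mask <- function(vol, voi) {
  d <- if (inherits(vol, "label_volume")) dim(vol$labels) else dim(vol$values)
  co <- axis_coords(vol)
  d2r <- (co[[1]] - voi$center_mm[1])^2
  d2c <- (co[[2]] - voi$center_mm[2])^2
  d2s <- (co[[3]] - voi$center_mm[3])^2
  tot <- rep(d2r, times = d[2] * d[3]) +
    rep(rep(d2c, each = d[1]), times = d[3]) +
    rep(d2s, each = d[1] * d[2])
  array(tot <= voi$radius_mm^2, dim = d)
}
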
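#' Geometric primitives for phantom regions
#'
#' Regions of a synthetic phantom are ellipsoids, spheres or axis-aligned
#' boxes, all specified in physical mm so that truth labels come from exact
#' analytic membership tests.
#'
#' @param center Centre in mm (length 3).
#' @param radii,radius,half_size Ellipsoid semi-axes, sphere radius or box
#'   half-widths, in mm.
#' @return A `phantom_geometry` object.
#' @export
geom_ellipsoid <- function(center, radii) {
  stopifnot(length(center) == 3, length(radii) == 3, all(radii > 0))
  structure(list(type = "ellipsoid", center = as.numeric(center),
                 radii = as.numeric(radii)), class = "phantom_geometry")
}

#' @rdname geom_ellipsoid
#' @export
geom_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(type = "sphere", center = as.numeric(center),
                 radius = as.numeric(radius)), class = "phantom_geometry")
}

#' @rdname geom_ellipsoid
#' @export
geom_box <- function(center, half_size) {
  stopifnot(length(center) == 3, length(half_size) == 3, all(half_size > 0))
  structure(list(type = "box", center = as.numeric(center),
                 half_size = as.numeric(half_size)), class = "phantom_geometry")
}

geom_bounds <- function(g) {
  ext <- switch(g$type, ellipsoid = g$radii, sphere = rep(g$radius, 3),
                box = g$half_size)
  rbind(lo = g$center - ext, hi = g$center + ext)
}

# Boolean membership array for a geometry on a voxel grid.
geometry_mask <- function(g, grid_shape, spacing, origin = c(0, 0, 0)) {
  co <- lapply(1:3, function(k) origin[k] + (seq_len(grid_shape[k]) - 1) * spacing[k])
  expand3 <- function(f) {
    # f(k) -> per-axis numeric vector; returns full array sum
    rep(f(1), times = grid_shape[2] * grid_shape[3]) +
      rep(rep(f(2), each = grid_shape[1]), times = grid_shape[3]) +
      rep(f(3), each = grid_shape[1] * grid_shape[2])
  }
  m <- switch(g$type,
    ellipsoid = expand3(function(k) ((co[[k]] - g$center[k]) / g$radii[k])^2) <= 1,
    sphere = expand3(function(k) (co[[k]] - g$center[k])^2) <= g$radius^2,
    box = expand3(function(k) as.numeric(abs(co[[k]] - g$center[k]) > g$half_size[k])) == 0
  )
  array(m, dim = grid_shape)
}

phantom_region <- function(name, class, geometry, mean_sul, sd_sul, hu = 40,
                           hu_sd = 10) {
  stopifnot(is.finite(mean_sul), mean_sul >= 0, is.finite(sd_sul), sd_sul >= 0)
  list(name = name, class = class, geometry = geometry,
       mean_sul = mean_sul, sd_sul = sd_sul, hu = hu, hu_sd = hu_sd)
}

#' Specification of a synthetic PET/CT phantom
#'
#' Defines the geometry and uptake statistics of a synthetic co-registered
#' PET/CT study: a soft-tissue body ellipsoid on an air background, a
#' homogeneous-but-noisy liver, optional avid organs, and planted lesions.
#' PET voxel values are independent Gaussian draws around each region's mean
#' SUL (clipped at zero); CT is piecewise-constant HU plus Gaussian noise.
#' Ground-truth labels come from the exact analytic region memberships.
#'
#' @param grid_shape Voxels per axis (row, column, slice).
#' @param voxel_spacing_mm Per-axis spacing in mm.
#' @param body_ellipsoid `phantom_geometry` of the body region.
#' @param liver_region List with `geometry`, `mean_sul`, `sd_sul` (and
#'   optionally `hu`, `hu_sd`). The liver is deliberately *not* a vocabulary
#'   class: sub-threshold liver tissue is Nominal in the truth, mirroring how
#'   the reference VOI proxies the organ.
#' @param organs List of organ regions (each a list with `class`, `geometry`,
#'   `mean_sul`, `sd_sul`, optional `hu`).
#' @param lesions List of lesion regions; `class` must be one of
#'   `Primary_Lesion`, `Lymphadenopathy`, `Other_Metastasis`, and each lesion's
#'   mean SUL must exceed the liver mean.
#' @param background_sul,background_sd Ambient body uptake (SUL).
#' @param body_hu,air_hu,ct_noise_sd CT channel assignments (HU).
#' @param seed Integer RNG seed; identical spec + seed reproduce the phantom
#'   bit for bit.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape, voxel_spacing_mm, body_ellipsoid,
                         liver_region, organs = list(), lesions = list(),
                         background_sul = 0.7, background_sd = 0.15,
                         body_hu = 40, air_hu = -1000, ct_noise_sd = 10,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0),
            background_sul >= 0, background_sd >= 0)
  lesion_classes <- c("Primary_Lesion", "Lymphadenopathy", "Other_Metastasis")
  for (l in lesions) {
    if (!l$class %in% lesion_classes) {
      stop("lesion class must be one of ", paste(lesion_classes, collapse = ", "))
    }
    if (l$mean_sul <= liver_region$mean_sul) {
      stop("lesion mean SUL must exceed liver mean SUL")
    }
  }
  spec <- structure(
    list(grid_shape = grid_shape, voxel_spacing_mm = voxel_spacing_mm,
         body_ellipsoid = body_ellipsoid, liver_region = liver_region,
         organs = organs, lesions = lesions,
         background_sul = background_sul, background_sd = background_sd,
         body_hu = body_hu, air_hu = air_hu, ct_noise_sd = ct_noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  extent_lo <- -0.5 * voxel_spacing_mm
  extent_hi <- (grid_shape - 0.5) * voxel_spacing_mm
  geoms <- c(list(list(name = "body", geometry = body_ellipsoid)),
             phantom_regions(spec))
  for (r in geoms) {
    b <- geom_bounds(r$geometry)
    if (any(b["lo", ] < extent_lo) || any(b["hi", ] > extent_hi)) {
      stop("region '", r$name, "' extends outside the grid bounds")
    }
  }
  spec
}

# All stochastic regions in fixed generation order: liver, organs, lesions.
phantom_regions <- function(spec) {
  regs <- list(phantom_region(
    "liver", NA_character_, spec$liver_region$geometry,
    spec$liver_region$mean_sul, spec$liver_region$sd_sul,
    hu = spec$liver_region$hu %||% 55, hu_sd = spec$ct_noise_sd
  ))
  for (i in seq_along(spec$organs)) {
    o <- spec$organs[[i]]
    regs[[length(regs) + 1L]] <- phantom_region(
      o$name %||% o$class, o$class, o$geometry, o$mean_sul, o$sd_sul,
      hu = o$hu %||% 45, hu_sd = spec$ct_noise_sd)
  }
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    regs[[length(regs) + 1L]] <- phantom_region(
      l$name %||% paste0(l$class, "_", i), l$class, l$geometry, l$mean_sul,
      l$sd_sul %||% 0.4, hu = l$hu %||% 50, hu_sd = spec$ct_noise_sd)
  }
  regs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic PET/CT phantom
#'
#' Draws the PET (SUL) and CT (HU) volumes and the exact ground-truth label
#' volume described by a [phantom_spec()]. Overlapping regions of different
#' tissue classes are an error (overlap resolution is never silently decided).
#'
#' @param spec A `phantom_spec`.
#' @return List with elements `pet` (scalar_volume, SUL), `ct` (scalar_volume,
#'   HU) and `truth` (label_volume). Voxels outside the body are `Background`;
#'   body voxels not covered by a region are `Nominal`; liver voxels are
#'   `Nominal` (the liver has no vocabulary class of its own); organ and lesion
#'   voxels carry their region's class.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  n <- prod(d)
  regs <- phantom_regions(spec)
  masks <- lapply(regs, function(r) geometry_mask(r$geometry, d, sp))
  # overlap check, pairwise, named error
  for (i in seq_along(masks)) {
    for (j in seq_len(i - 1L)) {
      if (any(masks[[i]] & masks[[j]])) {
        stop("phantom regions overlap: '", regs[[j]]$name, "' and '",
             regs[[i]]$name, "'")
      }
    }
  }
  body <- geometry_mask(spec$body_ellipsoid, d, sp)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  # PET: air ~ 0, ambient body, then each region in fixed order
  pet <- array(pmax(stats::rnorm(n, 0, 0.005), 0), dim = d)
  pet[body] <- stats::rnorm(sum(body), spec$background_sul, spec$background_sd)
  truth <- array(0L, dim = d)
  truth[body] <- class_index("Nominal")
  ct <- array(stats::rnorm(n, spec$air_hu, spec$ct_noise_sd / 2), dim = d)
  ct[body] <- stats::rnorm(sum(body), spec$body_hu, spec$ct_noise_sd)
  for (i in seq_along(regs)) {
    m <- masks[[i]]
    k <- sum(m)
    if (k == 0L) next
    pet[m] <- stats::rnorm(k, regs[[i]]$mean_sul, regs[[i]]$sd_sul)
    ct[m] <- stats::rnorm(k, regs[[i]]$hu, regs[[i]]$hu_sd)
    if (!is.na(regs[[i]]$class)) {
      truth[m] <- class_index(regs[[i]]$class)
    }
  }
  pet <- pmax(pet, 0)
  list(
    pet = scalar_volume(pet, sp, units = "SUL"),
    ct = scalar_volume(ct, sp, units = "HU"),
    truth = label_volume(truth, sp)
  )
}

#' Voxel mask of a named phantom region
#'
#' Convenience for tests and evaluation: the exact analytic membership mask of
#' one region (`"body"`, `"liver"`, or a region/lesion name) on the phantom
#' grid.
#'
#' @param spec A `phantom_spec`.
#' @param region Region name.
#' @return 3D logical array.
#' @export
phantom_region_mask <- function(spec, region) {
  if (region == "body") {
    return(geometry_mask(spec$body_ellipsoid, spec$grid_shape,
                         spec$voxel_spacing_mm))
  }
  regs <- phantom_regions(spec)
  nm <- vapply(regs, `[[`, "", "name")
  i <- match(region, nm)
  if (is.na(i)) stop("unknown phantom region '", region, "'")
  geometry_mask(regs[[i]]$geometry, spec$grid_shape, spec$voxel_spacing_mm)
}

#' Default torso phantom specification
#'
#' A 64 x 64 x 48 torso at 3.5 mm isotropic spacing (224 x 224 x 168 mm):
#' soft-tissue body (ambient 0.7 +/- 0.15 SUL), homogeneous noisy liver
#' (2.2 +/- 0.25 SUL), avid heart (4.0) and bladder (9.0), deliberately
#' sub-threshold kidneys (3.0), and optionally a primary breast lesion
#' (r = 11 mm, 6.0 SUL) plus an axillary lymph node (r = 9 mm, 5.0 SUL).
#' Uptake levels are typical clinical FDG SUL magnitudes; lesions clear the
#' PERCIST baseline threshold (1.5 x 2.2 + 2 x 0.25 = 3.8 SUL) by a wide
#' margin so that threshold-based annotation is well-posed.
#'
#' @param seed Integer RNG seed.
#' @param with_lesions Plant the primary lesion and lymph node?
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(seed = 1L, with_lesions = TRUE) {
  lesions <- list()
  if (with_lesions) {
    lesions <- list(
      list(name = "primary", class = "Primary_Lesion",
           geometry = geom_sphere(c(72, 72, 120), 11), mean_sul = 6.0,
           sd_sul = 0.4),
      list(name = "node", class = "Lymphadenopathy",
           geometry = geom_sphere(c(118, 70, 135), 9), mean_sul = 5.0,
           sd_sul = 0.35)
    )
  }
  phantom_spec(
    grid_shape = c(64, 64, 48),
    voxel_spacing_mm = c(3.5, 3.5, 3.5),
    body_ellipsoid = geom_ellipsoid(c(110, 110, 82), c(95, 85, 80)),
    liver_region = list(geometry = geom_ellipsoid(c(80, 115, 95), c(36, 30, 26)),
                        mean_sul = 2.2, sd_sul = 0.25, hu = 55),
    organs = list(
      list(name = "heart", class = "Heart",
           geometry = geom_ellipsoid(c(145, 100, 120), c(22, 22, 20)),
           mean_sul = 4.0, sd_sul = 0.3, hu = 45),
      list(name = "bladder", class = "Bladder",
           geometry = geom_sphere(c(110, 115, 22), 16), mean_sul = 9.0,
           sd_sul = 0.5, hu = 10),
      list(name = "kidney_l", class = "Kidney",
           geometry = geom_ellipsoid(c(62, 145, 55), c(14, 11, 16)),
           mean_sul = 3.0, sd_sul = 0.3, hu = 35),
      list(name = "kidney_r", class = "Kidney",
           geometry = geom_ellipsoid(c(158, 145, 55), c(14, 11, 16)),
           mean_sul = 3.0, sd_sul = 0.3, hu = 35)
    ),
    lesions = lesions,
    seed = seed
  )
}
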
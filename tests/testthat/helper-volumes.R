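# Small construction helpers used across tests.

toy_volume <- function(values, spacing = c(1, 1, 1), units = "SUL") {
  scalar_volume(values, spacing = spacing, units = units)
}

toy_labels <- function(labels, spacing = c(1, 1, 1)) {
  label_volume(labels, spacing = spacing)
}

# A uniform volume with a few voxels set.
volume_with <- function(dim, base = 0, at = NULL, value = 1,
                        spacing = c(1, 1, 1), units = "SUL") {
  a <- array(base, dim)
  if (!is.null(at)) a[at] <- value
  toy_volume(a, spacing, units)
}

pet_metadata <- function(...) {
  utils::modifyList(
    list(PatientWeight = 70, PatientHeight = 170, PatientSex = "female",
         InjectedDoseBq = 370e6, InjectionTime = 0, AcquisitionTime = 3600),
    list(...)
  )
}

# Small phantom with an oversized homogeneous liver (>= 5000 voxels) for
# statistics-recovery tests.
big_liver_spec <- function(seed = 1L) {
  phantom_spec(
    grid_shape = c(44, 44, 44),
    voxel_spacing_mm = c(4, 4, 4),
    body_ellipsoid = geom_ellipsoid(c(86, 86, 86), c(80, 80, 80)),
    liver_region = list(geometry = geom_sphere(c(86, 86, 86), 46),
                        mean_sul = 2.2, sd_sul = 0.25),
    background_sul = 0.7, background_sd = 0.15,
    seed = seed
  )
}
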
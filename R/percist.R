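#' Lean body mass (James equations)
#'
#' LBM in kg from the James equations, the convention associated with
#' PERCIST-era SUL quantification:
#' male `1.10 W - 128 (W/H)^2`, female `1.07 W - 148 (W/H)^2`,
#' with weight W in kg and height H in cm.
#'
#' @param weight_kg Body weight in kg (> 0).
#' @param height_cm Height in cm (> 0).
#' @param sex `"male"` or `"female"`.
#' @return Lean body mass in kg.
#' @export
#' @examples
#' lean_body_mass(80, 180, "male")    # 62.72
#' lean_body_mass(60, 165, "female")  # 44.63
lean_body_mass <- function(weight_kg, height_cm, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (!is.finite(weight_kg) || weight_kg <= 0) stop("`weight_kg` must be > 0")
  if (!is.finite(height_cm) || height_cm <= 0) stop("`height_cm` must be > 0")
  r2 <- (weight_kg / height_cm)^2
  lbm <- switch(sex,
    male = 1.10 * weight_kg - 128 * r2,
    female = 1.07 * weight_kg - 148 * r2
  )
  if (lbm <= 0) stop("non-physiologic inputs: computed LBM <= 0")
  lbm
}

#' Convert activity concentration to SUL
#'
#' SUL = concentration / (decay-corrected injected dose / lean body mass),
#' with concentration in Bq/mL, dose in Bq and LBM in grams (1 mL of tissue
#' is taken as 1 g). The dose is decay-corrected from injection to scan start
#' with the isotope half-life (default 18F: 109.77 min). A voxel whose
#' concentration equals decayed-dose / LBM-grams has SUL exactly 1; the map is
#' linear in concentration and inversely linear in dose.
#'
#' @param activity `scalar_volume` with units `"BQML"`.
#' @param injected_dose_bq Injected activity at injection time, in Bq (> 0).
#' @param injection_time_s,scan_time_s Injection and scan-start times in
#'   seconds (any common epoch); `scan_time_s >= injection_time_s`.
#' @param isotope_half_life_s Half-life in seconds (default 18F, 6586.2 s).
#' @param lbm_kg Lean body mass in kg.
#' @return `scalar_volume` in SUL (negative concentrations clip to 0).
#' @export
compute_sul <- function(activity, injected_dose_bq, injection_time_s,
                        scan_time_s, isotope_half_life_s = 109.77 * 60,
                        lbm_kg) {
  stopifnot(inherits(activity, "scalar_volume"))
  if (activity$units != "BQML") stop("`activity` must have units BQML")
  for (nm in c("injected_dose_bq", "injection_time_s", "scan_time_s", "lbm_kg")) {
    v <- get(nm)
    if (is.null(v) || length(v) != 1L || !is.finite(v)) {
      stop("missing or non-finite metadata field: ", nm)
    }
  }
  if (injected_dose_bq <= 0) stop("`injected_dose_bq` must be > 0")
  if (scan_time_s < injection_time_s) stop("scan time precedes injection time")
  if (lbm_kg <= 0) stop("`lbm_kg` must be > 0")
  decayed <- injected_dose_bq * 2^(-(scan_time_s - injection_time_s) / isotope_half_life_s)
  sul <- pmax(activity$values, 0) / (decayed / (lbm_kg * 1000))
  scalar_volume(sul, activity$spacing, activity$origin, units = "SUL")
}

#' Automatic body contour
#'
#' Thresholds the SUL volume at a partitioning threshold (default 0.1 SUL),
#' keeps the single largest 6-connected component, and fills interior holes.
#'
#' @param pet `scalar_volume` in SUL.
#' @param threshold Partitioning threshold in SUL.
#' @return 3D logical body mask.
#' @export
body_contour <- function(pet, threshold = 0.1) {
  stopifnot(inherits(pet, "scalar_volume"), pet$units == "SUL")
  mask <- pet$values >= threshold
  if (!any(mask)) stop("no body found: no voxels at or above ", threshold, " SUL")
  comp <- connected_components(mask)
  sizes <- tabulate(comp[comp > 0L])
  fill_holes(comp == which.max(sizes))
}

#' Automatically locate the liver reference VOI
#'
#' Searches candidate sphere centres on a coarse grid inside the body for a
#' sphere (default volume 3 cm^3, radius 8.947 mm) that fits entirely inside
#' the body and whose sampled mean SUL lies in a plausible liver band. Among
#' those candidates the centre minimising the coefficient of variation of a
#' *margin-enlarged* sphere is chosen: homogeneity is scored over the VOI
#' sphere grown by `margin_mm`, which penalises centres close to organ
#' boundaries and inside small homogeneous structures (renal cortex, blood
#' pool) that cannot contain an enlarged sphere of liver-like tissue — only a
#' large homogeneous organ scores well. An explicitly supplied centre
#' overrides the search.
#'
#' @param pet `scalar_volume` in SUL.
#' @param body Logical body mask from [body_contour()].
#' @param volume_cm3 Sphere volume (default 3 cm^3).
#' @param band Plausible liver mean SUL band (default 1.0 - 3.0).
#' @param stride Candidate-centre grid stride in voxels.
#' @param margin_mm Homogeneity margin added to the sphere radius when scoring
#'   candidates (default 7 mm, two PET voxels).
#' @param center_mm Optional user-supplied centre (mm); returned unchanged.
#' @return A [sphere_voi()].
#' @export
locate_liver_voi <- function(pet, body, volume_cm3 = 3, band = c(1, 3),
                             stride = 2L, margin_mm = 7, center_mm = NULL) {
  r <- sphere_radius_mm(volume_cm3)
  if (!is.null(center_mm)) return(sphere_voi(center_mm, r))
  stopifnot(inherits(pet, "scalar_volume"))
  if (!any(body)) stop("body mask is empty")
  d <- dim(pet$values)
  sphere_sums <- function(radius, with_fit) {
    off <- ball_offsets(radius, pet$spacing)
    fits <- array(TRUE, d)
    s1 <- array(0, d)
    s2 <- array(0, d)
    for (i in seq_len(nrow(off))) {
      if (with_fit) fits <- fits & shift3(body, off[i, ], fill = FALSE)
      sp <- shift3(pet$values, off[i, ], fill = 0)
      s1 <- s1 + sp
      s2 <- s2 + sp^2
    }
    list(mu = s1 / nrow(off), va = pmax(s2 / nrow(off) - (s1 / nrow(off))^2, 0),
         fits = fits)
  }
  voi_stats <- sphere_sums(r, with_fit = TRUE)
  score_stats <- sphere_sums(r + margin_mm, with_fit = FALSE)
  on_grid <- array(FALSE, d)
  on_grid[seq(1, d[1], stride), seq(1, d[2], stride), seq(1, d[3], stride)] <- TRUE
  cand <- voi_stats$fits & on_grid &
    voi_stats$mu >= band[1] & voi_stats$mu <= band[2]
  if (!any(cand)) {
    if (!any(voi_stats$fits & on_grid)) {
      stop("no candidate sphere fits inside the body")
    }
    stop("no candidate liver VOI with mean SUL in band [",
         band[1], ", ", band[2], "]")
  }
  cv <- sqrt(score_stats$va) / pmax(score_stats$mu, 1e-9)
  cv[!cand] <- Inf
  best <- arrayInd(which.min(cv), d)
  center <- pet$origin + (as.numeric(best) - 1) * pet$spacing
  sphere_voi(center, r)
}

#' Liver reference statistics
#'
#' Mean and standard deviation of SUL over the voxels whose centres lie inside
#' the sphere. The SD is the population SD (divide by n): the sampled voxels
#' are treated as the full reference population.
#'
#' @param pet `scalar_volume` in SUL.
#' @param voi A [sphere_voi()].
#' @return A `liver_stats` object: `mean_sul`, `sd_sul`, `n_voxels`.
#' @export
liver_statistics <- function(pet, voi) {
  stopifnot(inherits(pet, "scalar_volume"), inherits(voi, "sphere_voi"))
  m <- sphere_mask(pet, voi)
  if (!any(m)) stop("no voxel centres inside the VOI sphere")
  x <- pet$values[m]
  liver_stats(mean(x), sqrt(mean((x - mean(x))^2)), length(x))
}

#' @rdname liver_statistics
#' @param mean_sul,sd_sul,n_voxels Components of the statistic.
#' @export
liver_stats <- function(mean_sul, sd_sul, n_voxels = 1L) {
  if (!is.finite(mean_sul) || mean_sul <= 0) stop("`mean_sul` must be > 0")
  if (!is.finite(sd_sul) || sd_sul < 0) stop("`sd_sul` must be >= 0")
  if (n_voxels < 1) stop("`n_voxels` must be >= 1")
  structure(list(mean_sul = mean_sul, sd_sul = sd_sul,
                 n_voxels = as.integer(n_voxels)), class = "liver_stats")
}

#' PERCIST v1.0 thresholds from liver statistics
#'
#' The three liver-referenced thresholds:
#' \itemize{
#'   \item baseline assessment: `1.5 * mean + 2.0 * sd`
#'   \item reference (growth): `1.0 * mean - 2.0 * sd`
#'   \item follow-up assessment: `1.0 * mean + 2.0 * sd`
#' }
#' For any valid statistics `reference <= followup < baseline`.
#'
#' @param stats A `liver_stats` object.
#' @return A `threshold_set` with `baseline`, `reference`, `followup` (SUL).
#' @export
#' @examples
#' percist_thresholds(liver_stats(2.0, 0.3))  # 3.6, 1.4, 2.6
percist_thresholds <- function(stats) {
  stopifnot(inherits(stats, "liver_stats"))
  structure(list(
    baseline = 1.5 * stats$mean_sul + 2.0 * stats$sd_sul,
    reference = 1.0 * stats$mean_sul - 2.0 * stats$sd_sul,
    followup = 1.0 * stats$mean_sul + 2.0 * stats$sd_sul
  ), class = "threshold_set")
}

#' @export
print.liver_stats <- function(x, ...) {
  cat(sprintf("<liver_stats> mean %.4f SUL, SD %.4f SUL, n = %d\n",
              x$mean_sul, x$sd_sul, x$n_voxels))
  invisible(x)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> baseline %.4f, reference %.4f, follow-up %.4f SUL\n",
              x$baseline, x$reference, x$followup))
  invisible(x)
}
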
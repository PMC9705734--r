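# Volume and training-file I/O. PET/CT series are stored as a documented
# per-slice NIfTI container with a JSON sidecar carrying geometry and
# acquisition metadata; label volumes round-trip through single NIfTI files
# plus a vocabulary sidecar; training slices use a fixed little-endian binary
# layout plus 8-bit PNG label images. All round trips on phantom data are
# bit-exact (floating payloads are written as doubles).

required_pet_metadata <- function() {
  c("PatientWeight", "PatientHeight", "PatientSex",
    "InjectedDoseBq", "InjectionTime", "AcquisitionTime")
}

#' Write a PET (or CT) series
#'
#' Writes one transaxial slice per NIfTI file (`slice_0001.nii`, ...) plus a
#' `series.json` sidecar holding the series UID, geometry (spacing, origin,
#' dimensions), value units and acquisition metadata. Slice index encodes the
#' position along the slice axis.
#'
#' @param vol `scalar_volume`.
#' @param path Directory to create/write into.
#' @param metadata Named list; for PET series the fields
#'   `PatientWeight` (kg), `PatientHeight` (cm), `PatientSex`,
#'   `InjectedDoseBq`, `InjectionTime` (s), `AcquisitionTime` (s) are expected
#'   by [read_pet_series()].
#' @param series_uid Series identifier stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_pet_series <- function(vol, path, metadata = list(),
                             series_uid = "series-1") {
  stopifnot(inherits(vol, "scalar_volume"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$values)
  for (k in seq_len(d[3])) {
    sl <- vol$values[, , k]
    attr(sl, "pixdim") <- vol$spacing[1:2]
    RNifti::writeNifti(RNifti::asNifti(sl, datatype = "double"),
                       file.path(path, sprintf("slice_%04d.nii", k)))
  }
  side <- list(series_uid = series_uid, units = vol$units, dim = d,
               spacing_mm = vol$spacing, origin_mm = vol$origin,
               n_slices = d[3], metadata = metadata)
  jsonlite::write_json(side, file.path(path, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PET series with acquisition metadata
#'
#' Reassembles a volume from a per-slice series directory, checking geometric
#' consistency (all slices present and consecutive, uniform in-plane shape)
#' and, for PET series, that the acquisition metadata needed for SUL
#' conversion is present.
#'
#' @param path Series directory written by [write_pet_series()].
#' @param require_metadata Check for the SUL metadata fields (default TRUE;
#'   use FALSE for CT series).
#' @return List with `volume` (`scalar_volume`) and `metadata`.
#' @export
read_pet_series <- function(path, require_metadata = TRUE) {
  side_file <- file.path(path, "series.json")
  if (!file.exists(side_file)) stop("no series.json sidecar in ", path)
  side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "^slice_\\d+\\.nii$"))
  if (length(files) == 0L) stop("no slice files in ", path)
  idx <- as.integer(sub("^slice_(\\d+)\\.nii$", "\\1", files))
  if (!identical(idx, seq_len(side$n_slices)) || any(diff(idx) != 1L)) {
    stop("non-uniform slice spacing: slice indices ",
         paste(setdiff(seq_len(side$n_slices), idx), collapse = ", "),
         " missing from series")
  }
  slices <- lapply(file.path(path, files), function(f) {
    as.array(RNifti::readNifti(f))
  })
  shp <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), shp), TRUE))) {
    stop("mixed series: slice shapes are inconsistent")
  }
  vol <- array(unlist(slices, use.names = FALSE), dim = c(shp, length(slices)))
  meta <- as.list(side$metadata)
  if (isTRUE(require_metadata)) {
    missing <- setdiff(required_pet_metadata(), names(meta))
    missing <- c(missing, names(meta)[vapply(meta, function(x)
      is.null(x) || (length(x) == 1 && is.na(x)), TRUE)])
    missing <- intersect(unique(missing), required_pet_metadata())
    if (length(missing) > 0) {
      stop("missing acquisition metadata: ", paste(missing, collapse = ", "))
    }
  }
  list(
    volume = scalar_volume(vol, as.numeric(side$spacing_mm),
                           as.numeric(side$origin_mm), side$units),
    metadata = meta
  )
}

#' Write / read a label volume container
#'
#' Single-file NIfTI label volume plus a JSON sidecar recording the class
#' vocabulary (palette order = vocabulary order). Round-trip is bit-exact.
#'
#' @param labels `label_volume`.
#' @param path File path without extension; writes `<path>.nii` and
#'   `<path>.json`.
#' @return `path` invisibly / the `label_volume`.
#' @export
write_label_volume <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  arr <- labels$labels
  attr(arr, "pixdim") <- labels$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"),
                     paste0(path, ".nii"))
  jsonlite::write_json(
    list(vocabulary = labels$vocabulary, spacing_mm = labels$spacing,
         origin_mm = labels$origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  raw <- RNifti::readNifti(paste0(path, ".nii"))
  arr <- array(as.integer(raw), dim(raw))
  label_volume(arr, as.numeric(side$spacing_mm), as.numeric(side$origin_mm),
               side$vocabulary)
}

training_pair_magic <- function() 22100L  # arbitrary fixed constant

#' Write / read a training pair
#'
#' A training pair is one transaxial slice as (a) a binary two-channel matrix
#' file `<basename>.bin` — little-endian header of four int32 values
#' `{magic, rows, cols, channels}` followed by the channel-major (PET then
#' CT), column-major int16 payload — and (b) an 8-bit PNG `<basename>.png`
#' whose pixel value equals the label's vocabulary index. Both files share the
#' basename, as do all files representing the same slice.
#'
#' @param pet_slice,ct_slice Integer matrices (the encoded channels from
#'   [encode_channels()]).
#' @param label_slice Integer matrix of vocabulary indices.
#' @param dir Output directory.
#' @param basename Shared basename (no extension).
#' @return Invisibly, the two file paths / a list with `pet`, `ct`, `label`.
#' @export
write_training_pair <- function(pet_slice, ct_slice, label_slice, dir,
                                basename) {
  if (!identical(dim(pet_slice), dim(ct_slice)) ||
      !identical(dim(pet_slice), dim(label_slice))) {
    stop("slice shape mismatch between channels and labels")
  }
  if (max(label_slice) > 255L || min(label_slice) < 0L) {
    stop("label indices must fit 8 bits")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bin <- file.path(dir, paste0(basename, ".bin"))
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(c(training_pair_magic(), nrow(pet_slice), ncol(pet_slice), 2L),
           con, size = 4L, endian = "little")
  writeBin(as.integer(pet_slice), con, size = 2L, endian = "little")
  writeBin(as.integer(ct_slice), con, size = 2L, endian = "little")
  close(con)
  on.exit()
  png_file <- file.path(dir, paste0(basename, ".png"))
  png::writePNG(matrix(as.integer(label_slice), nrow(label_slice)) / 255,
                png_file)
  invisible(c(bin = bin, png = png_file))
}

#' @rdname write_training_pair
#' @export
read_training_pair <- function(dir, basename) {
  bin <- file.path(dir, paste0(basename, ".bin"))
  con <- file(bin, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 4L, size = 4L, endian = "little")
  if (hdr[1] != training_pair_magic()) stop("bad magic in ", bin)
  rows <- hdr[2]; cols <- hdr[3]; nch <- hdr[4]
  payload <- readBin(con, "integer", rows * cols * nch, size = 2L,
                     signed = TRUE, endian = "little")
  lab <- png::readPNG(file.path(dir, paste0(basename, ".png")))
  if (length(dim(lab)) == 3L) lab <- lab[, , 1]
  list(
    pet = matrix(payload[seq_len(rows * cols)], rows),
    ct = matrix(payload[rows * cols + seq_len(rows * cols)], rows),
    label = matrix(as.integer(round(lab * 255)), rows)
  )
}

#' Export a preprocessed, annotated study as training files
#'
#' Writes every transaxial slice of a preprocessed study as a training pair,
#' named `<study_id>_s<index>`.
#'
#' @param processed List from [preprocess_study()] with `labels`.
#' @param study_id Study identifier used in basenames.
#' @param dir Output directory.
#' @return Character vector of basenames, invisibly.
#' @export
export_training_slices <- function(processed, study_id, dir) {
  samples <- study_to_samples(processed, study_id)
  base <- vapply(samples, function(s) {
    b <- sprintf("%s_s%03d", s$study_id, s$slice_index)
    write_training_pair(s$pet_channel, s$ct_channel, s$label_slice, dir, b)
    b
  }, "")
  invisible(base)
}
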
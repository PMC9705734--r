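#' Tissue class vocabulary
#'
#' The fixed 16-entry tissue-class vocabulary used throughout the workflow.
#' Indices are stable and zero-based: `Background` is 0, `Nominal` is 1,
#' `Reference` (the liver reference VOI proxy) is 2, and so on. Label volumes,
#' PNG label slices and network outputs all use these indices.
#'
#' @return Character vector of 16 class names; index of a name is
#'   `match(name, class_vocabulary()) - 1L`.
#' @export
#' @examples
#' class_vocabulary()
#' class_index("Primary_Lesion")
class_vocabulary <- function() {
  c("Background", "Nominal", "Reference", "Primary_Lesion", "Lymphadenopathy",
    "Bladder", "Bowel", "Brain", "Brown_Fat", "Heart", "Kidney",
    "Other_Metastasis", "Salivary", "Spleen", "Thyroid", "Not_Significant")
}

#' Zero-based index of a tissue class
#'
#' @param name Class name(s).
#' @param vocabulary Character vector of class names (default the standard 16).
#' @return Integer index (0-based) into `vocabulary`.
#' @export
class_index <- function(name, vocabulary = class_vocabulary()) {
  i <- match(name, vocabulary)
  if (anyNA(i)) {
    stop("unknown tissue class: ", paste(name[is.na(i)], collapse = ", "))
  }
  i - 1L
}

#' Name of a tissue class index
#'
#' @param index Zero-based integer index (vectorised).
#' @param vocabulary Character vector of class names.
#' @return Character vector of class names.
#' @export
class_name <- function(index, vocabulary = class_vocabulary()) {
  if (any(index < 0 | index >= length(vocabulary))) {
    stop("class index out of range 0..", length(vocabulary) - 1L)
  }
  vocabulary[index + 1L]
}

#' Classes pooled as "Disease"
#'
#' Primary lesions and lymphadenopathy are pooled into a single Disease class
#' for detection-level evaluation.
#'
#' @return Character vector of the two pooled class names.
#' @export
disease_classes <- function() c("Primary_Lesion", "Lymphadenopathy")

#' Organ and lesion tissue classes
#'
#' The classes eligible for Round-Robin growth and for follow-up-threshold
#' clearing: everything except `Background`, `Nominal` and the `Reference`
#' VOI.
#'
#' @param vocabulary Class vocabulary.
#' @return Character vector of tissue class names.
#' @export
tissue_class_names <- function(vocabulary = class_vocabulary()) {
  setdiff(vocabulary, c("Background", "Nominal", "Reference"))
}
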
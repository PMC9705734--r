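#' Voxel-level confusion matrix
#'
#' Counts voxels by (truth class, predicted class) over co-registered label
#' volumes sharing a vocabulary: `matrix[t, p]` is the number of voxels with
#' truth `t` predicted as `p`. The total equals the voxel count.
#'
#' @param pred,truth Co-registered `label_volume`s with identical vocabulary.
#' @return A `confusion_matrix` object (counts matrix + vocabulary).
#' @export
confusion <- function(pred, truth) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  stopifnot_same_geometry(pred, truth)
  if (!identical(pred$vocabulary, truth$vocabulary)) {
    stop("vocabulary mismatch between prediction and truth")
  }
  nc <- length(pred$vocabulary)
  code <- as.integer(truth$labels) * nc + as.integer(pred$labels) + 1L
  m <- matrix(tabulate(code, nbins = nc * nc), nc, nc, byrow = TRUE,
              dimnames = list(truth = pred$vocabulary,
                              prediction = pred$vocabulary))
  structure(list(counts = m, vocabulary = pred$vocabulary),
            class = "confusion_matrix")
}

#' Pool primary lesions and lymphadenopathy into a Disease class
#'
#' Sums the `Primary_Lesion` and `Lymphadenopathy` rows and columns of a
#' confusion matrix into a single `Disease` row/column; the total count is
#' conserved.
#'
#' @param cm A `confusion_matrix` whose vocabulary contains both classes.
#' @return A pooled `confusion_matrix` (one class fewer).
#' @export
pool_disease <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  dc <- disease_classes()
  if (!all(dc %in% cm$vocabulary)) stop("disease classes not in vocabulary")
  keep <- cm$vocabulary
  i1 <- match(dc[1], keep)
  i2 <- match(dc[2], keep)
  m <- cm$counts
  m[i1, ] <- m[i1, ] + m[i2, ]
  m[, i1] <- m[, i1] + m[, i2]
  m <- m[-i2, -i2, drop = FALSE]
  vocab <- keep[-i2]
  vocab[vocab == dc[1]] <- "Disease"
  dimnames(m) <- list(truth = vocab, prediction = vocab)
  structure(list(counts = m, vocabulary = vocab), class = "confusion_matrix")
}

#' One-vs-rest per-class metrics
#'
#' Sensitivity, specificity, Dice and Jaccard for one class of a confusion
#' matrix, computed one-vs-rest: TP is the diagonal entry, FN the rest of the
#' truth row, FP the rest of the prediction column, TN the remainder. Metrics
#' with an empty denominator (e.g. sensitivity of a class absent from the
#' truth) are reported as `NA` (not applicable), never as 0.
#'
#' @param cm A `confusion_matrix`.
#' @param class Class name.
#' @return Named list: `sensitivity`, `specificity`, `dice`, `jaccard`.
#' @export
class_metrics <- function(cm, class) {
  stopifnot(inherits(cm, "confusion_matrix"))
  i <- match(class, cm$vocabulary)
  if (is.na(i)) stop("class '", class, "' not in vocabulary")
  m <- cm$counts
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       dice = ratio(2 * tp, 2 * tp + fp + fn),
       jaccard = ratio(tp, tp + fp + fn))
}

#' Study-level Disease metrics
#'
#' Pools `Primary_Lesion` and `Lymphadenopathy` voxels into per-volume Disease
#' masks and computes 3D Dice and Jaccard between the predicted and truth
#' masks, plus the percent difference in SUL-Max,
#' `100 * (SULmax_pred - SULmax_truth) / SULmax_truth`. When both masks are
#' empty the study is a concordant negative: not scorable. When exactly one
#' mask is empty the study is discordant: Dice and Jaccard are 0 (scorable),
#' the SUL-Max difference is incalculable (`NA`).
#'
#' @param pred,truth Co-registered `label_volume`s.
#' @param pet Co-registered `scalar_volume` in SUL.
#' @param study_id Identifier recorded in the result.
#' @return One-row data frame: `study_id`, `dice`, `jaccard`,
#'   `pct_delta_sulmax`, `scorable`, `truth_has_disease`,
#'   `pred_has_disease`.
#' @export
study_metrics <- function(pred, truth, pet, study_id = "study") {
  stopifnot_same_geometry(pred, truth)
  stopifnot_same_geometry(pred, pet)
  di <- class_index(disease_classes(), pred$vocabulary)
  pm <- pred$labels %in% di
  tm <- truth$labels %in% di
  has_p <- any(pm)
  has_t <- any(tm)
  if (!has_p && !has_t) {
    return(data.frame(study_id = study_id, dice = NA_real_,
                      jaccard = NA_real_, pct_delta_sulmax = NA_real_,
                      scorable = FALSE, truth_has_disease = FALSE,
                      pred_has_disease = FALSE))
  }
  inter <- sum(pm & tm)
  dice <- 2 * inter / (sum(pm) + sum(tm))
  jac <- inter / sum(pm | tm)
  pct <- if (has_p && has_t) {
    100 * (max(pet$values[pm]) - max(pet$values[tm])) / max(pet$values[tm])
  } else {
    NA_real_
  }
  data.frame(study_id = study_id, dice = dice, jaccard = jac,
             pct_delta_sulmax = pct, scorable = TRUE,
             truth_has_disease = has_t, pred_has_disease = has_p)
}

#' Aggregate study metrics (CLEANED / CORRECTED)
#'
#' Two aggregation conventions over per-study Disease metrics:
#' \describe{
#'   \item{CLEANED}{studies with any incalculable score are removed — only
#'     studies where both truth and prediction contain Disease remain.}
#'   \item{CORRECTED}{all studies are kept and each incalculable score is
#'     replaced by the perfect value for that metric (1.0 for Dice and
#'     Jaccard, 0\% for the SUL-Max difference).}
#' }
#'
#' @param metrics Data frame of rows from [study_metrics()].
#' @param mode `"CLEANED"` or `"CORRECTED"`.
#' @return Data frame with one row per metric (`dice`, `jaccard`,
#'   `pct_delta_sulmax`) and columns `mean`, `sd`, `median`, plus attribute-
#'   free column `n` (studies aggregated).
#' @export
aggregate_study_metrics <- function(metrics, mode = c("CLEANED", "CORRECTED")) {
  mode <- match.arg(mode)
  if (nrow(metrics) == 0L) stop("no study metrics to aggregate")
  if (mode == "CLEANED") {
    keep <- metrics$truth_has_disease & metrics$pred_has_disease
    m <- metrics[keep, , drop = FALSE]
    if (nrow(m) == 0L) stop("no calculable studies under CLEANED")
  } else {
    m <- metrics
    m$dice[is.na(m$dice)] <- 1.0
    m$jaccard[is.na(m$jaccard)] <- 1.0
    m$pct_delta_sulmax[is.na(m$pct_delta_sulmax)] <- 0.0
  }
  summarise <- function(x) c(mean = mean(x), sd = stats::sd(x),
                             median = stats::median(x))
  out <- rbind(dice = summarise(m$dice), jaccard = summarise(m$jaccard),
               pct_delta_sulmax = summarise(m$pct_delta_sulmax))
  data.frame(metric = rownames(out), out, n = nrow(m), mode = mode,
             row.names = NULL)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> ", sum(x$counts), " voxels, ",
      length(x$vocabulary), " classes\n", sep = "")
  print(x$counts)
  invisible(x)
}
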
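test_that("confusion matrices count truth rows against prediction columns", {
  truth <- toy_labels(array(sample(0:15, 6^3, TRUE), c(6, 6, 6)))
  cm_self <- confusion(truth, truth)
  expect_equal(unname(cm_self$counts), diag(tabulate(truth$labels + 1L, 16)))
  expect_equal(sum(cm_self$counts), 6^3)
  # hand-counted 3-voxel toy: truths A,A,B; preds A,B,B
  tr <- toy_labels(array(c(9L, 9L, 5L), c(3, 1, 1)))
  pr <- toy_labels(array(c(9L, 5L, 5L), c(3, 1, 1)))
  cm <- confusion(pr, tr)
  expect_equal(cm$counts["Heart", "Heart"], 1)
  expect_equal(cm$counts["Heart", "Bladder"], 1)
  expect_equal(cm$counts["Bladder", "Bladder"], 1)
  expect_equal(sum(cm$counts), 3)
})

test_that("disease pooling merges the two lesion classes and conserves totals", {
  tr <- toy_labels(array(c(rep(3L, 5), rep(4L, 3), rep(1L, 8)), c(16, 1, 1)))
  cm <- confusion(tr, tr)
  pooled <- pool_disease(cm)
  expect_equal(sum(pooled$counts), sum(cm$counts))
  expect_equal(pooled$counts["Disease", "Disease"], 8)
  expect_length(pooled$vocabulary, 15)
  expect_false("Lymphadenopathy" %in% pooled$vocabulary)
  # with no Lymphadenopathy voxels the Disease row equals the lesion row
  tr2 <- toy_labels(array(c(rep(3L, 5), rep(1L, 11)), c(16, 1, 1)))
  cm2 <- confusion(tr2, tr2)
  p2 <- pool_disease(cm2)
  expect_equal(p2$counts["Disease", ],
               cm2$counts["Primary_Lesion", -class_index("Lymphadenopathy") - 1L],
               ignore_attr = TRUE)
})

test_that("one-vs-rest metrics match hand computation and flag empty classes", {
  tr <- toy_labels(array(rep(c(3L, 1L), c(10, 90)), c(100, 1, 1)))
  pr <- tr
  pr$labels[9:10] <- 1L   # 2 false negatives
  pr$labels[11:12] <- 3L  # 2 false positives
  m <- class_metrics(confusion(pr, tr), "Primary_Lesion")
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$dice, 0.8)
  expect_equal(m$jaccard, 2 / 3, tolerance = 1e-12)
  expect_equal(m$specificity, 88 / 90)
  # perfect prediction
  mp <- class_metrics(confusion(tr, tr), "Primary_Lesion")
  expect_equal(unlist(mp), c(sensitivity = 1, specificity = 1, dice = 1,
                             jaccard = 1))
  # class absent from truth and prediction: undefined, not zero
  ma <- class_metrics(confusion(tr, tr), "Spleen")
  expect_true(is.na(ma$sensitivity))
  expect_true(is.na(ma$dice))
  expect_equal(ma$specificity, 1)
})

test_that("study metrics pool Disease and handle empty masks per convention", {
  pet <- volume_with(c(10, 10, 4), base = 1)
  mk <- function(vox3, vox4 = integer()) {
    a <- array(1L, c(10, 10, 4))
    a[vox3] <- 3L
    a[vox4] <- 4L
    toy_labels(a)
  }
  # identical non-empty masks, identical PET
  t1 <- mk(1:6, 50:53)
  m <- study_metrics(t1, t1, pet)
  expect_equal(m$dice, 1)
  expect_equal(m$jaccard, 1)
  expect_equal(m$pct_delta_sulmax, 0)
  expect_true(m$scorable)
  # masks 10 and 10 with overlap 8
  m2 <- study_metrics(mk(1:10), mk(3:12), pet)
  expect_equal(m2$dice, 0.8)
  expect_equal(m2$jaccard, 8 / 12, tolerance = 1e-12)
  # both empty: concordant negative, not scorable
  m3 <- study_metrics(mk(integer()), mk(integer()), pet)
  expect_false(m3$scorable)
  expect_true(is.na(m3$dice))
  # discordant: scorable with zero overlap, SUL-Max difference incalculable
  m4 <- study_metrics(mk(1:5), mk(integer()), pet)
  expect_true(m4$scorable)
  expect_equal(m4$dice, 0)
  expect_true(is.na(m4$pct_delta_sulmax))
  expect_true(m4$pred_has_disease)
  expect_false(m4$truth_has_disease)
  # SUL-Max percent difference uses (pred - truth)/truth
  pet2 <- pet
  pet2$values[1:5] <- 2
  pet2$values[21:25] <- 2.5
  m5 <- study_metrics(mk(21:25), mk(1:5), pet2)
  expect_equal(m5$pct_delta_sulmax, 100 * (2.5 - 2) / 2)
})

test_that("CLEANED and CORRECTED aggregation follow the stated conventions", {
  base <- do.call(rbind, lapply(1:59, function(i) {
    data.frame(study_id = paste0("s", i), dice = 0.9, jaccard = 0.85,
               pct_delta_sulmax = 1, scorable = TRUE,
               truth_has_disease = TRUE, pred_has_disease = TRUE)
  }))
  # 4 concordant negatives and 2 discordant cases
  neg <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(study_id = paste0("n", i), dice = NA_real_,
               jaccard = NA_real_, pct_delta_sulmax = NA_real_,
               scorable = FALSE, truth_has_disease = FALSE,
               pred_has_disease = FALSE)
  }))
  dis <- do.call(rbind, lapply(1:2, function(i) {
    data.frame(study_id = paste0("d", i), dice = 0, jaccard = 0,
               pct_delta_sulmax = NA_real_, scorable = TRUE,
               truth_has_disease = i == 1, pred_has_disease = i == 2)
  }))
  all65 <- rbind(base, neg, dis)
  cleaned <- aggregate_study_metrics(all65, "CLEANED")
  corrected <- aggregate_study_metrics(all65, "CORRECTED")
  expect_equal(unique(cleaned$n), 59)
  expect_equal(unique(corrected$n), 65)
  # with no non-scorable studies both modes agree
  same <- aggregate_study_metrics(base, "CLEANED")
  same2 <- aggregate_study_metrics(base, "CORRECTED")
  expect_equal(same$mean, same2$mean)
  # corrected mean rises toward 1 when perfect scores are substituted
  expect_gt(corrected[corrected$metric == "dice", "mean"][1] ,
            mean(c(rep(0.9, 59), 0, 0)) - 1e-12)
  expect_error(aggregate_study_metrics(base[0, ], "CLEANED"), "no study")
})

test_that("metrics agree with brute-force voxel counting on random volumes", {
  set.seed(29)
  for (i in 1:20) {
    d <- c(sample(3:8, 1), sample(3:8, 1), sample(3:8, 1))
    tr <- array(sample(0:15, prod(d), TRUE, prob = c(8, 8, rep(1, 14))), d)
    pr <- array(sample(0:15, prod(d), TRUE, prob = c(8, 8, rep(1, 14))), d)
    cm <- confusion(toy_labels(pr), toy_labels(tr))
    cls <- sample(class_vocabulary(), 1)
    counts <- oracle_class_counts(as.integer(pr), as.integer(tr),
                                  class_index(cls))
    m <- class_metrics(cm, cls)
    if (counts["tp"] + counts["fn"] > 0) {
      expect_equal(m$sensitivity,
                   counts[["tp"]] / (counts[["tp"]] + counts[["fn"]]))
    } else {
      expect_true(is.na(m$sensitivity))
    }
    if (!is.na(m$dice)) {
      # jaccard = dice / (2 - dice) identity
      expect_equal(m$jaccard, m$dice / (2 - m$dice), tolerance = 1e-12)
    }
  }
})
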
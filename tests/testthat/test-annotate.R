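test_that("candidate segmentation enforces the 7-voxel minimum cluster size", {
  a <- array(0, c(24, 8, 8))
  a[2:7, 3, 3] <- 5    # 6 connected voxels: dropped
  a[12:18, 3, 3] <- 5  # 7 connected voxels: retained
  comps <- segment_candidates(toy_volume(a), threshold = 4)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$size, 7)
  # sub-threshold volume: empty list
  expect_length(segment_candidates(volume_with(c(5, 5, 5), base = 1), 4), 0)
})

test_that("candidates are sorted by descending peak SUL", {
  a <- array(0, c(30, 8, 8))
  a[2:9, 3, 3] <- 5
  a[12:19, 3, 3] <- 7
  a[22:29, 3, 3] <- 6
  comps <- segment_candidates(toy_volume(a), threshold = 4)
  expect_equal(vapply(comps, `[[`, 0, "peak_sul"), c(7, 6, 5))
  expect_equal(vapply(comps, `[[`, 0L, "id"), 1:3)
})

test_that("planted phantom lesions are segmented to exactly their truth masks", {
  spec <- default_phantom_spec(seed = 23)
  ph <- generate_phantom(spec)
  st <- liver_statistics(ph$pet,
                         locate_liver_voi(ph$pet, body_contour(ph$pet)))
  thr <- percist_thresholds(st)
  comps <- segment_candidates(ph$pet, thr$baseline)
  comps <- assign_classes_from_truth(comps, ph$truth)
  for (r in c("primary", "node")) {
    m <- which(phantom_region_mask(spec, r))
    cls <- if (r == "primary") "Primary_Lesion" else "Lymphadenopathy"
    match_comp <- Filter(function(cc) cc$assigned_class == cls, comps)
    expect_length(match_comp, 1)
    expect_setequal(match_comp[[1]]$voxels, m)
  }
})

test_that("label-map assembly partitions every voxel", {
  pet <- volume_with(c(16, 16, 8), base = 0.5, spacing = c(2, 2, 2))
  body <- array(FALSE, c(16, 16, 8))
  body[3:14, 3:14, 2:7] <- TRUE
  voi <- sphere_voi(c(12, 12, 8), 3)
  labs <- assemble_label_map(pet, body, voi)
  expect_setequal(unique(as.integer(labs$labels)),
                  class_index(c("Background", "Nominal", "Reference")))
  # with one 10-voxel component
  cmp <- structure(list(id = 1L, voxels = which(body)[200:209], size = 10L,
                        peak_sul = 5, assigned_class = "Primary_Lesion"),
                   class = "candidate_component")
  labs2 <- assemble_label_map(pet, body, voi, list(cmp))
  expect_equal(sum(labs2$labels == class_index("Primary_Lesion")), 10)
  # partition conservation
  expect_equal(sum(tabulate(labs2$labels + 1L, 16)), prod(dim(pet$values)))
})

test_that("component overlaps are rejected", {
  pet <- volume_with(c(10, 10, 10), base = 0.5)
  body <- array(TRUE, c(10, 10, 10))
  voi <- sphere_voi(c(2, 2, 2), 1.5)
  mk <- function(id, vox) structure(
    list(id = id, voxels = vox, size = length(vox), peak_sul = 5,
         assigned_class = "Heart"), class = "candidate_component")
  expect_error(
    assemble_label_map(pet, body, voi, list(mk(1, 500:509), mk(2, 505:514))),
    "overlap")
  ref_vox <- which(sphere_mask(pet, voi))
  expect_error(assemble_label_map(pet, body, voi, list(mk(1, ref_vox[1:3]))),
               "Reference")
  expect_error(assemble_label_map(pet, body, voi, list(
    structure(list(id = 1, voxels = 1:8, size = 8, peak_sul = 2,
                   assigned_class = NA_character_),
              class = "candidate_component"))), "no assigned class")
})

test_that("growth with an unreachable threshold changes nothing", {
  ph <- generate_phantom(default_phantom_spec(seed = 31))
  ann <- annotate_study(ph$pet,
                        function(x) assign_classes_from_truth(x, ph$truth),
                        grow = FALSE)
  grown <- round_robin_grow(ann$labels, ph$pet, growth_threshold = 99,
                            grow_classes = "Heart")
  expect_identical(grown$labels, ann$labels$labels)
})

test_that("growth along a thin eligible line matches the literal step simulator", {
  # seed region abutting a 5-voxel 1-voxel-thick eligible line
  d <- c(9, 5, 5)
  pet <- array(0, d)
  labels <- array(class_index("Nominal"), d)
  labels[2, 3, 3] <- class_index("Heart")
  pet[2, 3, 3] <- 5
  pet[3:7, 3, 3] <- 3  # eligible line
  grown <- round_robin_grow(toy_labels(labels), toy_volume(pet),
                            growth_threshold = 2.5, grow_classes = "Heart")
  oracle <- oracle_rr_grow(labels, pet, 2.5, class_index("Heart"))
  expect_identical(grown$labels, oracle)
  # the line is 1-voxel thick, so the pool erodes away entirely after the
  # first annexation: exactly one voxel is annexed
  expect_equal(sum(oracle == class_index("Heart")), 2)
})

test_that("contended voxels go to the hotter frontier, ties to the lower class", {
  d <- c(5, 5, 3)
  pet <- array(0, d)
  labels <- array(class_index("Nominal"), d)
  labels[2, 3, 2] <- class_index("Heart")     # index 9
  labels[4, 3, 2] <- class_index("Bladder")   # index 5
  pet[2, 3, 2] <- 6   # hotter frontier
  pet[4, 3, 2] <- 4
  pet[3, 3, 2] <- 3   # contended voxel
  grown <- round_robin_grow(toy_labels(labels), toy_volume(pet), 2.5,
                            c("Heart", "Bladder"))
  expect_equal(grown$labels[3, 3, 2], class_index("Heart"))
  # equal frontiers: lower vocabulary index (Bladder) wins
  pet[2, 3, 2] <- 4
  grown2 <- round_robin_grow(toy_labels(labels), toy_volume(pet), 2.5,
                             c("Heart", "Bladder"))
  expect_equal(grown2$labels[3, 3, 2], class_index("Bladder"))
  # class iteration order cannot matter: oracle agrees
  oracle <- oracle_rr_grow(labels, pet, 2.5,
                           class_index(c("Bladder", "Heart")))
  expect_identical(grown2$labels, oracle)
})

test_that("grown regions never overwrite non-Nominal labels and respect the threshold", {
  ph <- generate_phantom(default_phantom_spec(seed = 37))
  ann <- annotate_study(ph$pet,
                        function(x) assign_classes_from_truth(x, ph$truth),
                        grow = FALSE)
  before <- ann$labels$labels
  grown <- grow_tissue_classes(ann$labels, ph$pet, 2.5)
  after <- grown$labels
  changed <- before != after
  expect_true(all(before[changed] == class_index("Nominal")))
  expect_true(all(ph$pet$values[changed] >= 2.5))
  # label partition conservation
  expect_equal(sum(tabulate(after + 1L, 16)), length(after))
})

test_that("lowering the growth threshold never shrinks a grown region", {
  for (seed in 1:5) {
    cs <- random_growth_case(c(7, 7, 7), n_seeds = 1, seed = seed)
    lab <- toy_labels(cs$labels)
    pet <- toy_volume(cs$pet)
    hi <- round_robin_grow(lab, pet, 2.0, cs$grow_classes)
    lo <- round_robin_grow(lab, pet, 1.0, cs$grow_classes)
    gi <- class_index(cs$grow_classes[1])
    expect_true(all(lo$labels[hi$labels == gi] == gi))
  }
})

test_that("reference refinement grows a superset and recovers the liver mean", {
  spec <- big_liver_spec(seed = 41)
  ph <- generate_phantom(spec)
  body <- body_contour(ph$pet)
  voi <- locate_liver_voi(ph$pet, body)
  labels <- assemble_label_map(ph$pet, body, voi)
  ref <- refine_reference(labels, ph$pet)
  ref_idx <- class_index("Reference")
  vox0 <- which(labels$labels == ref_idx)
  vox1 <- which(ref$labels$labels == ref_idx)
  expect_true(all(vox0 %in% vox1))
  expect_gt(length(vox1), length(vox0))
  expect_lt(abs(ref$stats$mean_sul - 2.2), 0.1)
  # isolated reference with no eligible neighbours keeps its stats
  d <- c(7, 7, 7)
  pet2 <- array(0.2, d)
  lab2 <- array(class_index("Nominal"), d)
  lab2[4, 4, 4] <- ref_idx
  pet2[4, 4, 4] <- 2.0
  ref2 <- refine_reference(toy_labels(lab2), toy_volume(pet2))
  expect_equal(ref2$stats$n_voxels, 1L)
  expect_equal(ref2$stats$mean_sul, 2.0)
  expect_error(refine_reference(toy_labels(array(1L, d)), toy_volume(pet2)),
               "Reference region absent")
})

test_that("class weights are normalised reciprocal frequencies", {
  # two equal classes in a 2-entry vocabulary -> both weights 1
  lab <- matrix(c(0L, 1L), 2, 4)
  w <- class_weights(list(lab), vocabulary = c("A", "B"))
  expect_equal(unname(w), c(1, 1))
  # class A three times class B -> weight_B = 3 * weight_A
  lab2 <- array(c(rep(0L, 9), rep(1L, 3)), c(12, 1, 1))
  w2 <- class_weights(list(lab2), vocabulary = c("A", "B"))
  expect_equal(unname(w2[2] / w2[1]), 3)
  expect_equal(mean(w2), 1)
  # absent classes get zero weight
  w3 <- class_weights(list(array(0L, c(3, 3, 3))))
  expect_equal(unname(w3["Heart"]), 0)
  expect_equal(unname(w3["Background"]), 1)
})
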
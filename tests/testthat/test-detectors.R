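test_that("reference detector finds separated in-focus organoids at IoU >= 0.7", {
  sp <- scene_spec(width = 450, height = 450, n_organoids = 3,
                   overlap_allowed = FALSE, defocus_fraction = 0,
                   illumination_gradient = 0, noise_sigma = 0.01, seed = 11)
  sc <- generate_scene(sp)
  dets <- reference_blob_detect(as.array(sc$image))
  expect_identical(nrow(dets), 3L)
  m <- greedy_match_boxes(sc$ground_truth$boxes, dets, 0.7)
  expect_identical(nrow(m$pairs), 3L)
  validate_detector_output(dets, 450)
})

test_that("heavily defocused organoids are rejected by the focus filter", {
  sp <- scene_spec(width = 450, height = 450, n_organoids = 3,
                   overlap_allowed = FALSE, defocus_fraction = 1 / 3,
                   defocus_sigma = 10, illumination_gradient = 0,
                   noise_sigma = 0.01, seed = 11)
  sc <- generate_scene(sp)
  dets <- reference_blob_detect(as.array(sc$image))
  blurred <- which(!sc$ground_truth$in_focus)
  expect_identical(length(blurred), 1L)
  m <- greedy_match_boxes(sc$ground_truth$boxes, dets, 0.5)
  expect_false(blurred %in% m$pairs$a)
  in_focus <- which(sc$ground_truth$in_focus)
  expect_true(all(in_focus %in% m$pairs$a))
})

test_that("blank and near-blank patches produce no detections", {
  blank <- matrix(0.8, 300, 300)
  expect_identical(nrow(reference_blob_detect(blank)), 0L)
  set.seed(5)
  noisy <- blank + matrix(rnorm(300 * 300, 0, 0.01), 300, 300)
  cfg <- detector_config(threshold_mode = "fixed", fixed_threshold = 0.05)
  expect_identical(nrow(reference_blob_detect(noisy, cfg)), 0L)
  expect_error(reference_blob_detect(matrix(c(NA, runif(99)), 10, 10)), "finite")
  expect_error(reference_blob_detect(matrix(0.5, 20, 30)), "square")
})

test_that("reference detection is deterministic and translation-equivariant", {
  sp <- scene_spec(width = 220, height = 220, n_organoids = 1,
                   radius_range = c(20, 30), overlap_allowed = FALSE,
                   defocus_fraction = 0, illumination_gradient = 0,
                   noise_sigma = 0, seed = 3)
  sc <- generate_scene(sp)
  base <- matrix(round(sp$background * 255) / 255, 450, 450)
  put <- function(dx, dy) {
    out <- base
    out[dx + 1:220, dy + 1:220] <- as.array(sc$image)
    out
  }
  d1 <- reference_blob_detect(put(40, 60))
  d1_again <- reference_blob_detect(put(40, 60))
  expect_identical(d1, d1_again)
  d2 <- reference_blob_detect(put(40 + 17, 60 + 23))
  expect_identical(nrow(d1), 1L)
  expect_identical(nrow(d2), 1L)
  expect_equal(d2$xmin - d1$xmin, 17)
  expect_equal(d2$ymin - d1$ymin, 23)
  expect_equal(d2$xmax - d1$xmax, 17)
  expect_equal(d2$ymax - d1$ymax, 23)
})

test_that("raising the score floor never adds detections", {
  sp <- easy_scene_spec(21, width = 450, height = 450, n = 5)
  sc <- generate_scene(sp)
  patch <- as.array(sc$image)
  floors <- c(0, 0.2, 0.5, 0.8, 1)
  counts <- vapply(floors, function(f)
    nrow(reference_blob_detect(patch, detector_config(score_floor = f))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("score_threshold_filter keeps order and respects bounds", {
  d <- detections(boxes(c(0, 20, 40), 0, c(10, 30, 50), 10),
                  score = c(0.3, 0.9, 0.8))
  expect_identical(score_threshold_filter(d, 0), d)
  expect_identical(nrow(score_threshold_filter(d, 0.5)), 2L)
  expect_identical(score_threshold_filter(d, 0.5)$score, c(0.9, 0.8))
  expect_identical(nrow(score_threshold_filter(d, 1)), 0L)
  expect_error(score_threshold_filter(d, 1.5))
})

test_that("the oracle backend returns ground truth clipped to the tile", {
  gt <- boxes(c(10, 430, 600), c(10, 100, 200), c(60, 480, 650), c(60, 150, 250))
  det <- make_oracle_detector(gt)
  d <- det(matrix(0, 450, 450), origin = c(0, 0))
  expect_identical(nrow(d), 2L)            # third box wholly outside
  expect_identical(d$xmax[2], 450)         # second box clipped at the frame
  expect_true(all(d$score == 1))
  validate_detector_output(d, 450)
})

test_that("the detector output contract rejects out-of-frame boxes and bad scores", {
  good <- detections(boxes(0, 0, 10, 10), 0.5)
  expect_silent(validate_detector_output(good, 450))
  bad <- good; bad$xmax <- 500
  expect_error(validate_detector_output(bad, 450), "outside the patch")
})
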
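test_that("scenes are fully determined by their seed", {
  sp <- scene_spec(width = 400, height = 300, n_organoids = 8, seed = 5)
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(as.array(s1$image), as.array(s2$image))
  expect_identical(s1$ground_truth, s2$ground_truth)
  sp2 <- sp; sp2$seed <- 6
  expect_false(identical(as.array(generate_scene(sp2)$image), as.array(s1$image)))
})

test_that("an empty scene is pure background with empty ground truth", {
  sp <- scene_spec(width = 200, height = 150, n_organoids = 0,
                   illumination_gradient = 0, noise_sigma = 0, seed = 1)
  s <- generate_scene(sp)
  expect_identical(nrow(s$ground_truth$boxes), 0L)
  expect_identical(length(unique(as.numeric(s$image))), 1L)
})

test_that("non-overlap placement yields pairwise disjoint ground-truth boxes", {
  sp <- scene_spec(width = 800, height = 600, n_organoids = 5,
                   overlap_allowed = FALSE, seed = 9)
  gt <- generate_scene(sp)$ground_truth$boxes
  expect_identical(nrow(gt), 5L)
  iom <- iou_matrix(gt, gt); diag(iom) <- 0
  expect_true(all(iom == 0))
  # impossible packing errors out instead of looping forever
  sp_bad <- scene_spec(width = 130, height = 130, n_organoids = 50,
                       radius_range = c(30, 40), overlap_allowed = FALSE,
                       max_place_tries = 20, seed = 2)
  expect_error(generate_scene(sp_bad), "could not place")
})

test_that("ground-truth boxes tightly bound the rendered organoid", {
  sp <- scene_spec(width = 300, height = 300, n_organoids = 1,
                   radius_range = c(25, 45), defocus_fraction = 0,
                   illumination_gradient = 0, noise_sigma = 0, seed = 13)
  for (seed in c(13, 14, 15, 16)) {
    sp$seed <- seed
    s <- generate_scene(sp)
    img <- as.array(s$image)
    bg <- max(img)
    # foreground: darker than background by more than half the rim contrast
    fg <- which(img < bg - (sp$background - sp$rim_intensity) / 2, arr.ind = TRUE)
    gx <- fg[, 1] - 1; gy <- fg[, 2] - 1
    b <- s$ground_truth$boxes
    expect_true(all(gx >= b$xmin & gx < b$xmax & gy >= b$ymin & gy < b$ymax))
    # the foreground touches all four sides within 1 px
    expect_lte(min(gx) - b$xmin, 1); expect_lte(b$xmax - 1 - max(gx), 1)
    expect_lte(min(gy) - b$ymin, 1); expect_lte(b$ymax - 1 - max(gy), 1)
  }
})

test_that("sampled organoid sizes track the configured uniform range", {
  sp <- scene_spec(width = 3000, height = 2250, n_organoids = 600,
                   radius_range = c(15, 60), seed = 99)
  ax <- generate_scene(sp)$ground_truth$true_axes
  expect_identical(nrow(ax), 600L)
  mid <- mean(c(15, 60))
  expect_lt(abs(mean(ax$semi_major) - mid) / mid, 0.05)
  expect_true(all(ax$semi_minor <= ax$semi_major))
  expect_true(all(ax$semi_major >= 15 & ax$semi_major <= 60))
})

test_that("fixture datasets round-trip through the annotation CSV", {
  dir <- withr::local_tempdir()
  sp <- scene_spec(width = 450, height = 450, n_organoids = 3,
                   overlap_allowed = FALSE, seed = 41)
  fx <- generate_fixture_dataset(4, sp, dir)
  expect_identical(length(fx$images), 4L)
  expect_true(all(file.exists(fx$images)))
  recs <- read_annotation_csv(fx$csv)
  expect_identical(nrow(recs),
                   sum(vapply(fx$ground_truths, function(g) nrow(g$boxes), integer(1))))
  expect_true(all(recs$class == "organoid"))
  # every box round-trips exactly
  for (i in seq_along(fx$images)) {
    sub <- recs[recs$filename == basename(fx$images[i]), ]
    gt <- fx$ground_truths[[i]]$boxes
    expect_equal(as.numeric(sub$xmin), gt$xmin)
    expect_equal(as.numeric(sub$ymax), gt$ymax)
  }
  # written pixels are the quantized scene (8-bit exact round trip)
  sp1 <- sp; sp1$seed <- sp$seed
  s1 <- generate_scene(sp1)
  expect_identical(as.array(read_image(fx$images[1])), as.array(s1$image))
})
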
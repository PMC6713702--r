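write_lines_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("annotation rows parse into validated records", {
  path <- write_lines_csv(c("filename,width,height,class,xmin,ymin,xmax,ymax",
                            "img1.png,300,300,organoid,10,20,50,80"))
  recs <- read_annotation_csv(path)
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$filename, "img1.png")
  expect_equal(unlist(recs[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 10L, ymin = 20L, xmax = 50L, ymax = 80L))
  # header order is irrelevant
  path2 <- write_lines_csv(c("xmax,xmin,ymax,ymin,class,filename,height,width",
                             "50,10,80,20,organoid,img1.png,300,300"))
  expect_identical(read_annotation_csv(path2), recs)
})

test_that("schema and row-level violations are reported with context", {
  missing_col <- write_lines_csv(c("filename,width,height,xmin,ymin,xmax,ymax",
                                   "a.png,300,300,1,1,5,5"))
  expect_error(read_annotation_csv(missing_col), "class")
  degenerate <- write_lines_csv(c("filename,width,height,class,xmin,ymin,xmax,ymax",
                                  "a.png,300,300,organoid,10,20,50,80",
                                  "a.png,300,300,organoid,30,20,30,80"))
  expect_error(read_annotation_csv(degenerate), "row\\(s\\) 2")
  outside <- write_lines_csv(c("filename,width,height,class,xmin,ymin,xmax,ymax",
                               "a.png,300,300,organoid,250,20,350,80"))
  expect_error(read_annotation_csv(outside), "outside its patch")
  odd_size <- write_lines_csv(c("filename,width,height,class,xmin,ymin,xmax,ymax",
                                "a.png,512,512,organoid,10,20,50,80"))
  expect_warning(read_annotation_csv(odd_size, expect_published_sizes = TRUE),
                 "patch sizes")
})

test_that("the upstream corner+size dialect converts to corners on read", {
  path <- write_lines_csv(c("filename,class,x_min,y_min,width,height",
                            "a.png,organoid,10,20,40,60"))
  recs <- read_annotation_csv(path, dialect = "corner_size")
  expect_equal(unlist(recs[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 10L, ymin = 20L, xmax = 50L, ymax = 80L))
  expect_true(is.na(recs$width[1]))
})

test_that("write -> read is the identity on random record sets", {
  set.seed(19)
  b <- random_boxes(100, limit = 300, max_side = 60)
  recs <- data.frame(filename = sprintf("p%02d.png", sample(1:20, 100, replace = TRUE)),
                     width = 300L, height = 300L, class = "organoid", b)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(recs, path)
  back <- read_annotation_csv(path)
  expect_equal(back$xmin, recs$xmin)
  expect_identical(back$filename, recs$filename)   # order preserved
  write_annotation_csv(back, path)
  expect_identical(read_annotation_csv(path), back)
  # empty records -> header-only file
  write_annotation_csv(NULL, path)
  expect_identical(length(readLines(path)), 1L)
})

test_that("patchification counts follow floor division and crops are exact", {
  set.seed(20)
  img <- matrix(runif(1500 * 1125), 1500, 1125)
  p300 <- patchify_for_annotation(img, 300, stem = "im")
  expect_identical(length(p300), 15L)      # 5 x 3
  p450 <- patchify_for_annotation(img, 450)
  expect_identical(length(p450), 6L)       # 3 x 2
  expect_warning(p0 <- patchify_for_annotation(matrix(0, 299, 299), 300), "skipped")
  expect_identical(length(p0), 0L)
  # a patch is bit-identical to the source crop it came from
  pk <- p300[[7]]
  crop <- img[pk$col * 300 + 1:300, pk$row * 300 + 1:300]
  expect_identical(pk$patch[, , drop = TRUE], crop)
  expect_match(pk$filename, "^im_s300_r[0-4]_c[0-4]\\.png$")
})

test_that("train/test splitting partitions filenames, never boxes", {
  set.seed(21)
  recs <- data.frame(filename = rep(sprintf("p%02d.png", 1:10), each = 4),
                     width = 300L, height = 300L, class = "organoid",
                     random_boxes(40, limit = 300, max_side = 50))
  sp <- train_test_split(recs, test_fraction = 0.1, seed = 3)
  expect_identical(length(unique(sp$test$filename)), 1L)
  expect_identical(length(unique(sp$train$filename)), 9L)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(recs))
  expect_length(intersect(sp$train$filename, sp$test$filename), 0)
  # all 4 boxes of the held-out file travel together
  expect_identical(nrow(sp$test), 4L)
  # seeded reproducibility
  sp2 <- train_test_split(recs, test_fraction = 0.1, seed = 3)
  expect_identical(sp$test$filename, sp2$test$filename)
  expect_error(train_test_split(recs[recs$filename == "p01.png", ], 0.1, 1),
               "2 distinct filenames")
  expect_error(train_test_split(recs, 1.5, 1))
})
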
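wa <- function(id, b) worker_annotations(id, b)
two_boxes <- boxes(c(10, 100), c(10, 100), c(60, 160), c(60, 160))

test_that("pairwise agreement is the Dice-style match fraction", {
  expect_identical(pairwise_agreement(wa("w1", two_boxes), wa("w2", two_boxes)), 1)
  disjoint_a <- boxes(c(0, 50), c(0, 0), c(10, 60), c(10, 10))
  disjoint_b <- boxes(c(100, 150), c(0, 0), c(110, 160), c(10, 10))
  expect_identical(pairwise_agreement(wa("w1", disjoint_a), wa("w2", disjoint_b)), 0)
  # 2 vs 2 boxes, exactly one matched pair -> 2*1/4
  mixed_b <- boxes(c(10, 300), c(10, 300), c(60, 360), c(60, 360))
  expect_identical(pairwise_agreement(wa("w1", two_boxes), wa("w2", mixed_b)), 0.5)
  expect_identical(pairwise_agreement(wa("w1", empty_boxes()), wa("w2", empty_boxes())), 1)
})

test_that("escalation triggers strictly below the 80% threshold", {
  expect_true(needs_escalation(0.79))
  expect_false(needs_escalation(0.80))
  expect_false(needs_escalation(1.0))
  expect_true(needs_escalation(0))
})

test_that("the 70% support rule keeps 2-of-2 and 3-of-3 but drops 1-of-2 and 2-of-3", {
  b <- boxes(10, 10, 60, 60)
  other <- boxes(200, 200, 260, 260)
  # 2 of 2
  r22 <- aggregate_consensus(list(wa("w1", b), wa("w2", b)))
  expect_identical(nrow(r22$boxes), 1L)
  expect_identical(r22$support, 1)
  # 1 of 2 -> support 0.5, dropped
  r12 <- aggregate_consensus(list(wa("w1", b), wa("w2", other)))
  expect_identical(nrow(r12$boxes), 0L)
  # 2 of 3 -> support 0.667, dropped; 3 of 3 kept
  r23 <- aggregate_consensus(list(wa("w1", b), wa("w2", b), wa("w3", other)))
  expect_identical(nrow(r23$boxes), 0L)
  expect_true(r23$escalated)
  r33 <- aggregate_consensus(list(wa("w1", b), wa("w2", b), wa("w3", b)))
  expect_identical(nrow(r33$boxes), 1L)
  expect_identical(r33$support, 1)
  expect_error(aggregate_consensus(list(wa("w1", b))), "at least 2")
})

test_that("consensus boxes are the rounded mean of cluster members", {
  a <- boxes(10, 10, 60, 60)
  b <- boxes(12, 11, 63, 62)
  r <- aggregate_consensus(list(wa("w1", a), wa("w2", b)))
  expect_identical(unlist(r$boxes[1, ]),
                   c(xmin = 11, ymin = round(10.5), xmax = round(61.5), ymax = 61))
})

test_that("aggregation ignores worker order and is anti-monotone in support", {
  set.seed(12)
  for (i in 1:20) {
    ws <- lapply(1:3, function(k)
      wa(paste0("w", k), random_boxes(sample(0:4, 1), limit = 200, max_side = 60)))
    r1 <- aggregate_consensus(ws, support_threshold = 0.6)
    r2 <- aggregate_consensus(rev(ws), support_threshold = 0.6)
    expect_identical(r1$boxes, r2$boxes)
    expect_identical(r1$support, r2$support)
    # retained boxes never exceed the largest single worker's count
    expect_lte(nrow(r1$boxes), max(vapply(ws, function(w) nrow(w$boxes), integer(1))))
    # raising the threshold never adds boxes
    r_hi <- aggregate_consensus(ws, support_threshold = 0.9)
    expect_lte(nrow(r_hi$boxes), nrow(r1$boxes))
  }
})

test_that("worker annotation CSVs round-trip through the extended dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  ws <- list(wa("alice", two_boxes), wa("bob", boxes(10, 12, 58, 61)))
  write_worker_annotation_csv(ws, path, image_name = "patch_1.png")
  back <- read_worker_annotation_csv(path)
  expect_setequal(names(back), c("alice", "bob"))
  expect_identical(back$alice$boxes$xmin, two_boxes$xmin)
  expect_identical(nrow(back$bob$boxes), 1L)
})
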
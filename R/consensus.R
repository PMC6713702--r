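#' Multi-annotator bounding-box consensus
#'
#' These functions reproduce the crowdsourced annotation aggregation used
#' to build the organoid dataset: each image patch is boxed by two workers;
#' if their agreement (computed from box IoU) falls below 80% the patch is
#' escalated to a third worker; the final boxes are an aggregate in which a
#' box is kept only with at least 70% agreement among all workers.
#'
#' @name consensus
NULL

#' Construct one worker's annotation set
#'
#' @param worker_id Opaque worker identifier.
#' @param b Box data frame (may be empty).
#' @return A list of class `worker_annotations`.
#' @export
worker_annotations <- function(worker_id, b) {
  validate_boxes(b)
  structure(list(worker_id = as.character(worker_id), boxes = b),
            class = "worker_annotations")
}

#' Agreement between two workers' box sets
#'
#' Boxes are greedy-matched at `match_iou`; agreement is the Dice-style
#' ratio `2 * |matches| / (|a| + |b|)`: 1 when the sets correspond
#' box-for-box, 0 when nothing matches. Two empty sets agree perfectly
#' (1.0).
#'
#' @param a,b [worker_annotations()] objects.
#' @param match_iou IoU at or above which two boxes count as the same
#'   annotation; defaults to 0.7, the same match rule the evaluation
#'   metric uses.
#' @return Agreement ratio in `[0, 1]`.
#' @export
pairwise_agreement <- function(a, b, match_iou = 0.7) {
  stopifnot(inherits(a, "worker_annotations"), inherits(b, "worker_annotations"))
  na <- nrow(a$boxes); nb <- nrow(b$boxes)
  if (na + nb == 0) return(1.0)
  m <- greedy_match_boxes(a$boxes, b$boxes, match_iou)
  2 * nrow(m$pairs) / (na + nb)
}

#' Should an image be escalated to another annotator?
#'
#' Escalation is triggered strictly below the threshold ("less than 80%
#' agreement"): agreement of exactly 0.8 does not escalate.
#'
#' @param agreement Agreement ratio in `[0, 1]`.
#' @param escalation_threshold Default 0.8.
#' @return `TRUE` if another worker is needed.
#' @export
needs_escalation <- function(agreement, escalation_threshold = 0.8) {
  stopifnot(agreement >= 0, agreement <= 1)
  agreement < escalation_threshold
}

#' Aggregate worker annotations into consensus boxes
#'
#' Boxes are clustered across workers by greedy matching: all cross-worker
#' box pairs with IoU at or above `match_iou` are visited in descending IoU
#' order (ties broken by worker id, then box index, with workers first
#' sorted by id so the result does not depend on input order) and their
#' clusters are merged whenever no worker would end up contributing two
#' boxes to one cluster. Each cluster's support is the fraction of workers
#' contributing to it; clusters with support at or above
#' `support_threshold` are retained and reported as the coordinate-wise
#' mean of their member boxes, rounded to the nearest integer.
#'
#' Note the consequential reading of the 70% rule with three workers: a box
#' drawn by 2 of 3 workers has support 0.667 < 0.7 and is dropped.
#'
#' @param workers List of at least two [worker_annotations()].
#' @param support_threshold Minimum fraction of workers endorsing a box;
#'   default 0.7.
#' @param match_iou Box-match IoU; default 0.7.
#' @return A list of class `consensus_result` with `boxes` (integer
#'   consensus boxes), `support` (per retained box), `escalated` (`TRUE`
#'   when more than two workers were involved), and `n_workers`.
#' @export
aggregate_consensus <- function(workers, support_threshold = 0.7, match_iou = 0.7) {
  if (!is.list(workers) || length(workers) < 2 ||
      !all(vapply(workers, inherits, logical(1), "worker_annotations")))
    stop("need at least 2 worker_annotations objects")
  stopifnot(support_threshold > 0, support_threshold <= 1,
            match_iou > 0, match_iou <= 1)
  ids <- vapply(workers, `[[`, character(1), "worker_id")
  if (anyDuplicated(ids)) stop("duplicate worker_id")
  workers <- workers[order(ids)]
  ids <- ids[order(ids)]
  nw <- length(workers)
  pool <- do.call(rbind, lapply(seq_len(nw), function(k) {
    b <- workers[[k]]$boxes
    if (nrow(b) == 0) return(NULL)
    data.frame(b[c("xmin", "ymin", "xmax", "ymax")], worker = k,
               idx = seq_len(nrow(b)))
  }))
  if (is.null(pool) || nrow(pool) == 0)
    return(structure(list(boxes = empty_boxes(), support = numeric(0),
                          escalated = nw > 2, n_workers = nw),
                     class = "consensus_result"))
  cluster <- seq_len(nrow(pool))            # singleton clusters
  iom <- iou_matrix(pool, pool)
  cand <- which(upper.tri(iom) & iom >= match_iou, arr.ind = TRUE)
  if (nrow(cand) > 0) {
    cross <- pool$worker[cand[, 1]] != pool$worker[cand[, 2]]
    cand <- cand[cross, , drop = FALSE]
  }
  if (nrow(cand) > 0) {
    ious <- iom[cand]
    ord <- order(-ious, pool$worker[cand[, 1]], pool$idx[cand[, 1]],
                 pool$worker[cand[, 2]], pool$idx[cand[, 2]])
    for (k in ord) {
      ci <- cluster[cand[k, 1]]; cj <- cluster[cand[k, 2]]
      if (ci == cj) next
      members_i <- pool$worker[cluster == ci]
      members_j <- pool$worker[cluster == cj]
      if (length(intersect(members_i, members_j)) > 0) next
      cluster[cluster == cj] <- ci
    }
  }
  out_boxes <- empty_boxes(); support <- numeric(0)
  for (cid in sort(unique(cluster))) {
    rows <- pool[cluster == cid, , drop = FALSE]
    s <- length(unique(rows$worker)) / nw
    if (s < support_threshold) next
    out_boxes <- rbind(out_boxes,
                       data.frame(xmin = round(mean(rows$xmin)),
                                  ymin = round(mean(rows$ymin)),
                                  xmax = round(mean(rows$xmax)),
                                  ymax = round(mean(rows$ymax))))
    support <- c(support, s)
  }
  if (nrow(out_boxes) > 1) {
    ord <- order(out_boxes$xmin, out_boxes$ymin, out_boxes$xmax, out_boxes$ymax)
    out_boxes <- out_boxes[ord, , drop = FALSE]
    support <- support[ord]
    rownames(out_boxes) <- NULL
  }
  structure(list(boxes = out_boxes, support = support,
                 escalated = nw > 2, n_workers = nw),
            class = "consensus_result")
}

#' Read or write per-worker annotations
#'
#' The worker CSV dialect is the [annotation-csv] schema extended with a
#' `worker_id` column.
#'
#' @param path CSV path.
#' @return For the reader, a named list of [worker_annotations()] (one per
#'   worker id, for a single-patch file).
#' @export
read_worker_annotation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"worker_id" %in% names(df))
    stop("worker annotation CSV needs a worker_id column")
  lapply(split(df, df$worker_id), function(d)
    worker_annotations(d$worker_id[1], boxes(d$xmin, d$ymin, d$xmax, d$ymax)))
}

#' @rdname read_worker_annotation_csv
#' @param workers List of [worker_annotations()].
#' @param image_name,width,height Patch identity written into each row.
#' @export
write_worker_annotation_csv <- function(workers, path, image_name = "patch",
                                        width = 450, height = 450) {
  rows <- do.call(rbind, lapply(workers, function(wk) {
    if (nrow(wk$boxes) == 0) return(NULL)
    data.frame(filename = image_name, width = width, height = height,
               class = "organoid", wk$boxes, worker_id = wk$worker_id)
  }))
  if (is.null(rows))
    rows <- data.frame(annotation_schema_frame(), worker_id = character(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
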
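#' @title Detection evaluation: precision, recall, AP, mAP, confusion matrix
#' @description
#' Standard single-/multi-class detection evaluation. Detections and ground
#' truths are given per image as data.frames of center-format pixel boxes
#' (`cx, cy, w, h`, plus `score` and `class_id` for detections, `class_id`
#' for ground truths). Matching is greedy within an image: detections are
#' visited in descending score order, each may claim at most one still
#' unmatched ground truth of its class with IoU at or above the threshold.
#' AP uses the 101-point interpolation convention; mAP\@0.5:0.95 averages
#' AP over IoU thresholds 0.50, 0.55, ..., 0.95.
#' @name evalmetrics
NULL

#' Match detections to ground truths
#'
#' @param dets list (one element per image) of detection data.frames
#'   (`cx, cy, w, h, score, class_id`).
#' @param gts list (same length) of ground-truth data.frames
#'   (`cx, cy, w, h, class_id`).
#' @param iou_thr IoU threshold for a match.
#' @return an object of class `pr_data`: score-sorted detection records
#'   with a TP flag per class, plus per-class ground-truth counts.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  stopifnot(length(dets) == length(gts))
  recs <- list()
  gt_count <- integer()
  for (img in seq_along(dets)) {
    g <- gts[[img]]
    d <- dets[[img]]
    if (nrow(g) > 0L) {
      tab <- table(factor(g$class_id))
      for (cl in names(tab)) {
        gt_count[cl] <- (if (cl %in% names(gt_count)) gt_count[cl] else 0L) +
          as.integer(tab[cl])
      }
    }
    if (nrow(d) == 0L) next
    d <- d[order(-d$score), , drop = FALSE]
    used <- rep(FALSE, nrow(g))
    tp <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      cand <- which(!used & g$class_id == d$class_id[i])
      if (length(cand) > 0L) {
        ious <- vapply(cand, function(j)
          iou_xywh(c(d$cx[i], d$cy[i], d$w[i], d$h[i]),
                   c(g$cx[j], g$cy[j], g$w[j], g$h[j])), numeric(1L))
        best <- which.max(ious)
        if (ious[best] >= iou_thr) {
          tp[i] <- TRUE
          used[cand[best]] <- TRUE
        }
      }
    }
    recs[[length(recs) + 1L]] <- data.frame(
      class_id = d$class_id, score = d$score, tp = tp)
  }
  records <- if (length(recs)) do.call(rbind, recs)
  else data.frame(class_id = integer(), score = numeric(), tp = logical())
  records <- records[order(-records$score), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, gt_count = gt_count,
                 iou_thr = iou_thr), class = "pr_data")
}

# precision/recall curve for one class
.pr_curve <- function(records, n_gt) {
  if (nrow(records) == 0L)
    return(data.frame(recall = numeric(), precision = numeric()))
  tp_cum <- cumsum(records$tp)
  fp_cum <- cumsum(!records$tp)
  data.frame(recall = tp_cum / n_gt,
             precision = tp_cum / (tp_cum + fp_cum))
}

#' Average precision for one class
#'
#' @param pr a `pr_data` from [match_detections()].
#' @param class_id which class (default: the only class present).
#' @param method `"101"` (default, 101-point interpolation) or
#'   `"all"` (all-point / exact area under the interpolated PR curve).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(pr, class_id = NULL, method = c("101", "all")) {
  method <- match.arg(method)
  stopifnot(inherits(pr, "pr_data"))
  if (is.null(class_id)) {
    cls <- names(pr$gt_count)
    if (length(cls) != 1L)
      stop("class_id required when several classes are present")
    class_id <- as.integer(cls)
  }
  n_gt <- pr$gt_count[as.character(class_id)]
  if (is.na(n_gt) || n_gt == 0L) {
    warning("no ground truths for class ", class_id, "; AP undefined")
    return(NA_real_)
  }
  rec <- pr$records[pr$records$class_id == class_id, , drop = FALSE]
  curve <- .pr_curve(rec, n_gt)
  if (nrow(curve) == 0L) return(0)
  # interpolated precision: max precision at any recall >= r
  p_at <- function(r) {
    ok <- curve$recall >= r - 1e-12
    if (!any(ok)) 0 else max(curve$precision[ok])
  }
  if (method == "101") {
    mean(vapply(seq(0, 1, by = 0.01), p_at, numeric(1L)))
  } else {
    rs <- sort(unique(c(0, curve$recall)))
    sum(diff(rs) * vapply(rs[-1L], p_at, numeric(1L)))
  }
}

#' Detection metrics: mAP\@0.5, mAP\@0.5:0.95, precision, recall
#'
#' mAP averages per-class AP over classes that have ground truths (classes
#' without any are excluded with a warning). Precision and recall are
#' reported at the confidence that maximizes F1 on the IoU-0.5 matching.
#'
#' @inheritParams match_detections
#' @return list with `map50`, `map5095`, `precision`, `recall`,
#'   `f1_conf` (the operating confidence).
#' @export
map_metrics <- function(dets, gts) {
  n_gt_total <- sum(vapply(gts, nrow, integer(1L)))
  if (n_gt_total == 0L) stop("no ground truths in the evaluation set")
  thr <- seq(0.5, 0.95, by = 0.05)
  aps <- matrix(NA_real_, length(thr), 0L)
  classes <- sort(unique(unlist(lapply(gts, function(g) g$class_id))))
  aps <- matrix(NA_real_, length(thr), length(classes),
                dimnames = list(NULL, as.character(classes)))
  pr50 <- NULL
  for (ti in seq_along(thr)) {
    pr <- match_detections(dets, gts, iou_thr = thr[ti])
    if (thr[ti] == 0.5) pr50 <- pr
    for (cl in classes)
      aps[ti, as.character(cl)] <-
        suppressWarnings(average_precision(pr, cl))
  }
  map_at <- function(ti) mean(aps[ti, ], na.rm = TRUE)
  # max-F1 operating point on the IoU-0.5 matching, all classes pooled
  rec <- pr50$records
  best <- list(f1 = -1, p = 0, r = 0, conf = NA_real_)
  if (nrow(rec) > 0L) {
    tp_cum <- cumsum(rec$tp); fp_cum <- cumsum(!rec$tp)
    p <- tp_cum / (tp_cum + fp_cum)
    r <- tp_cum / n_gt_total
    f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
    i <- which.max(f1)
    best <- list(f1 = f1[i], p = p[i], r = r[i], conf = rec$score[i])
  }
  list(map50 = map_at(1L),
       map5095 = mean(vapply(seq_along(thr), map_at, numeric(1L))),
       precision = best$p, recall = best$r, f1_conf = best$conf)
}

#' Detection confusion matrix
#'
#' Rows are predicted classes plus a background row (unmatched ground
#' truths, i.e. misses); columns are true classes plus a background column
#' (unmatched detections, i.e. false positives). Matching is greedy by
#' score at `iou_thr`, class-agnostic (class confusions land off-diagonal).
#'
#' @inheritParams match_detections
#' @param conf_thr detections below this confidence are ignored.
#' @param num_classes number of classes (default: inferred).
#' @return `(num_classes + 1) x (num_classes + 1)` integer matrix.
#' @export
confusion_matrix <- function(dets, gts, conf_thr = 0.25, iou_thr = 0.45,
                             num_classes = NULL) {
  stopifnot(length(dets) == length(gts))
  if (is.null(num_classes)) {
    ids <- c(unlist(lapply(gts, function(g) g$class_id)),
             unlist(lapply(dets, function(d) d$class_id)))
    num_classes <- if (length(ids)) max(ids) + 1L else 1L
  }
  labs <- c(paste0("class", 0:(num_classes - 1L)), "background")
  cm <- matrix(0L, num_classes + 1L, num_classes + 1L,
               dimnames = list(predicted = labs, truth = labs))
  for (img in seq_along(dets)) {
    d <- dets[[img]]
    d <- d[d$score >= conf_thr, , drop = FALSE]
    d <- d[order(-d$score), , drop = FALSE]
    g <- gts[[img]]
    used <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(d))) {
      cand <- which(!used)
      matched <- FALSE
      if (length(cand) > 0L) {
        ious <- vapply(cand, function(j)
          iou_xywh(c(d$cx[i], d$cy[i], d$w[i], d$h[i]),
                   c(g$cx[j], g$cy[j], g$w[j], g$h[j])), numeric(1L))
        best <- which.max(ious)
        if (ious[best] >= iou_thr) {
          cm[d$class_id[i] + 1L, g$class_id[cand[best]] + 1L] <-
            cm[d$class_id[i] + 1L, g$class_id[cand[best]] + 1L] + 1L
          used[cand[best]] <- TRUE
          matched <- TRUE
        }
      }
      if (!matched)
        cm[d$class_id[i] + 1L, num_classes + 1L] <-
          cm[d$class_id[i] + 1L, num_classes + 1L] + 1L
    }
    for (j in which(!used))
      cm[num_classes + 1L, g$class_id[j] + 1L] <-
        cm[num_classes + 1L, g$class_id[j] + 1L] + 1L
  }
  cm
}
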
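# Evaluation: greedy matching, AP conventions, mAP threshold sweep,
# confusion matrix, and complexity counting on runnable models.

gt_df <- function(cx, cy, w, h, cls = 0L)
  data.frame(cx = cx, cy = cy, w = w, h = h, class_id = cls)
det_df <- function(cx, cy, w, h, score, cls = 0L)
  data.frame(cx = cx, cy = cy, w = w, h = h, score = score, class_id = cls)

test_that("matching is greedy, single-claim, and class-aware", {
  gts <- list(gt_df(c(20, 60), c(20, 60), 10, 10))
  perfect <- list(det_df(c(20, 60), c(20, 60), 10, 10, c(0.9, 0.8)))
  pr <- match_detections(perfect, gts, 0.5)
  expect_true(all(pr$records$tp))
  expect_identical(unname(pr$gt_count["0"]), 2L)
  # duplicate detection of one gt: 1 TP + 1 FP
  dup <- list(det_df(c(20, 20), c(20, 20), 10, 10, c(0.9, 0.8)))
  pr2 <- match_detections(dup, list(gt_df(20, 20, 10, 10)), 0.5)
  expect_identical(sum(pr2$records$tp), 1L)
  expect_identical(sum(!pr2$records$tp), 1L)
  # class mismatch never matches
  wrong <- list(det_df(20, 20, 10, 10, 0.9, cls = 1L))
  pr3 <- match_detections(wrong, list(gt_df(20, 20, 10, 10, cls = 0L)), 0.5)
  expect_false(any(pr3$records$tp))
})

test_that("randomized matching agrees with an independent greedy oracle", {
  set.seed(50)
  for (rep in 1:8) {
    gts <- list(rand_boxes_df(6)[, c("cx", "cy", "w", "h", "class_id")])
    dets <- list(rand_boxes_df(10))
    pr <- match_detections(dets, gts, 0.5)
    # oracle: same protocol, written independently
    d <- dets[[1]][order(-dets[[1]]$score), ]
    g <- gts[[1]]
    used <- rep(FALSE, nrow(g))
    tp_ref <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      best_iou <- 0; best_j <- 0
      for (j in seq_len(nrow(g))) {
        if (used[j] || g$class_id[j] != d$class_id[i]) next
        v <- iou_xywh(unlist(d[i, 1:4]), unlist(g[j, 1:4]))
        if (v > best_iou) { best_iou <- v; best_j <- j }
      }
      if (best_j > 0 && best_iou >= 0.5) { tp_ref[i] <- TRUE; used[best_j] <- TRUE }
    }
    expect_identical(pr$records$tp, tp_ref)
  }
})

test_that("average precision reproduces the hand PR integration", {
  # all detections TP covering all gts
  gts <- list(gt_df(c(10, 30, 50), c(10, 30, 50), 8, 8))
  dets <- list(det_df(c(10, 30, 50), c(10, 30, 50), 8, 8, c(0.9, 0.8, 0.7)))
  pr <- match_detections(dets, gts, 0.5)
  expect_equal(average_precision(pr), 1)
  expect_equal(average_precision(pr, method = "all"), 1)
  # no TPs
  none <- list(det_df(100, 100, 8, 8, 0.9))
  pr0 <- match_detections(none, gts, 0.5)
  expect_equal(average_precision(pr0), 0)
  # 2 gts, detections (TP 0.9, FP 0.8, TP 0.7): all-point AP = 5/6
  gts2 <- list(gt_df(c(10, 40), c(10, 40), 8, 8))
  dets2 <- list(det_df(c(10, 100, 40), c(10, 100, 40), 8, 8,
                       c(0.9, 0.8, 0.7)))
  pr2 <- match_detections(dets2, gts2, 0.5)
  expect_equal(average_precision(pr2, method = "all"), 5 / 6)
  expect_equal(average_precision(pr2, method = "all"),
               naive_ap_allpoint(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2))
  # the 101-point value approximates it closely
  expect_lt(abs(average_precision(pr2) - 5 / 6), 0.01)
  expect_warning(average_precision(match_detections(dets2,
                                                    list(gt_df(10, 10, 8, 8, cls = 3L)), 0.5),
                                   class_id = 0L), "no ground truths")
})

test_that("101-point and all-point AP stay within the documented bound", {
  set.seed(51)
  for (rep in 1:10) {
    n_gt <- sample(5:15, 1)
    gts <- list(gt_df(runif(n_gt, 10, 190), runif(n_gt, 10, 190), 8, 8))
    k <- sample(5:20, 1)
    pick <- sample(n_gt, min(k, n_gt), replace = TRUE)
    dets <- list(det_df(gts[[1]]$cx[pick] + runif(length(pick), -3, 3),
                        gts[[1]]$cy[pick] + runif(length(pick), -3, 3),
                        8, 8, runif(length(pick))))
    pr <- match_detections(dets, gts, 0.5)
    expect_lte(abs(average_precision(pr) - average_precision(pr, method = "all")),
               0.01)
  }
})

test_that("the threshold sweep behaves: perfect, marginal-IoU, and ordering", {
  gts <- list(gt_df(c(20, 60), c(20, 60), 10, 10))
  perfect <- list(det_df(c(20, 60), c(20, 60), 10, 10, c(0.9, 0.8)))
  mm <- map_metrics(perfect, gts)
  expect_equal(mm$map50, 1); expect_equal(mm$map5095, 1)
  expect_equal(mm$precision, 1); expect_equal(mm$recall, 1)
  # detections at IoU ~ 0.53 with the gts: AP@0.5 = 1, higher thresholds 0
  # (x-shift d: IoU = (10 - d)*10 / (100 + 10 d); d = 3.1 -> IoU ~ 0.527)
  shifted <- list(det_df(c(20, 60) + 3.1, c(20, 60), 10, 10, c(0.9, 0.8)))
  mm2 <- map_metrics(shifted, gts)
  expect_equal(mm2$map50, 1)
  expect_equal(mm2$map5095, 0.1, tolerance = 1e-9)
  # monotone: map5095 never exceeds map50
  set.seed(52)
  for (rep in 1:5) {
    g <- list(rand_boxes_df(8)[, c("cx", "cy", "w", "h", "class_id")])
    d <- list(rand_boxes_df(12))
    mr <- map_metrics(d, g)
    expect_lte(mr$map5095, mr$map50 + 1e-12)
  }
  empty_gt <- data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                         h = numeric(), class_id = integer())
  expect_error(map_metrics(list(det_df(1, 1, 1, 1, 0.5)), list(empty_gt)),
               "no ground truths")
})

test_that("AP depends on score ranks only", {
  set.seed(53)
  gts <- list(gt_df(runif(6, 20, 180), runif(6, 20, 180), 12, 12))
  dets <- list(det_df(gts[[1]]$cx + runif(6, -2, 2), gts[[1]]$cy, 12, 12,
                      runif(6, 0.2, 0.9)))
  dets[[1]] <- rbind(dets[[1]], det_df(c(5, 195), c(5, 195), 10, 10,
                                       c(0.15, 0.5)))
  ap1 <- average_precision(match_detections(dets, gts, 0.5))
  rescaled <- lapply(dets, function(d) { d$score <- d$score * 0.37; d })
  ap2 <- average_precision(match_detections(rescaled, gts, 0.5))
  expect_equal(ap1, ap2)
})

test_that("confusion matrix tallies TP, confusions, FP and FN as documented", {
  # perfect single-class detections: diagonal
  gts <- list(gt_df(c(20, 60), c(20, 60), 10, 10))
  perfect <- list(det_df(c(20, 60), c(20, 60), 10, 10, c(0.9, 0.8)))
  cm <- confusion_matrix(perfect, gts, conf_thr = 0.25, num_classes = 1L)
  expect_equal(unname(cm), rbind(c(2, 0), c(0, 0)))
  # no detections: everything in the background (miss) row
  cm0 <- confusion_matrix(list(perfect[[1]][0, ]), gts, num_classes = 1L)
  expect_equal(unname(cm0), rbind(c(0, 0), c(2, 0)))
  # mixed two-class toy case against a hand tally:
  # gt: class0 at (20,20), class1 at (60,60)
  # det: class0 at (20,20) TP; class1 at (20,20)? -- overlaps nothing free;
  # class1 at (60,60) after class-agnostic match -> confusion if classes differ
  gts2 <- list(data.frame(cx = c(20, 60), cy = c(20, 60), w = 10, h = 10,
                          class_id = c(0L, 1L)))
  dets2 <- list(data.frame(cx = c(20, 60, 120), cy = c(20, 60, 120),
                           w = 10, h = 10, score = c(0.9, 0.8, 0.7),
                           class_id = c(0L, 0L, 1L)))
  cm2 <- confusion_matrix(dets2, gts2, conf_thr = 0.25, num_classes = 2L)
  # hand tally: det1 class0 matches gt class0 (TP); det2 class0 matches gt
  # class1 (confusion); det3 class1 matches nothing (FP); no gt unmatched
  expect_equal(unname(cm2), rbind(c(1, 1, 0), c(0, 0, 1), c(0, 0, 0)))
})

test_that("parameter and FLOP counting follow the documented conventions", {
  # single 3->8 conv, k = 3, with bias: 3*8*9 + 8 = 224
  lone <- feedtray:::nn_conv(3, 8, 3, bias = TRUE)
  expect_identical(as.integer(feedtray:::.n_params_layers(list(lone))), 224L)
  # its FLOPs on a 4x4 input (padding 1): 2 * 8*3*9*16 = 6912
  fake <- structure(list(layers = list(lone), cfg = list(input_size = 4L)),
                    class = "feed_detector")
  expect_equal(count_flops(fake, 4) * 1e9, 2 * 8 * 3 * 9 * 16)
  # doubling the input quadruples conv FLOPs
  expect_equal(count_flops(fake, 8), 4 * count_flops(fake, 4))
  # measured ghost-block MACs equal the theoretical cost (normalization
  # excluded per the documented convention)
  cfg <- ghost_config(16, 32, ratio = 2, primary_kernel = 1, cheap_kernel = 3)
  gb <- ghost_block(cfg)
  gm <- structure(list(layers = list(gb), cfg = list(input_size = 8L)),
                  class = "feed_detector")
  bn_elts <- 16 * 64 + 16 * 64 + 16 * 64  # primary BN, cheap BN, id BN
  macs <- (count_flops(gm, 8) * 1e9 - 2 * bn_elts) / 2
  expect_equal(macs, theoretical_cost(cfg, 8, 8)$ghost_macs)
  # fused block never has more parameters than the training form
  p_train <- count_params(gb)
  invisible(ghost_forward(gb, array(rnorm(16 * 64), c(1, 16, 8, 8)),
                          train = TRUE))
  fuse_ghost(gb)
  expect_lte(count_params(gb), p_train)
})
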
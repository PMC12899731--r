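# Compact detector: parameter accounting, loss composition, gradient flow,
# NMS, prediction contracts, fuse propagation, and training reproducibility.

test_that("attention adds zero parameters; ghost blocks reduce them", {
  base <- build_detector(detector_config(use_repghost = FALSE,
                                         use_ensimam = FALSE), seed = 1)
  attn <- build_detector(detector_config(use_repghost = FALSE,
                                         use_ensimam = TRUE), seed = 1)
  ghst <- build_detector(detector_config(use_repghost = TRUE,
                                         use_ensimam = FALSE), seed = 1)
  expect_identical(count_params(attn), count_params(base))
  expect_lt(count_params(ghst), count_params(base))
  # same ordering at a different width
  base16 <- build_detector(detector_config(base_channels = 16L,
                                           use_repghost = FALSE), seed = 1)
  ghst16 <- build_detector(detector_config(base_channels = 16L,
                                           use_repghost = TRUE), seed = 1)
  expect_lt(count_params(ghst16), count_params(base16))
})

test_that("toy model parameter count equals an independent hand summation", {
  m <- build_detector(detector_config(base_channels = 8L, num_classes = 1L,
                                      use_repghost = FALSE,
                                      use_ensimam = FALSE), seed = 1)
  conv_p <- function(cin, cout, k) cin * cout * k^2 + 2 * cout  # conv + BN
  # stem 3->8, down 8->16, block (16->8->16), down 16->32, block
  # (32->16->32), head conv 32->32, head 1x1 conv 32->6 with bias
  expected <- conv_p(3, 8, 3) + conv_p(8, 16, 3) +
    conv_p(16, 8, 3) + conv_p(8, 16, 3) +
    conv_p(16, 32, 3) +
    conv_p(32, 16, 3) + conv_p(16, 32, 3) +
    conv_p(32, 32, 3) + (32 * 6 + 6)
  expect_identical(count_params(m), as.integer(expected))
})

test_that("a YAML model config round-trips into detector_config", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("input_size: 192", "base_channels: 16",
               "use_repghost: false", "loss_weights: [1.0, 0.25, 5.0]"), f)
  cfg <- detector_config_from_yaml(f)
  expect_identical(cfg$input_size, 192L)
  expect_identical(cfg$base_channels, 16L)
  expect_false(cfg$use_repghost)
  expect_equal(cfg$loss_weights, c(1, 0.25, 5))
  expect_identical(cfg$num_classes, 1L)  # defaults retained
  writeLines("bogus_key: 3", f)
  expect_error(detector_config_from_yaml(f), "unknown")
  unlink(f)
})

test_that("loss weights mask and recompose the total exactly", {
  set.seed(40)
  samples <- easy_samples(8)
  m1 <- build_detector(detector_config(input_size = 160L,
                                       loss_weights = c(1, 0, 0)), seed = 2)
  l1 <- compute_losses(m1, samples)
  expect_equal(l1$total, l1$obj)
  m2 <- build_detector(detector_config(input_size = 160L,
                                       loss_weights = c(1, 0.5, 7.5)), seed = 2)
  l2 <- compute_losses(m2, samples)
  expect_equal(l2$total, 1 * l2$obj + 0.5 * l2$cls + 7.5 * l2$loc)
  expect_true(all(is.finite(unlist(l2))))
})

test_that("every learnable parameter receives a finite gradient", {
  set.seed(41)
  m <- build_detector(detector_config(input_size = 160L), seed = 3)
  samples <- easy_samples(4)
  b <- feedtray:::.make_batch(m, samples)
  feedtray:::.zero_grads(m$layers)
  head <- feedtray:::.forward_model(m, b$x, train = TRUE)
  lg <- feedtray:::.loss_and_grad(head, b$labels, m$cfg, m$stride, b$h, b$w)
  feedtray:::.backward_model(m, lg$grad)
  n_with_grad <- 0L
  for (e in feedtray:::.flatten_layers(m$layers)) {
    for (nm in e$param_names) {
      g <- e[[paste0("d", nm)]]
      expect_false(is.null(g), label = paste("gradient missing for", e$type, nm))
      expect_true(all(is.finite(g)))
      n_with_grad <- n_with_grad + length(g)
    }
  }
  expect_identical(n_with_grad, count_params(m))
})

test_that("greedy NMS matches trivial cases and the brute-force oracle", {
  two <- data.frame(cx = c(10, 10), cy = c(10, 10), w = c(6, 6), h = c(6, 6),
                    score = c(0.9, 0.8), class_id = c(0L, 0L))
  out <- nms(two, 0.45)
  expect_identical(nrow(out), 1L)
  expect_equal(out$score, 0.9)
  disjoint <- data.frame(cx = c(10, 50, 90), cy = c(10, 50, 90),
                         w = 8, h = 8, score = c(0.5, 0.9, 0.7),
                         class_id = 0L)
  expect_identical(nrow(nms(disjoint, 0.45)), 3L)
  # same box, different classes: class-aware NMS keeps both
  cross <- data.frame(cx = 10, cy = 10, w = 6, h = 6,
                      score = c(0.9, 0.8), class_id = c(0L, 1L))
  expect_identical(nrow(nms(cross, 0.45)), 2L)
  set.seed(42)
  for (rep in 1:10) {
    dets <- rand_boxes_df(10)
    expect_equal(nms(dets, 0.45), naive_nms(dets, 0.45))
  }
  expect_error(nms(data.frame(cx = 1, cy = 1, w = 1, h = 1, score = 1.2,
                              class_id = 0L), 0.45), "scores")
})

test_that("prediction returns valid boxes on any input, including odd sizes", {
  set.seed(43)
  m <- build_detector(detector_config(input_size = 160L), seed = 4)
  blank <- array(20L, c(160, 160, 3))
  dets <- predict(m, blank, conf = 0.9)
  expect_s3_class(dets, "data.frame")
  if (nrow(dets) > 0) {
    expect_true(all(dets$w > 0 & dets$h > 0))
    expect_true(all(dets$cx - dets$w / 2 >= 0 & dets$cx + dets$w / 2 <= 160))
  }
  # non-multiple-of-32 image is letterboxed, never an error
  odd <- array(sample(0:255, 150 * 170 * 3, replace = TRUE), c(150, 170, 3))
  dets2 <- predict(m, odd, conf = 0.5)
  if (nrow(dets2) > 0) {
    expect_true(all(dets2$cx + dets2$w / 2 <= 170 + 1e-9))
    expect_true(all(dets2$cy + dets2$h / 2 <= 150 + 1e-9))
  }
})

test_that("injected duplicate predictions collapse to the top of each cluster", {
  base <- data.frame(cx = c(30, 80, 120), cy = c(30, 80, 120),
                     w = 16, h = 12, score = c(0.95, 0.9, 0.85),
                     class_id = 0L)
  dup <- base
  dup$score <- dup$score - 0.2
  dup$cx <- dup$cx + 1   # near-identical duplicates
  mixed <- rbind(base, dup)[sample(6), ]
  out <- nms(mixed, 0.45)
  expect_identical(nrow(out), 3L)
  expect_equal(sort(out$score), sort(base$score))
})

test_that("fused and unfused models predict identically", {
  set.seed(44)
  m <- build_detector(detector_config(input_size = 160L), seed = 5)
  samples <- easy_samples(8)
  # a couple of training iterations so running stats and weights are
  # non-trivial
  m <- train_detector(m, samples, train_config(epochs = 2, batch_size = 4,
                                               seed = 9))
  img <- easy_samples(1)[[1]]$image
  before <- predict(m, img, conf = 0.05)
  m <- fuse_detector(m)
  after <- predict(m, img, conf = 0.05)
  expect_identical(nrow(before), nrow(after))
  if (nrow(before) > 0) {
    expect_equal(before$score, after$score, tolerance = 1e-4)
    expect_equal(before[, c("cx", "cy", "w", "h")],
                 after[, c("cx", "cy", "w", "h")], tolerance = 1e-3)
  }
})

test_that("a one-epoch run records finite history and is seed-reproducible", {
  samples <- easy_samples(8)
  m <- build_detector(detector_config(input_size = 160L), seed = 6)
  m <- train_detector(m, samples, train_config(epochs = 1, batch_size = 4,
                                               seed = 7))
  expect_identical(nrow(m$history), 1L)
  expect_true(all(is.finite(unlist(m$history[, c("obj", "cls", "loc", "total")]))))
  # identical seeds give identical trajectories
  ma <- build_detector(detector_config(input_size = 160L), seed = 8)
  ma <- train_detector(ma, samples, train_config(epochs = 2, batch_size = 4,
                                                 seed = 11))
  mb <- build_detector(detector_config(input_size = 160L), seed = 8)
  mb <- train_detector(mb, samples, train_config(epochs = 2, batch_size = 4,
                                                 seed = 11))
  expect_identical(ma$history, mb$history)
})
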
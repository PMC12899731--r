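# Synthetic scene generator: determinism, label validity, construction
# guarantees, augmentation geometry, dataset layout and statistics.

test_that("generation is a pure function of parameters and seed", {
  p <- scene_params(image_size = 256L, particle_count = c(8L, 15L))
  a <- generate_sample(p, seed = 123)
  b <- generate_sample(p, seed = 123)
  expect_identical(a, b)
  c <- generate_sample(p, seed = 124)
  expect_false(identical(a$image, c$image))
  # the caller's RNG state is untouched
  set.seed(99); r1 <- runif(1)
  set.seed(99); invisible(generate_sample(p, seed = 1)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("labels are valid boxes and match the rendered particle count", {
  p <- scene_params(image_size = 256L, particle_count = c(5L, 5L),
                    adhesion_prob = 0)
  s <- generate_sample(p, seed = 3)
  expect_identical(nrow(s$labels), 5L)
  L <- s$labels
  expect_true(all(L[, 2:5] >= 0 & L[, 2:5] <= 1))
  expect_true(all(L[, 4:5] > 0))
  expect_true(all(L[, 2] - L[, 4] / 2 >= 0 & L[, 2] + L[, 4] / 2 <= 1))
  # non-adhesive placement enforces disjoint label boxes
  for (i in seq_len(nrow(L) - 1)) for (j in (i + 1):nrow(L))
    expect_equal(iou_xywh(L[i, 2:5], L[j, 2:5]), 0)
  # a zero particle count yields a background-only sample
  p0 <- scene_params(image_size = 128L, particle_count = c(0L, 0L))
  s0 <- generate_sample(p0, seed = 1)
  expect_identical(nrow(s0$labels), 0L)
  expect_identical(dim(s0$image), c(128L, 128L, 3L))
  # pixel values are 8-bit
  expect_true(all(s$image >= 0L & s$image <= 255L))
})

test_that("horizontal flip mirrors cx and preserves box sizes", {
  s <- generate_sample(scene_params(image_size = 192L,
                                    particle_count = c(4L, 4L)), seed = 5)
  f <- augment_complete(s, flip = TRUE, rot_k = 0L, crop = c(0, 0, 1),
                        brightness = 1, contrast = 1)
  expect_equal(f$labels[, "cx"], 1 - s$labels[, "cx"])
  expect_equal(f$labels[, c("cy", "w", "h")], s$labels[, c("cy", "w", "h")])
  expect_identical(f$image[, dim(f$image)[2]:1, ], s$image)
})

test_that("a quarter rotation maps labels by (cx,cy,w,h) -> (cy, 1-cx, h, w)", {
  s <- generate_sample(scene_params(image_size = 192L,
                                    particle_count = c(5L, 5L)), seed = 6)
  r <- augment_complete(s, flip = FALSE, rot_k = 1L, crop = c(0, 0, 1),
                        brightness = 1, contrast = 1)
  expect_equal(r$labels[, "cx"], s$labels[, "cy"])
  expect_equal(r$labels[, "cy"], 1 - s$labels[, "cx"])
  expect_equal(r$labels[, "w"], s$labels[, "h"])
  expect_equal(r$labels[, "h"], s$labels[, "w"])
  # image content moves with the labels: check a marked pixel
  img <- array(0L, c(8, 8, 3)); img[2, 5, ] <- 255L   # row 2, col 5
  ms <- structure(list(image = img,
                       labels = matrix(numeric(), 0, 5,
                                       dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))),
                  class = "image_sample")
  mr <- augment_complete(ms, flip = FALSE, rot_k = 1L, crop = c(0, 0, 1),
                         brightness = 1, contrast = 1)
  # pixel at (x=5, y=2) in [0,1] coords ~ (0.5625, 0.1875) -> (0.1875, 0.4375)
  hit <- which(mr$image[, , 1] == 255L, arr.ind = TRUE)
  expect_equal(unname(hit[1, "col"]) / 8, 2 / 8, tolerance = 0.13)
  expect_equal(unname(hit[1, "row"]) / 8, 1 - 5 / 8 + 1 / 8, tolerance = 0.13)
})

test_that("identity-parameter augmentation leaves the sample unchanged", {
  s <- generate_sample(scene_params(image_size = 160L,
                                    particle_count = c(3L, 6L)), seed = 7)
  a <- augment_complete(s, flip = FALSE, rot_k = 0L, crop = c(0, 0, 1),
                        brightness = 1, contrast = 1)
  expect_identical(a$image, s$image)
  expect_equal(a$labels, s$labels)
})

test_that("cropping drops boxes below the retention threshold and keeps geometry valid", {
  set.seed(8)
  p <- scene_params(image_size = 256L, particle_count = c(10L, 16L))
  for (seed in 1:6) {
    s <- generate_sample(p, seed = seed)
    a <- augment_complete(s, seed = seed)
    L <- a$labels
    if (nrow(L) > 0) {
      expect_true(all(L[, 2:5] >= -1e-9 & L[, 2:5] <= 1 + 1e-9))
      expect_true(all(L[, 4:5] > 0))
      expect_true(all(is.finite(L)))
    }
    expect_identical(dim(a$image)[3], 3L)
  }
})

test_that("local copy-paste augmentation appends labels without overlap", {
  p <- scene_params(image_size = 192L, particle_count = c(6L, 8L))
  donors <- lapply(1:3, function(i) generate_sample(p, seed = 20 + i))
  s <- generate_sample(p, seed = 30)
  # zero pastes is the identity
  a0 <- augment_local(s, donors, n_paste = 0L)
  expect_identical(a0$image, s$image)
  expect_equal(nrow(a0$labels), nrow(s$labels))
  # pasting onto an empty background appends exactly n labels
  bg <- generate_sample(scene_params(image_size = 192L,
                                     particle_count = c(0L, 0L)), seed = 31)
  a3 <- augment_local(bg, donors, seed = 1, n_paste = 3L)
  expect_identical(nrow(a3$labels), 3L)
  # label count is monotone and pasted boxes stay clear of existing ones
  a <- augment_local(s, donors, seed = 2, n_paste = 4L)
  expect_gte(nrow(a$labels), nrow(s$labels))
  newL <- a$labels[seq(nrow(s$labels) + 1, nrow(a$labels)), , drop = FALSE]
  oldL <- s$labels
  sz <- 192
  for (i in seq_len(nrow(newL))) for (j in seq_len(nrow(oldL)))
    expect_lte(iou_xywh(newL[i, 2:5] * sz, oldL[j, 2:5] * sz), 0.1 + 1e-9)
})

test_that("dataset statistics compute the documented fractions", {
  mk <- function(labels) structure(list(image = array(0L, c(64, 64, 3)),
                                        labels = labels),
                                   class = "image_sample")
  # one 10x10 px box in a 640 px image: area well below the threshold
  s1 <- mk(matrix(c(0, 0.5, 0.5, 10 / 640, 10 / 640), 1, 5,
                  dimnames = list(NULL, c("class", "cx", "cy", "w", "h"))))
  st1 <- dataset_stats(list(s1))
  expect_equal(st1$fraction_small, 1)
  # aspects {1, 3}: half elongated
  s2 <- mk(matrix(c(0, 0.3, 0.3, 0.1, 0.1,
                    0, 0.7, 0.7, 0.3, 0.1), 2, 5, byrow = TRUE,
                  dimnames = list(NULL, c("class", "cx", "cy", "w", "h"))))
  st2 <- dataset_stats(list(s2))
  expect_equal(st2$fraction_elongated, 0.5)
  expect_identical(st2$n_targets, 2L)
  expect_equal(sum(st2$spatial_histogram), 1)
  expect_error(dataset_stats(list(mk(matrix(numeric(), 0, 5)))), "no labels")
})

test_that("the split is seeded, reproducible, and matches the documented counts", {
  sp <- split_dataset(3461, 0.9, seed = 0)
  expect_identical(length(sp$train), 3115L)
  expect_identical(length(sp$val), 346L)
  expect_identical(split_dataset(3461, 0.9, seed = 0), sp)
  expect_false(identical(split_dataset(3461, 0.9, seed = 1)$train, sp$train))
  sp10 <- split_dataset(10, 0.9, seed = 0)
  expect_identical(length(sp10$train), 9L)
  expect_identical(length(sp10$val), 1L)
  expect_identical(sort(c(sp10$train, sp10$val)), 1:10)
  expect_error(split_dataset(1, 0.9), ">= 2")
  expect_error(split_dataset(10, 1.2), "in \\(0, 1\\)")
})

test_that("dataset writing produces the YOLO layout and refuses overwrites", {
  dir <- file.path(tempdir(), "ft_ds_test")
  unlink(dir, recursive = TRUE)
  p <- scene_params(image_size = 96L, particle_count = c(2L, 4L))
  man <- generate_dataset(p, 6, 0.8, dir, seed = 1)
  expect_identical(length(man$train), 5L)
  expect_identical(length(man$val), 1L)
  expect_true(file.exists(file.path(dir, "data.yaml")))
  expect_identical(length(list.files(file.path(dir, "images", "train"))), 5L)
  expect_identical(length(list.files(file.path(dir, "labels", "train"))), 5L)
  expect_error(generate_dataset(p, 6, 0.8, dir, seed = 1), "not empty")
  # rerunning with force and the same seed reproduces identical files
  lbl_before <- readLines(list.files(file.path(dir, "labels", "train"),
                                     full.names = TRUE)[1])
  man2 <- generate_dataset(p, 6, 0.8, dir, seed = 1, force = TRUE)
  lbl_after <- readLines(list.files(file.path(dir, "labels", "train"),
                                    full.names = TRUE)[1])
  expect_identical(man2, man)
  expect_identical(lbl_after, lbl_before)
  # round trip through the reader
  back <- read_dataset(dir, "train")
  expect_identical(length(back), 5L)
  expect_true(all(vapply(back, function(s) all(dim(s$image)[1:2] == 96L),
                         logical(1))))
  unlink(dir, recursive = TRUE)
})

test_that("label files round-trip exactly at the written precision", {
  lab <- matrix(c(0, 0.5, 0.25, 0.1, 0.05,
                  0, 0.123456, 0.654321, 0.02, 0.4), 2, 5, byrow = TRUE)
  f <- tempfile(fileext = ".txt")
  write_yolo_labels(lab, f)
  back <- read_yolo_labels(f)
  expect_equal(unname(back), unname(lab), tolerance = 1e-6)
  write_yolo_labels(matrix(numeric(), 0, 5), f)
  expect_identical(nrow(read_yolo_labels(f)), 0L)
  unlink(f)
})
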
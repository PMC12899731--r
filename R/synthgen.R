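#' @title Synthetic feeding-tray scenes with YOLO labels
#' @description
#' A seeded generator of feeding-tray-like images annotated with
#' normalized YOLO labels, emulating the statistical profile of real
#' residual-feed imagery: dense small particles (about 85% below the
#' small-object area threshold), a large elongated fraction (about 40%
#' with box aspect ratio above 2), center-biased placement (trays sit in
#' the image center), mutual adhesion clusters, uneven illumination over a
#' tray-mesh background, mild turbidity blur, and unlabeled distractors
#' (air bubbles, glints, debris) plus occasional dark occluder silhouettes.
#'
#' Particles are rendered as rotated capsules whose axis-aligned extent is
#' constructed to realize a sampled label box exactly (up to pixel
#' rasterization), so the generator's size/elongation statistics are
#' controlled by construction and only jittered by sampling noise. Labels
#' are derived from the rendered mask of every particle; distractors and
#' occluders are never labeled. Generation is a pure function of
#' (parameters, seed).
#' @name synthgen
NULL

#' Scene generation parameters
#'
#' @param image_size square image size in pixels.
#' @param particle_count inclusive integer range to draw the per-image
#'   particle count from.
#' @param small_fraction_target probability that a particle's label box is
#'   below the small-object area threshold (`(32/640 * image_size)^2`).
#' @param elongated_fraction_target probability that a particle's label
#'   box has aspect ratio above 2.
#' @param aspect_compact,aspect_elongated aspect-ratio ranges for compact
#'   and elongated label boxes (the latter must stay above 2, the former
#'   below, with a rasterization margin).
#' @param center_bias_sigma standard deviation of particle centers around
#'   the image center, as a fraction of `image_size`.
#' @param adhesion_prob probability that a particle is placed adjacent to
#'   (touching) an already placed one rather than independently.
#' @param illumination_gradient relative amplitude of the linear
#'   illumination gradient (0 = flat lighting).
#' @param turbidity_blur_sigma Gaussian blur sigma in pixels (0 = sharp).
#' @param distractor_rates named Poisson means per image for `bubbles`,
#'   `glints` and `debris`.
#' @param occluder_rate Poisson mean of dark occluder silhouettes.
#' @param seed default seed used when the generating functions are not
#'   given one explicitly.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(image_size = 640L,
                         particle_count = c(18L, 45L),
                         small_fraction_target = 0.85,
                         elongated_fraction_target = 0.40,
                         aspect_compact = c(1.0, 1.9),
                         aspect_elongated = c(2.15, 5.0),
                         center_bias_sigma = 0.18,
                         adhesion_prob = 0.30,
                         illumination_gradient = 0.25,
                         turbidity_blur_sigma = 0.6,
                         distractor_rates = c(bubbles = 2, glints = 4,
                                              debris = 1.5),
                         occluder_rate = 0.25,
                         seed = 0L) {
  stopifnot(image_size >= 64L,
            small_fraction_target >= 0, small_fraction_target <= 1,
            elongated_fraction_target >= 0, elongated_fraction_target <= 1,
            length(particle_count) == 2L, particle_count[1L] >= 0L)
  structure(list(image_size = as.integer(image_size),
                 particle_count = as.integer(particle_count),
                 small_fraction_target = small_fraction_target,
                 elongated_fraction_target = elongated_fraction_target,
                 aspect_compact = aspect_compact,
                 aspect_elongated = aspect_elongated,
                 center_bias_sigma = center_bias_sigma,
                 adhesion_prob = adhesion_prob,
                 illumination_gradient = illumination_gradient,
                 turbidity_blur_sigma = turbidity_blur_sigma,
                 distractor_rates = distractor_rates,
                 occluder_rate = occluder_rate,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Relaxed parameters for easy desk-scale training scenes
#'
#' Larger, well-separated particles, no adhesion, distractors or blur:
#' the benchmark regime for the desk-scale learnability check.
#'
#' @param image_size square image size in pixels.
#' @param particle_count per-image particle count range.
#' @return a [scene_params()] object.
#' @export
scene_params_easy <- function(image_size = 160L, particle_count = c(2L, 4L)) {
  p <- scene_params(image_size = image_size,
                    particle_count = particle_count,
                    small_fraction_target = 0,
                    elongated_fraction_target = 0.4,
                    aspect_elongated = c(2.2, 3.2),
                    center_bias_sigma = 0.28,
                    adhesion_prob = 0,
                    illumination_gradient = 0.1,
                    turbidity_blur_sigma = 0,
                    distractor_rates = c(bubbles = 0, glints = 0, debris = 0),
                    occluder_rate = 0)
  p$size_rel_large <- c(2.2, 5.5)  # label area in units of the small threshold
  p
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

# tray-mesh background with illumination gradient and sensor noise;
# returns (H,W,3) in [0,1]
.render_background <- function(s) {
  xs <- matrix(rep(seq_len(s), each = s), s, s)   # column index (x)
  ys <- matrix(rep(seq_len(s), times = s), s, s)  # row index (y)
  period <- runif(1, 0.028, 0.045) * s
  phase <- runif(2, 0, 2 * pi)
  mesh <- 1 - 0.18 * (abs(sin(2 * pi * xs / period + phase[1L]))^24 +
                      abs(sin(2 * pi * ys / period + phase[2L]))^24)
  mottle <- 0.05 * sin(2 * pi * xs / (s * runif(1, 0.3, 0.6)) + runif(1, 0, 6)) *
    sin(2 * pi * ys / (s * runif(1, 0.3, 0.6)) + runif(1, 0, 6))
  base <- c(0.16, 0.21, 0.19) * runif(3, 0.85, 1.15)
  img <- array(0, c(s, s, 3L))
  for (ch in 1:3) img[, , ch] <- base[ch] * mesh + mottle * base[ch]
  img
}

.apply_illumination <- function(img, amp) {
  if (amp <= 0) return(img)
  s <- dim(img)[1L]
  ang <- runif(1, 0, 2 * pi)
  xs <- matrix(rep(seq_len(s), each = s), s, s) / s - 0.5
  ys <- matrix(rep(seq_len(s), times = s), s, s) / s - 0.5
  grad <- 1 + amp * (cos(ang) * xs + sin(ang) * ys) * 2
  for (ch in 1:3) img[, , ch] <- img[, , ch] * grad
  img
}

# paint an anti-aliased capsule (segment of half-length hl, radius rho,
# angle theta) centered at (px, py); returns the image and the tight pixel
# bbox of the painted mask (or NULL if nothing was painted)
.draw_capsule <- function(img, px, py, theta, hl, rho, col, alpha = 1,
                          shade = TRUE) {
  s <- dim(img)[1L]
  ext <- hl + rho + 1.5
  x0 <- max(1L, floor(px - ext)); x1 <- min(s, ceiling(px + ext))
  y0 <- max(1L, floor(py - ext)); y1 <- min(s, ceiling(py + ext))
  if (x0 > x1 || y0 > y1) return(list(img = img, bbox = NULL))
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(rep(xs - px, each = length(ys)), length(ys), length(xs))
  dy <- matrix(rep(ys - py, times = length(xs)), length(ys), length(xs))
  u <- pmin(pmax(dx * cos(theta) + dy * sin(theta), -hl), hl)
  dist <- sqrt((dx - u * cos(theta))^2 + (dy - u * sin(theta))^2)
  a <- pmin(pmax(rho + 0.5 - dist, 0), 1) * alpha
  if (all(a <= 0)) return(list(img = img, bbox = NULL))
  shading <- if (shade) 0.72 + 0.45 * sqrt(pmax(1 - dist / (rho + 0.5), 0))
  else matrix(1, nrow(a), ncol(a))
  for (ch in 1:3) {
    patch <- img[ys, xs, ch]
    img[ys, xs, ch] <- patch * (1 - a) + col[ch] * shading * a
  }
  solid <- which(a >= 0.5 * alpha, arr.ind = TRUE)
  bbox <- if (nrow(solid) > 0L) {
    c(x_min = xs[min(solid[, 2L])], x_max = xs[max(solid[, 2L])],
      y_min = ys[min(solid[, 1L])], y_max = ys[max(solid[, 1L])])
  }
  list(img = img, bbox = bbox)
}

# sample capsule geometry realizing a label box with the given flags:
# returns half-length, radius and angle whose axis-aligned extent is
# (target_w x target_h)
.capsule_from_box <- function(target_w, target_h, theta_max = 40 * pi / 180) {
  wb <- max(target_w, target_h); hb <- min(target_w, target_h)
  portrait <- target_h > target_w
  for (try in seq_len(25L)) {
    theta <- runif(1, 0, theta_max) * (25 - try + 1) / 25
    den <- cos(theta) - sin(theta)
    l <- if (den > 1e-6) (wb - hb) / den else 0
    rho <- (hb - l * sin(theta)) / 2
    if (l >= 0 && rho >= 0.7 && l * sin(theta) <= hb) {
      if (runif(1) < 0.5) theta <- -theta   # both tilt directions
      if (portrait) theta <- pi / 2 - theta
      return(list(hl = l / 2, rho = rho, theta = theta))
    }
  }
  # fall back to the axis-aligned solution
  theta <- if (portrait) pi / 2 else 0
  list(hl = (wb - hb) / 2, rho = hb / 2, theta = theta)
}

# sample a label box (w, h in pixels) from the size/elongation targets
.sample_box_dims <- function(p) {
  thr_area <- (32 / 640 * p$image_size)^2
  small <- runif(1) < p$small_fraction_target
  elong <- runif(1) < p$elongated_fraction_target
  rel <- if (small) exp(runif(1, log(0.10), log(0.88)))
  else {
    rng <- if (!is.null(p$size_rel_large)) p$size_rel_large else c(1.15, 3.5)
    exp(runif(1, log(rng[1L]), log(rng[2L])))
  }
  area <- rel * thr_area
  asp <- if (elong) runif(1, p$aspect_elongated[1L], p$aspect_elongated[2L])
  else runif(1, p$aspect_compact[1L], p$aspect_compact[2L])
  w <- sqrt(area * asp); h <- sqrt(area / asp)
  if (runif(1) < 0.5) c(w = h, h = w) else c(w = w, h = h)
}

.boxes_intersect <- function(b, boxes, pad = 1) {
  if (length(boxes) == 0L) return(FALSE)
  for (o in boxes) {
    if (b["x_min"] - pad <= o["x_max"] && b["x_max"] + pad >= o["x_min"] &&
        b["y_min"] - pad <= o["y_max"] && b["y_max"] + pad >= o["y_min"])
      return(TRUE)
  }
  FALSE
}

# separable Gaussian blur, replicate borders
.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  s <- dim(img)[1L]
  blur1 <- function(m) {
    # along rows (vertical), then columns (horizontal)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
                 m[rep(nrow(m), r), , drop = FALSE])
    v <- matrix(0, nrow(m), ncol(m))
    for (o in -r:r) v <- v + k[o + r + 1L] * pad[(1L + r + o):(nrow(m) + r + o), , drop = FALSE]
    pad <- cbind(v[, rep(1L, r), drop = FALSE], v,
                 v[, rep(ncol(m), r), drop = FALSE])
    h <- matrix(0, nrow(m), ncol(m))
    for (o in -r:r) h <- h + k[o + r + 1L] * pad[, (1L + r + o):(ncol(m) + r + o), drop = FALSE]
    h
  }
  for (ch in 1:3) img[, , ch] <- blur1(img[, , ch])
  img
}

.draw_occluder <- function(img, s) {
  len <- runif(1, 0.08, 0.2) * s
  geo <- list(hl = len / 2, rho = runif(1, 0.012, 0.03) * s,
              theta = runif(1, 0, pi))
  pos <- pmin(pmax(rnorm(2, s / 2, 0.22 * s), 0.1 * s), 0.9 * s)
  col <- c(0.10, 0.12, 0.14) * runif(1, 0.8, 1.2)
  .draw_capsule(img, pos[1L], pos[2L], geo$theta, geo$hl, geo$rho, col,
                alpha = 0.9)$img
}

.draw_distractors <- function(img, p) {
  s <- p$image_size
  rt <- p$distractor_rates
  for (i in seq_len(stats::rpois(1L, rt[["bubbles"]]))) {
    pos <- runif(2, 0.05 * s, 0.95 * s)
    r <- runif(1, 1.2, 3.5)
    img <- .draw_capsule(img, pos[1L], pos[2L], 0, 0, r,
                         c(0.75, 0.85, 0.9), alpha = 0.35)$img
    img <- .draw_capsule(img, pos[1L] - r / 3, pos[2L] - r / 3, 0, 0,
                         max(r / 4, 0.6), c(1, 1, 1), alpha = 0.5)$img
  }
  for (i in seq_len(stats::rpois(1L, rt[["glints"]]))) {
    pos <- runif(2, 0.02 * s, 0.98 * s)
    img <- .draw_capsule(img, pos[1L], pos[2L], runif(1, 0, pi),
                         runif(1, 0, 1.5), runif(1, 0.5, 1.1),
                         c(0.95, 0.97, 0.9), alpha = 0.8, shade = FALSE)$img
  }
  for (i in seq_len(stats::rpois(1L, rt[["debris"]]))) {
    pos <- pmin(pmax(rnorm(2, s / 2, 0.25 * s), 0.05 * s), 0.95 * s)
    img <- .draw_capsule(img, pos[1L], pos[2L], runif(1, 0, pi),
                         runif(1, 1, 4), runif(1, 1, 2.5),
                         c(0.35, 0.38, 0.3) * runif(1, 0.8, 1.2),
                         alpha = 0.85)$img
  }
  img
}

#' Generate one synthetic feeding-tray sample
#'
#' Renders the scene and returns the image together with exact normalized
#' YOLO labels for every feed particle (one row per particle:
#' `class, cx, cy, w, h`). Distractors and occluders are not labeled.
#' Bitwise deterministic for fixed `(p, seed)`; the caller's RNG state is
#' left untouched.
#'
#' @param p a [scene_params()].
#' @param seed integer seed (default `p$seed`).
#' @return an object of class `image_sample`: list with `image`
#'   (`H x W x 3` integer array, 0..255) and `labels` (numeric matrix with
#'   columns `class, cx, cy, w, h`, normalized).
#' @export
generate_sample <- function(p, seed = p$seed) {
  stopifnot(inherits(p, "scene_params"))
  .with_seed(seed, {
    s <- p$image_size
    img <- .render_background(s)
    img <- .apply_illumination(img, p$illumination_gradient)
    for (i in seq_len(stats::rpois(1L, p$occluder_rate)))
      img <- .draw_occluder(img, s)

    n <- if (p$particle_count[1L] >= p$particle_count[2L]) p$particle_count[1L]
    else sample(p$particle_count[1L]:p$particle_count[2L], 1L)
    placed <- list()   # pixel bboxes of placed particles
    labels <- list()
    margin <- 2
    for (i in seq_len(n)) {
      dims <- .sample_box_dims(p)
      ok <- FALSE
      for (try in seq_len(60L)) {
        adhere <- length(placed) > 0L && runif(1) < p$adhesion_prob
        if (adhere) {
          ref <- placed[[sample(length(placed), 1L)]]
          rc <- c((ref["x_min"] + ref["x_max"]) / 2,
                  (ref["y_min"] + ref["y_max"]) / 2)
          ang <- runif(1, 0, 2 * pi)
          d <- (ref["x_max"] - ref["x_min"] + dims["w"]) / 2 * runif(1, 0.75, 1.0)
          ctr <- rc + d * c(cos(ang), sin(ang))
        } else {
          ctr <- rnorm(2, s / 2, p$center_bias_sigma * s)
        }
        ctr[1L] <- min(max(ctr[1L], dims["w"] / 2 + margin), s - dims["w"] / 2 - margin)
        ctr[2L] <- min(max(ctr[2L], dims["h"] / 2 + margin), s - dims["h"] / 2 - margin)
        cand <- c(x_min = ctr[1L] - dims["w"] / 2, x_max = ctr[1L] + dims["w"] / 2,
                  y_min = ctr[2L] - dims["h"] / 2, y_max = ctr[2L] + dims["h"] / 2)
        names(cand) <- c("x_min", "x_max", "y_min", "y_max")
        if (adhere || !.boxes_intersect(cand, placed)) { ok <- TRUE; break }
      }
      if (!ok) next
      geo <- .capsule_from_box(dims["w"] - 1, dims["h"] - 1)
      col <- c(0.72, 0.55, 0.33) * runif(1, 0.75, 1.15) +
        c(runif(1, -0.04, 0.04), runif(1, -0.04, 0.04), runif(1, -0.03, 0.03))
      res <- .draw_capsule(img, ctr[1L], ctr[2L], geo$theta, geo$hl, geo$rho,
                           pmin(pmax(col, 0), 1))
      img <- res$img
      if (is.null(res$bbox)) next
      bb <- res$bbox
      placed[[length(placed) + 1L]] <- bb
      labels[[length(labels) + 1L]] <- c(
        0,
        (bb["x_min"] + bb["x_max"]) / 2 / s,
        (bb["y_min"] + bb["y_max"]) / 2 / s,
        (bb["x_max"] - bb["x_min"] + 1) / s,
        (bb["y_max"] - bb["y_min"] + 1) / s)
    }
    img <- .draw_distractors(img, p)
    img <- .gauss_blur(img, p$turbidity_blur_sigma)
    img <- img + array(stats::rnorm(length(img), sd = 0.012), dim(img))
    img8 <- array(as.integer(round(pmin(pmax(img, 0), 1) * 255)), dim(img))
    lab <- if (length(labels)) do.call(rbind, labels)
    else matrix(numeric(), 0L, 5L)
    colnames(lab) <- c("class", "cx", "cy", "w", "h")
    rownames(lab) <- NULL
    structure(list(image = img8, labels = lab), class = "image_sample")
  })
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("<image_sample> %dx%d px, %d labeled particle(s)\n",
              dim(x$image)[2L], dim(x$image)[1L], nrow(x$labels)))
  invisible(x)
}

#' Seeded train/validation index split
#'
#' @param n number of samples (>= 2).
#' @param split_ratio training fraction in (0, 1); the training count is
#'   `round(n * split_ratio)`.
#' @param seed integer seed.
#' @return list with integer vectors `train` and `val`.
#' @export
split_dataset <- function(n, split_ratio = 0.9, seed = 0L) {
  if (n < 2L) stop("n must be >= 2")
  if (split_ratio <= 0 || split_ratio >= 1) stop("split_ratio must be in (0, 1)")
  .with_seed(seed, {
    ord <- sample(n)
    ntr <- round(n * split_ratio)
    ntr <- min(max(ntr, 1L), n - 1L)
    list(train = sort(ord[seq_len(ntr)]), val = sort(ord[(ntr + 1L):n]))
  })
}

#' Generate a dataset in YOLO directory layout
#'
#' Writes `images/{train,val}/*.png`, `labels/{train,val}/*.txt` and a
#' `data.yaml` manifest under `out_dir`. The i-th sample is generated with
#' seed `seed + i`, and the train/val split with `seed`, so a rerun with
#' the same arguments reproduces the dataset byte for byte.
#'
#' @param p a [scene_params()].
#' @param n number of images (>= 2).
#' @param split_ratio training fraction (default 0.9).
#' @param out_dir output directory; must be empty or absent unless `force`.
#' @param seed integer seed.
#' @param force overwrite a non-empty `out_dir`?
#' @return (invisibly) list with the train/val file manifests.
#' @export
generate_dataset <- function(p, n, split_ratio = 0.9, out_dir, seed = 0L,
                             force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force)
    stop("out_dir exists and is not empty (use force = TRUE to overwrite)")
  sp <- split_dataset(n, split_ratio, seed)
  for (d in c("images/train", "images/val", "labels/train", "labels/val"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(train = character(), val = character())
  for (i in seq_len(n)) {
    split <- if (i %in% sp$train) "train" else "val"
    smp <- generate_sample(p, seed = seed + i)
    stem <- sprintf("img_%05d", i)
    img_path <- file.path(out_dir, "images", split, paste0(stem, ".png"))
    write_image(smp$image, img_path)
    write_yolo_labels(smp$labels,
                      file.path(out_dir, "labels", split, paste0(stem, ".txt")))
    manifest[[split]] <- c(manifest[[split]], img_path)
  }
  yaml::write_yaml(list(path = normalizePath(out_dir),
                        train = "images/train", val = "images/val",
                        nc = 1L, names = list("residual_feed")),
                   file.path(out_dir, "data.yaml"))
  invisible(manifest)
}

# ---- augmentation -------------------------------------------------------

# rotate an (H,W,3) image k*90 degrees counter-clockwise
.rot90_img <- function(img, k) {
  k <- k %% 4L
  if (k == 0L) return(img)
  for (r in seq_len(k)) {
    h <- dim(img)[1L]; w <- dim(img)[2L]
    out <- array(0L, c(w, h, 3L))
    for (ch in 1:3) out[, , ch] <- t(img[, , ch])[w:1, , drop = FALSE]
    img <- out
  }
  img
}

# label map for one 90-degree counter-clockwise rotation:
# (cx, cy, w, h) -> (cy, 1 - cx, h, w)
.rot90_labels <- function(lab, k) {
  k <- k %% 4L
  for (r in seq_len(k))
    lab <- cbind(class = lab[, 1L], cx = lab[, 3L], cy = 1 - lab[, 2L],
                 w = lab[, 5L], h = lab[, 4L])
  lab
}

#' Geometric + photometric augmentation ("complete" pipeline)
#'
#' Applies random cropping, rotation (multiples of 90 degrees, keeping the
#' label geometry exact), horizontal flipping, and brightness/contrast
#' adjustment, with label-consistent geometry. Cropping drops boxes that
#' retain less than 30% of their original area. Each transform parameter
#' can be fixed explicitly (useful for tests); unset parameters are drawn
#' from the seeded RNG.
#'
#' @param s an `image_sample`.
#' @param seed integer seed for the random draws.
#' @param flip horizontal flip (logical), or `NULL` to draw.
#' @param rot_k number of 90-degree counter-clockwise rotations (0-3), or
#'   `NULL` to draw.
#' @param crop crop window `c(x0, y0, size)` in normalized units, or
#'   `NULL` to draw (`c(0, 0, 1)` = no crop).
#' @param brightness,contrast photometric gains (1 = identity), or `NULL`
#'   to draw.
#' @param min_area_frac label retention threshold under cropping.
#' @return the augmented `image_sample`.
#' @export
augment_complete <- function(s, seed = 0L, flip = NULL, rot_k = NULL,
                             crop = NULL, brightness = NULL, contrast = NULL,
                             min_area_frac = 0.3) {
  stopifnot(inherits(s, "image_sample"))
  .with_seed(seed, {
    if (is.null(flip)) flip <- runif(1) < 0.5
    if (is.null(rot_k)) rot_k <- sample(0:3, 1L)
    if (is.null(crop)) {
      size <- runif(1, 0.7, 1)
      crop <- c(runif(1, 0, 1 - size), runif(1, 0, 1 - size), size)
    }
    if (is.null(brightness)) brightness <- runif(1, 0.85, 1.15)
    if (is.null(contrast)) contrast <- runif(1, 0.85, 1.15)
    img <- s$image
    lab <- s$labels

    # crop (normalized window), renormalize labels, drop small remnants
    if (crop[3L] < 1) {
      sz <- dim(img)[1L]
      x0 <- round(crop[1L] * sz); y0 <- round(crop[2L] * sz)
      cs <- round(crop[3L] * sz)
      x0 <- min(max(x0, 0L), sz - cs); y0 <- min(max(y0, 0L), sz - cs)
      img <- img[(y0 + 1L):(y0 + cs), (x0 + 1L):(x0 + cs), , drop = FALSE]
      if (nrow(lab) > 0L) {
        px <- cbind(x1 = (lab[, 2L] - lab[, 4L] / 2) * sz - x0,
                    x2 = (lab[, 2L] + lab[, 4L] / 2) * sz - x0,
                    y1 = (lab[, 3L] - lab[, 5L] / 2) * sz - y0,
                    y2 = (lab[, 3L] + lab[, 5L] / 2) * sz - y0)
        cl <- cbind(pmin(pmax(px[, "x1"], 0), cs), pmin(pmax(px[, "x2"], 0), cs),
                    pmin(pmax(px[, "y1"], 0), cs), pmin(pmax(px[, "y2"], 0), cs))
        area_new <- pmax(cl[, 2L] - cl[, 1L], 0) * pmax(cl[, 4L] - cl[, 3L], 0)
        area_old <- (px[, "x2"] - px[, "x1"]) * (px[, "y2"] - px[, "y1"])
        keep <- area_new >= min_area_frac * area_old & area_new > 0
        lab <- cbind(class = lab[keep, 1L, drop = TRUE],
                     cx = (cl[keep, 1L] + cl[keep, 2L]) / 2 / cs,
                     cy = (cl[keep, 3L] + cl[keep, 4L]) / 2 / cs,
                     w = (cl[keep, 2L] - cl[keep, 1L]) / cs,
                     h = (cl[keep, 4L] - cl[keep, 3L]) / cs)
        if (!is.matrix(lab)) lab <- matrix(lab, ncol = 5L,
                                           dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))
      }
    }

    img <- .rot90_img(img, rot_k)
    lab <- .rot90_labels(lab, rot_k)
    if (flip) {
      img <- img[, dim(img)[2L]:1, , drop = FALSE]
      if (nrow(lab) > 0L) lab[, 2L] <- 1 - lab[, 2L]
    }
    imgf <- img / 255
    imgf <- (imgf - 0.5) * contrast + 0.5
    imgf <- imgf * brightness
    img <- array(as.integer(round(pmin(pmax(imgf, 0), 1) * 255)), dim(img))
    colnames(lab) <- c("class", "cx", "cy", "w", "h")
    structure(list(image = img, labels = lab), class = "image_sample")
  })
}

#' Copy-paste augmentation for small dense targets ("local" pipeline)
#'
#' Crops labeled particle patches from donor samples and pastes them at
#' center-biased free locations of `s`, appending the corresponding
#' labels. A pasted box never overlaps an existing label above IoU 0.1
#' (rejection sampling); pastes that find no free location within the try
#' budget are skipped with a warning.
#'
#' @param s an `image_sample` to augment.
#' @param donors non-empty list of `image_sample` donors.
#' @param seed integer seed.
#' @param n_paste number of patches to paste.
#' @param max_tries placement attempts per patch.
#' @return the augmented `image_sample` (label count never decreases).
#' @export
augment_local <- function(s, donors, seed = 0L, n_paste = 3L,
                          max_tries = 30L) {
  stopifnot(inherits(s, "image_sample"), length(donors) > 0L)
  .with_seed(seed, {
    img <- s$image
    lab <- s$labels
    sz <- dim(img)[1L]
    boxes <- lab
    for (k in seq_len(n_paste)) {
      # pick a donor patch
      patch <- NULL
      for (t in seq_len(10L)) {
        d <- donors[[sample(length(donors), 1L)]]
        if (nrow(d$labels) == 0L) next
        li <- sample(nrow(d$labels), 1L)
        dl <- d$labels[li, ]
        dsz <- dim(d$image)[1L]
        x1 <- max(1L, floor((dl[2L] - dl[4L] / 2) * dsz))
        x2 <- min(dsz, ceiling((dl[2L] + dl[4L] / 2) * dsz))
        y1 <- max(1L, floor((dl[3L] - dl[5L] / 2) * dsz))
        y2 <- min(dsz, ceiling((dl[3L] + dl[5L] / 2) * dsz))
        if (x2 > x1 && y2 > y1) {
          patch <- d$image[y1:y2, x1:x2, , drop = FALSE]
          patch_cls <- dl[1L]
          break
        }
      }
      if (is.null(patch)) next
      ph <- dim(patch)[1L]; pw <- dim(patch)[2L]
      if (ph >= sz - 4L || pw >= sz - 4L) next
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        ctr <- pmin(pmax(stats::rnorm(2, sz / 2, 0.2 * sz),
                         c(pw, ph) / 2 + 2), sz - c(pw, ph) / 2 - 2)
        cand <- c(0, ctr[1L] / sz, ctr[2L] / sz, pw / sz, ph / sz)
        ok <- TRUE
        if (nrow(boxes) > 0L) {
          for (b in seq_len(nrow(boxes))) {
            if (iou_xywh(cand[2:5] * sz, boxes[b, 2:5] * sz) > 0.1) {
              ok <- FALSE; break
            }
          }
        }
        if (!ok) next
        x0 <- round(ctr[1L] - pw / 2); y0 <- round(ctr[2L] - ph / 2)
        # feathered blend: full patch interior, soft 1-px border
        aw <- matrix(1, ph, pw)
        aw[1L, ] <- 0.5; aw[ph, ] <- 0.5; aw[, 1L] <- 0.5; aw[, pw] <- 0.5
        for (ch in 1:3) {
          tgt <- img[(y0 + 1L):(y0 + ph), (x0 + 1L):(x0 + pw), ch]
          img[(y0 + 1L):(y0 + ph), (x0 + 1L):(x0 + pw), ch] <-
            as.integer(round(tgt * (1 - aw) + patch[, , ch] * aw))
        }
        newlab <- c(patch_cls, (x0 + pw / 2) / sz, (y0 + ph / 2) / sz,
                    pw / sz, ph / sz)
        lab <- rbind(lab, newlab)
        boxes <- rbind(boxes, newlab)
        placed <- TRUE
        break
      }
      if (!placed)
        warning("no free paste location found within the try budget; paste skipped")
    }
    colnames(lab) <- c("class", "cx", "cy", "w", "h")
    rownames(lab) <- NULL
    structure(list(image = img, labels = lab), class = "image_sample")
  })
}

#' Label statistics of a sample collection
#'
#' Computes, purely from the labels: target counts, the fraction of small
#' targets (normalized box area below `(32/640)^2`, the small-object
#' threshold scaled to the image), the fraction of elongated targets
#' (aspect ratio above 2), a normalized spatial histogram of box centers,
#' and a histogram of relative box sizes.
#'
#' @param samples non-empty list of `image_sample` objects.
#' @param spatial_bins grid size of the spatial histogram.
#' @return an object of class `dataset_stats`.
#' @export
dataset_stats <- function(samples, spatial_bins = 8L) {
  stopifnot(length(samples) > 0L)
  labs <- do.call(rbind, lapply(samples, `[[`, "labels"))
  n_targets <- if (is.null(labs)) 0L else nrow(labs)
  if (n_targets == 0L) stop("no labels in the sample collection")
  area <- labs[, 4L] * labs[, 5L]
  small_thr <- (32 / 640)^2
  aspect <- pmax(labs[, 4L], labs[, 5L]) / pmin(labs[, 4L], labs[, 5L])
  bins <- function(v) pmin(pmax(ceiling(v * spatial_bins), 1L), spatial_bins)
  sp <- table(factor(bins(labs[, 3L]), levels = seq_len(spatial_bins)),
              factor(bins(labs[, 2L]), levels = seq_len(spatial_bins)))
  size_hist <- graphics::hist(sqrt(area) / (32 / 640),
                              breaks = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 4, Inf),
                              plot = FALSE)
  structure(list(
    n_images = length(samples),
    n_targets = n_targets,
    fraction_small = mean(area < small_thr),
    fraction_elongated = mean(aspect > 2),
    spatial_histogram = unclass(sp / sum(sp)),
    size_histogram = list(breaks = size_hist$breaks,
                          counts = size_hist$counts)
  ), class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf(
    "<dataset_stats> %d image(s), %d target(s)\n  small fraction: %.3f | elongated fraction: %.3f\n",
    x$n_images, x$n_targets, x$fraction_small, x$fraction_elongated))
  invisible(x)
}
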
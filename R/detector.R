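#' @title Compact trainable tray-feed detector
#' @description
#' A runnable, config-driven anchor-free detector for desk-scale
#' experiments: a small strided backbone (plain or ghost-block
#' bottlenecks), an optional parameter-free attention site, and a
#' single-scale decoupled-free head at stride 8 predicting, per grid cell,
#' box offsets `(tx, ty)`, box sizes `(tw, th)`, an objectness logit and
#' per-class logits. Training minimizes
#' `lambda1 * L_obj + lambda2 * L_cls + lambda3 * L_loc` where the
#' localization term is the elongation-aware IoU loss ([enwiou]) on decoded
#' boxes, with binary cross-entropy for objectness and classes, optimized
#' by Adam. The three architecture/loss improvements (ghost blocks,
#' attention, the modulated IoU loss) toggle independently for ablations.
#' @name detector
NULL

#' Configuration of the compact detector
#'
#' @param input_size training image size in pixels (multiple of 32).
#' @param num_classes number of classes (default 1: residual feed).
#' @param base_channels stem width; stages use 2x and 4x this.
#' @param use_repghost use ghost-block bottlenecks in the backbone stages.
#' @param use_ensimam insert the parameter-free attention after the
#'   backbone.
#' @param use_enwiou use the focusing/orientation-modulated IoU loss for
#'   localization (`FALSE`: plain `1 - IoU`).
#' @param loss_weights `c(obj, cls, loc)` loss weights.
#' @param nms_conf,nms_iou prediction confidence and NMS IoU thresholds.
#' @param ensimam_cfg,enwiou_cfg component configurations.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(input_size = 160L, num_classes = 1L,
                            base_channels = 8L,
                            use_repghost = TRUE, use_ensimam = TRUE,
                            use_enwiou = TRUE,
                            loss_weights = c(1.0, 0.5, 7.5),
                            nms_conf = 0.25, nms_iou = 0.45,
                            ensimam_cfg = ensimam_config(),
                            enwiou_cfg = enwiou_config()) {
  if (input_size %% 32L != 0L) stop("input_size must be a multiple of 32")
  if (any(loss_weights < 0)) stop("loss weights must be >= 0")
  structure(list(input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes),
                 base_channels = as.integer(base_channels),
                 use_repghost = isTRUE(use_repghost),
                 use_ensimam = isTRUE(use_ensimam),
                 use_enwiou = isTRUE(use_enwiou),
                 loss_weights = loss_weights,
                 nms_conf = nms_conf, nms_iou = nms_iou,
                 ensimam_cfg = ensimam_cfg, enwiou_cfg = enwiou_cfg),
            class = "detector_config")
}

#' Read a detector configuration from a YAML file
#'
#' The file may set any argument of [detector_config()] (unknown keys are
#' an error); unset keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `detector_config`.
#' @export
detector_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(detector_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown detector config keys: ",
                        paste(bad, collapse = ", "))
  if (!is.null(vals$loss_weights)) vals$loss_weights <- unlist(vals$loss_weights)
  do.call(detector_config, vals)
}

.conv_bn_act <- function(cin, cout, k, s) {
  list(nn_conv(cin, cout, k, s), nn_bn(cout), nn_act("silu"))
}

# backbone bottleneck: two 3x3 convs, or their ghost replacements
# (1x1 primary + depthwise 3x3, ratio 2), mirroring the nano mapping
.block <- function(c, ghost) {
  ch <- c %/% 2L
  if (ghost) {
    list(ghost_block(ghost_config(c, ch, ratio = 2L, primary_kernel = 1L)),
         ghost_block(ghost_config(ch, c, ratio = 2L, primary_kernel = 1L)))
  } else {
    c(.conv_bn_act(c, ch, 3L, 1L), .conv_bn_act(ch, c, 3L, 1L))
  }
}

#' Build a compact detector
#'
#' @param cfg a [detector_config()].
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `feed_detector`.
#' @examples
#' m <- build_detector(detector_config(base_channels = 8L), seed = 1)
#' count_params(m)
#' @export
build_detector <- function(cfg = detector_config(), seed = NULL) {
  stopifnot(inherits(cfg, "detector_config"))
  if (!is.null(seed)) set.seed(seed)
  c1 <- cfg$base_channels; c2 <- 2L * c1; c3 <- 4L * c1
  no <- 5L + cfg$num_classes
  layers <- c(
    .conv_bn_act(3L, c1, 3L, 2L),            # stride 2
    .conv_bn_act(c1, c2, 3L, 2L),            # stride 4
    .block(c2, cfg$use_repghost),
    .conv_bn_act(c2, c3, 3L, 2L),            # stride 8
    .block(c3, cfg$use_repghost)
  )
  if (cfg$use_ensimam) layers <- c(layers, list(nn_attention(cfg$ensimam_cfg)))
  layers <- c(layers,
              .conv_bn_act(c3, c3, 3L, 1L),
              list(nn_conv(c3, no, 1L, 1L, bias = TRUE)))
  structure(list(layers = layers, cfg = cfg, stride = 8L, trained = FALSE),
            class = "feed_detector")
}

.forward_model <- function(model, v, train = FALSE) {
  for (e in model$layers) v <- layer_forward(e, v, train)
  v
}

.backward_model <- function(model, dv) {
  for (e in rev(model$layers)) dv <- layer_backward(e, dv)
  dv
}

#' @export
count_params.feed_detector <- function(model, ...)
  as.integer(.n_params_layers(model$layers))

#' @export
count_flops.feed_detector <- function(model, input_size = model$cfg$input_size,
                                      ...) {
  hw <- as.integer(input_size)
  total_macs <- 0; bn_elts <- 0
  walk <- function(layers, hw) {
    for (e in layers) {
      if (e$type == "ghost") {
        hw <- walk(list(e$sub$primary_conv, e$sub$primary_bn), hw)
        if (e$cfg$ratio > 1L) {
          hw2 <- walk(list(e$sub$cheap_conv, e$sub$cheap_bn), hw)
          if (e$cfg$use_identity_branch)
            bn_elts <<- bn_elts + e$cfg$intrinsic * hw^2
          hw <- hw2
        }
      } else if (e$type == "conv") {
        ho <- (hw + 2L * e$pad - e$k) %/% e$stride + 1L
        total_macs <<- total_macs + (e$cin / e$groups) * e$cout * e$k^2 * ho^2
        hw <- ho
      } else if (e$type == "bn") {
        bn_elts <<- bn_elts + e$c * hw^2
      }
    }
    hw
  }
  walk(model$layers, hw)
  (2 * total_macs + 2 * bn_elts) / 1e9
}

#' @export
print.feed_detector <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "<feed_detector> %dpx, %d class(es), base width %d\n  ghost blocks: %s | attention: %s | modulated IoU loss: %s\n  %d learnable params | trained: %s\n",
    cfg$input_size, cfg$num_classes, cfg$base_channels,
    if (cfg$use_repghost) "yes" else "no",
    if (cfg$use_ensimam) "yes" else "no",
    if (cfg$use_enwiou) "yes" else "no",
    count_params(x), if (isTRUE(x$trained)) "yes" else "no"))
  invisible(x)
}

#' @export
summary.feed_detector <- function(object, ...) {
  print(object)
  h <- object$history
  if (!is.null(h)) {
    cat(sprintf("  trained %d epoch(s); total loss %.4f -> %.4f\n",
                nrow(h), h$total[1L], h$total[nrow(h)]))
    if ("val_map50" %in% names(h) && any(is.finite(h$val_map50)))
      cat(sprintf("  final val mAP@0.5: %.4f\n", h$val_map50[nrow(h)]))
  }
  invisible(object)
}

# image (H,W,3) in [0,255] -> (C,H,W) in [0,1], letterboxed (bottom/right
# gray padding) to a multiple of `mult`
.prep_image <- function(img, mult = 32L) {
  if (is.character(img)) img <- read_image(img)
  if (max(img) > 1) img <- img / 255
  h <- dim(img)[1L]; w <- dim(img)[2L]
  hp <- as.integer(ceiling(h / mult) * mult)
  wp <- as.integer(ceiling(w / mult) * mult)
  if (hp != h || wp != w) {
    pad <- array(114 / 255, c(hp, wp, 3L))
    pad[1:h, 1:w, ] <- img
    img <- pad
  }
  list(x = aperm(img, c(3L, 1L, 2L)), h = h, w = w)
}

.sig <- function(z) 1 / (1 + exp(-z))
.softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

# decode one head map (no x npos) to pixel boxes; returns matrix with
# columns cx, cy, w, h, obj_p, then class probabilities
.decode_head <- function(m, gh, gw, stride, num_classes) {
  npos <- gh * gw
  i <- rep(seq_len(gh), times = gw)   # row (y) index, position-major
  j <- rep(seq_len(gw), each = gh)
  cx <- (j - 1 + .sig(m[1L, ])) * stride
  cy <- (i - 1 + .sig(m[2L, ])) * stride
  w <- (2 * .sig(m[3L, ]))^2 * 4 * stride
  h <- (2 * .sig(m[4L, ]))^2 * 4 * stride
  obj <- .sig(m[5L, ])
  cls <- matrix(.sig(m[5L + seq_len(num_classes), , drop = FALSE]),
                num_classes, npos)
  cbind(cx = cx, cy = cy, w = pmax(w, 1e-6), h = pmax(h, 1e-6),
        obj = obj, t(cls))
}

# assign each ground-truth box (normalized labels) to the grid cell
# containing its center; one gt per cell (first wins)
.assign_targets <- function(labels, gh, gw, stride, img_h, img_w) {
  if (is.null(labels) || nrow(labels) == 0L)
    return(data.frame(pos = integer(), cls = integer(),
                      cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  cx <- labels[, 2L] * img_w; cy <- labels[, 3L] * img_h
  w <- labels[, 4L] * img_w; h <- labels[, 5L] * img_h
  j <- pmin(pmax(floor(cx / stride) + 1L, 1L), gw)
  i <- pmin(pmax(floor(cy / stride) + 1L, 1L), gh)
  pos <- as.integer(i + (j - 1L) * gh)
  keep <- !duplicated(pos)
  data.frame(pos = pos[keep], cls = as.integer(labels[keep, 1L]),
             cx = cx[keep], cy = cy[keep], w = w[keep], h = h[keep])
}

# loss (and optionally gradient w.r.t. the raw head output) for a batch.
# head: value object from the forward pass; targets: list of label
# matrices (class, cx, cy, w, h normalized)
.loss_and_grad <- function(head, targets, cfg, stride, img_h, img_w,
                           want_grad = TRUE) {
  lw <- cfg$loss_weights
  nc <- cfg$num_classes
  gh <- head$h; gw <- head$w
  n <- length(head$maps)
  obj_sum <- 0; cls_sum <- 0; cls_n <- 0
  loc_sum <- 0; loc_n <- 0
  dmaps <- if (want_grad) lapply(head$maps, function(m) m * 0)
  for (s in seq_len(n)) {
    m <- head$maps[[s]]
    npos <- ncol(m)
    tg <- .assign_targets(targets[[s]], gh, gw, stride, img_h, img_w)
    tobj <- numeric(npos); tobj[tg$pos] <- 1
    zo <- m[5L, ]
    obj_sum <- obj_sum + mean(.softplus(zo) - tobj * zo)
    if (want_grad)
      dmaps[[s]][5L, ] <- lw[1L] * (.sig(zo) - tobj) / (npos * n)
    if (nrow(tg) > 0L) {
      # classification (binary cross-entropy per class at assigned cells)
      zc <- matrix(m[5L + seq_len(nc), tg$pos], nc, nrow(tg))
      tc <- matrix(0, nc, nrow(tg))
      tc[cbind(tg$cls + 1L, seq_len(nrow(tg)))] <- 1
      cls_sum <- cls_sum + sum(.softplus(zc) - tc * zc)
      cls_n <- cls_n + nrow(tg) * nc
      # localization on decoded boxes
      for (q in seq_len(nrow(tg))) {
        p <- tg$pos[q]
        tx <- m[1L, p]; ty <- m[2L, p]; tw <- m[3L, p]; th <- m[4L, p]
        jj <- (p - 1L) %/% gh; ii <- (p - 1L) %% gh
        pb <- c(cx = (jj + .sig(tx)) * stride, cy = (ii + .sig(ty)) * stride,
                w = max((2 * .sig(tw))^2 * 4 * stride, 1e-6),
                h = max((2 * .sig(th))^2 * 4 * stride, 1e-6))
        gb <- c(cx = tg$cx[q], cy = tg$cy[q], w = tg$w[q], h = tg$h[q])
        if (cfg$use_enwiou) {
          bd <- enwiou(pb, gb, cfg$enwiou_cfg)
          loc_sum <- loc_sum + bd$loss
          if (want_grad) gbox <- .enwiou_grad(pb, gb, cfg$enwiou_cfg)
        } else {
          loc_sum <- loc_sum + (1 - iou_xywh(pb, gb))
          if (want_grad) gbox <- -.iou_grad_xywh(pb, gb)
        }
        loc_n <- loc_n + 1L
        if (want_grad) {
          sx <- .sig(tx); sy <- .sig(ty); sw <- .sig(tw); sh <- .sig(th)
          dmaps[[s]][1L, p] <- dmaps[[s]][1L, p] +
            gbox[1L] * stride * sx * (1 - sx)
          dmaps[[s]][2L, p] <- dmaps[[s]][2L, p] +
            gbox[2L] * stride * sy * (1 - sy)
          dmaps[[s]][3L, p] <- dmaps[[s]][3L, p] +
            gbox[3L] * 32 * stride * sw * sw * (1 - sw)
          dmaps[[s]][4L, p] <- dmaps[[s]][4L, p] +
            gbox[4L] * 32 * stride * sh * sh * (1 - sh)
        }
      }
      if (want_grad) {
        dmaps[[s]][5L + seq_len(nc), tg$pos] <-
          dmaps[[s]][5L + seq_len(nc), tg$pos] + lw[2L] * (.sig(zc) - tc)
      }
    }
  }
  obj <- obj_sum / n
  cls <- if (cls_n > 0L) cls_sum / cls_n else 0
  loc <- if (loc_n > 0L) loc_sum / loc_n else 0
  if (want_grad) {
    # normalize cls/loc grads by their counts (the sums above are raw)
    dmaps <- lapply(dmaps, function(dm) {
      if (cls_n > 0L) dm[5L + seq_len(nc), ] <- dm[5L + seq_len(nc), ] / cls_n
      if (loc_n > 0L) dm[1:4, ] <- dm[1:4, ] * lw[3L] / loc_n
      dm
    })
  }
  list(obj = obj, cls = cls, loc = loc,
       total = lw[1L] * obj + lw[2L] * cls + lw[3L] * loc,
       grad = if (want_grad) .val(dmaps, head$c, head$h, head$w))
}

#' Loss components for a batch of images
#'
#' Runs the forward pass in training mode on a batch and returns the
#' objectness, classification and localization losses and their weighted
#' total.
#'
#' @param model a [build_detector()] model.
#' @param samples list of `image_sample` objects (see [generate_sample()]).
#' @return list with `obj`, `cls`, `loc`, `total`.
#' @export
compute_losses <- function(model, samples) {
  b <- .make_batch(model, samples)
  head <- .forward_model(model, b$x, train = TRUE)
  out <- .loss_and_grad(head, b$labels, model$cfg, model$stride,
                        b$h, b$w, want_grad = FALSE)
  out[c("obj", "cls", "loc", "total")]
}

.make_batch <- function(model, samples, prepped = NULL) {
  xs <- if (is.null(prepped)) lapply(samples, function(s) .prep_image(s$image)$x)
  else prepped
  d <- dim(xs[[1L]])
  maps <- lapply(xs, function(x) matrix(x, d[1L], d[2L] * d[3L]))
  list(x = .val(maps, d[1L], d[2L], d[3L]),
       labels = lapply(samples, `[[`, "labels"),
       h = d[2L], w = d[3L])
}

#' Training configuration
#'
#' @param epochs,batch_size,learning_rate,seed the usual knobs; the
#'   optimizer is Adam.
#' @param eval_every validate (mAP@0.5 on `val`) every this many epochs
#'   (0 = never).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L,
                         learning_rate = 5e-3, seed = 0L, eval_every = 0L) {
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

#' Train a compact detector
#'
#' Runs the standard loop — forward, composite loss, backward, Adam step —
#' over a list of synthetic samples. Fully deterministic for a fixed seed.
#'
#' @param model a [build_detector()] model.
#' @param dataset list of `image_sample` objects.
#' @param tc a [train_config()].
#' @param val optional list of `image_sample` objects for per-epoch mAP.
#' @param verbose print per-epoch losses?
#' @return the trained model, with a `history` data.frame (per-epoch `obj`,
#'   `cls`, `loc`, `total`, and `val_map50` when validated).
#' @export
train_detector <- function(model, dataset, tc = train_config(), val = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(model, "feed_detector"), length(dataset) >= 1L)
  set.seed(tc$seed)
  opt <- adam_state(model$layers, lr = tc$learning_rate)
  prepped <- lapply(dataset, function(s) .prep_image(s$image)$x)
  hist <- vector("list", tc$epochs)
  for (ep in seq_len(tc$epochs)) {
    ord <- sample(length(dataset))
    sums <- c(obj = 0, cls = 0, loc = 0, total = 0); nb <- 0L
    for (start in seq(1L, length(ord), by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
      b <- .make_batch(model, dataset[idx], prepped = prepped[idx])
      .zero_grads(model$layers)
      head <- .forward_model(model, b$x, train = TRUE)
      lg <- .loss_and_grad(head, b$labels, model$cfg, model$stride, b$h, b$w)
      if (!is.finite(lg$total))
        stop(sprintf("non-finite loss at epoch %d (obj %.4g cls %.4g loc %.4g)",
                     ep, lg$obj, lg$cls, lg$loc))
      .backward_model(model, lg$grad)
      opt <- adam_step(opt)
      sums <- sums + c(lg$obj, lg$cls, lg$loc, lg$total); nb <- nb + 1L
    }
    row <- as.list(sums / nb)
    if (!is.null(val) && tc$eval_every > 0L &&
        (ep %% tc$eval_every == 0L || ep == tc$epochs)) {
      row$val_map50 <- .quick_map50(model, val)
    } else row$val_map50 <- NA_real_
    hist[[ep]] <- as.data.frame(row)
    if (verbose)
      cat(sprintf("epoch %2d: obj %.4f cls %.4f loc %.4f total %.4f%s\n",
                  ep, row$obj, row$cls, row$loc, row$total,
                  if (is.finite(row$val_map50))
                    sprintf(" val mAP@0.5 %.3f", row$val_map50) else ""))
  }
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

.quick_map50 <- function(model, val, conf = 0.05) {
  dets <- lapply(seq_along(val), function(i)
    predict(model, val[[i]]$image, conf = conf))
  gts <- lapply(val, function(s) {
    h <- dim(s$image)[1L]; w <- dim(s$image)[2L]
    lb <- s$labels
    if (is.null(lb) || nrow(lb) == 0L)
      return(data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                        h = numeric(), class_id = integer()))
    data.frame(cx = lb[, 2L] * w, cy = lb[, 3L] * h,
               w = lb[, 4L] * w, h = lb[, 5L] * h,
               class_id = as.integer(lb[, 1L]))
  })
  tryCatch(map_metrics(dets, gts)$map50, error = function(e) NA_real_)
}

#' Predict detections on an image
#'
#' Runs the model in evaluation mode (fused ghost blocks are fine), decodes
#' the head to pixel-space boxes, filters by confidence, applies
#' class-aware greedy NMS, and clips boxes to the image. Images whose size
#' is not a multiple of 32 are letterboxed (bottom/right gray padding),
#' never rejected.
#'
#' @param object a `feed_detector`.
#' @param image `(H,W,3)` array in 0..255 (or 0..1), or a PNG path.
#' @param conf,iou confidence and NMS IoU thresholds (defaults from the
#'   model config).
#' @param ... unused.
#' @return data.frame of detections: `cx, cy, w, h` (pixels), `score`,
#'   `class_id`.
#' @export
predict.feed_detector <- function(object, image,
                                  conf = object$cfg$nms_conf,
                                  iou = object$cfg$nms_iou, ...) {
  pi <- .prep_image(image)
  v <- .val_from_array(array(pi$x, c(1L, dim(pi$x))))
  head <- .forward_model(object, v, train = FALSE)
  nc <- object$cfg$num_classes
  dec <- .decode_head(head$maps[[1L]], head$h, head$w, object$stride, nc)
  cls_p <- dec[, 5L + seq_len(nc), drop = FALSE]
  best <- max.col(cls_p, ties.method = "first")
  score <- dec[, "obj"] * cls_p[cbind(seq_len(nrow(dec)), best)]
  keep <- which(score >= conf)
  dets <- data.frame(cx = dec[keep, "cx"], cy = dec[keep, "cy"],
                     w = dec[keep, "w"], h = dec[keep, "h"],
                     score = score[keep], class_id = best[keep] - 1L)
  dets <- nms(dets, iou_thr = iou)
  if (nrow(dets) > 0L) {
    # clip to the original (pre-letterbox) image
    x1 <- pmax(dets$cx - dets$w / 2, 0); x2 <- pmin(dets$cx + dets$w / 2, pi$w)
    y1 <- pmax(dets$cy - dets$h / 2, 0); y2 <- pmin(dets$cy + dets$h / 2, pi$h)
    ok <- x2 > x1 & y2 > y1
    dets <- data.frame(cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                       w = x2 - x1, h = y2 - y1,
                       score = dets$score, class_id = dets$class_id)[ok, ]
    rownames(dets) <- NULL
  }
  dets
}

#' Greedy non-maximum suppression
#'
#' Score-descending, class-aware: within each class, a detection is kept
#' iff its IoU with every higher-scoring kept detection of that class is
#' at most `iou_thr`.
#'
#' @param dets data.frame with `cx, cy, w, h, score, class_id`.
#' @param iou_thr suppression threshold.
#' @return the surviving subset, score-descending.
#' @export
nms <- function(dets, iou_thr = 0.45) {
  if (nrow(dets) == 0L) return(dets)
  if (any(dets$score < 0 | dets$score > 1))
    stop("scores must be in [0, 1]")
  dets <- dets[order(-dets$score), , drop = FALSE]
  keep <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (dets$class_id[j] != dets$class_id[i]) next
      if (iou_xywh(unlist(dets[j, 1:4]), unlist(dets[i, 1:4])) > iou_thr) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fuse every ghost block of a model into single-path inference form
#'
#' @param model a `feed_detector`.
#' @return the model (ghost blocks fused in place).
#' @export
fuse_detector <- function(model) {
  for (e in model$layers)
    if (e$type == "ghost" && e$mode != "fused_inference") fuse_ghost(e)
  model
}
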
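# Independent reference implementations used as oracles. These are written
# as literal, loop-based transcriptions of the definitions and never share
# code with the package internals they check.

sigm <- function(z) 1 / (1 + exp(-z))

# per-pixel, loop-based three-branch attention on a (C,H,W) array
# (zero padding, divisor M-1, literal channel L2 fusion norm)
naive_ensimam <- function(x, lambda = 1e-4, alpha = 1, beta = 1,
                          eps = 1e-4) {
  C <- dim(x)[1L]; H <- dim(x)[2L]; W <- dim(x)[3L]
  out <- array(0, dim(x))
  at <- function(ch, i, j) if (i >= 1 && i <= H && j >= 1 && j <= W) ch[i, j] else 0
  for (c in seq_len(C)) {
    ch <- matrix(x[c, , ], H, W)
    mu <- mean(ch)
    v <- sum((ch - mu)^2) / (H * W - 1)
    nrm <- sqrt(sum(ch^2))
    wg <- nrm / (nrm + eps)
    wl <- (1 - wg) / 2
    for (i in seq_len(H)) for (j in seq_len(W)) {
      ag <- sigm((ch[i, j] - mu)^2 / (4 * (v + lambda)) + 0.5)
      vals <- numeric(9); k <- 0
      for (di in -1:1) for (dj in -1:1) {
        k <- k + 1; vals[k] <- at(ch, i + di, j + dj)
      }
      mloc <- mean(vals)
      vloc <- mean((vals - mloc)^2)
      al <- sigm(alpha * vloc)
      gx <- -at(ch, i - 1, j - 1) + at(ch, i - 1, j + 1) -
        2 * at(ch, i, j - 1) + 2 * at(ch, i, j + 1) -
        at(ch, i + 1, j - 1) + at(ch, i + 1, j + 1)
      gy <- -at(ch, i - 1, j - 1) - 2 * at(ch, i - 1, j) - at(ch, i - 1, j + 1) +
        at(ch, i + 1, j - 1) + 2 * at(ch, i + 1, j) + at(ch, i + 1, j + 1)
      ae <- sigm(beta * sqrt(gx^2 + gy^2))
      a <- wg * ag + wl * al + wl * ae
      out[c, i, j] <- ch[i, j] * a
    }
  }
  out
}

# formula-literal scalar loss: composes the defining pieces directly
naive_enwiou <- function(pred, gt, alpha = 1.9, delta = 3, tau = 2,
                         eta = 0.1) {
  inter_1d <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))
  iw <- inter_1d(pred[1] - pred[3] / 2, pred[1] + pred[3] / 2,
                 gt[1] - gt[3] / 2, gt[1] + gt[3] / 2)
  ih <- inter_1d(pred[2] - pred[4] / 2, pred[2] + pred[4] / 2,
                 gt[2] - gt[4] / 2, gt[2] + gt[4] / 2)
  inter <- iw * ih
  iou <- inter / (pred[3] * pred[4] + gt[3] * gt[4] - inter)
  d <- sqrt((gt[1] - pred[1])^2 + (gt[2] - pred[2])^2)
  wg <- max(pred[1] + pred[3] / 2, gt[1] + gt[3] / 2) -
    min(pred[1] - pred[3] / 2, gt[1] - gt[3] / 2)
  hg <- max(pred[2] + pred[4] / 2, gt[2] + gt[4] / 2) -
    min(pred[2] - pred[4] / 2, gt[2] - gt[4] / 2)
  beta <- d / sqrt(wg^2 + hg^2)
  r <- beta / (delta * alpha^(beta - delta))
  ar <- function(b) max(b[3], b[4]) / min(b[3], b[4])
  gamma <- if (max(ar(pred), ar(gt)) > tau) {
    same <- (pred[3] > pred[4]) == (gt[3] > gt[4])
    if (same) 1 - eta else 1 + eta
  } else 1
  min(max(r * (1 - iou) * gamma, 0), 1)
}

# loop-based ghost module forward in evaluation mode (zero-initialized
# running stats are fine for shape checks; used with explicit weights)
naive_conv2d <- function(x, W, k, stride, groups = 1, b = NULL) {
  # x: (C,H,W); W: cout x (cin/g * k^2), channel fastest then kernel row/col
  C <- dim(x)[1L]; H <- dim(x)[2L]; Wd <- dim(x)[3L]
  pad <- k %/% 2L
  cout <- nrow(W); cpg_in <- C / groups; cpg_out <- cout / groups
  xp <- array(0, c(C, H + 2 * pad, Wd + 2 * pad))
  xp[, pad + seq_len(H), pad + seq_len(Wd)] <- x
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (Wd + 2 * pad - k) %/% stride + 1L
  y <- array(0, c(cout, Ho, Wo))
  for (co in seq_len(cout)) {
    g <- ceiling(co / cpg_out)
    for (io in seq_len(Ho)) for (jo in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(cpg_in)) for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
        widx <- ci + di * cpg_in + dj * cpg_in * k
        acc <- acc + W[co, widx] *
          xp[(g - 1) * cpg_in + ci, (io - 1) * stride + 1 + di,
             (jo - 1) * stride + 1 + dj]
      }
      y[co, io, jo] <- acc + if (is.null(b)) 0 else b[co]
    }
  }
  y
}

# independent O(n^2) greedy NMS (score-descending, class-aware)
naive_nms <- function(dets, iou_thr) {
  if (nrow(dets) == 0L) return(dets)
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  kept <- integer()
  for (i in seq_len(nrow(dets))) {
    suppress <- FALSE
    for (j in kept) {
      if (dets$class_id[j] != dets$class_id[i]) next
      if (feedtray::iou_xywh(unlist(dets[j, c("cx", "cy", "w", "h")]),
                             unlist(dets[i, c("cx", "cy", "w", "h")])) > iou_thr)
        suppress <- TRUE
    }
    if (!suppress) kept <- c(kept, i)
  }
  out <- dets[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force PR-curve integration: exact area under the interpolated
# precision envelope
naive_ap_allpoint <- function(scores, tp, n_gt) {
  ord <- order(-scores)
  tp <- tp[ord]
  tpc <- cumsum(tp); fpc <- cumsum(!tp)
  prec <- tpc / (tpc + fpc); rec <- tpc / n_gt
  ap <- 0; prev_r <- 0
  for (r in sort(unique(rec))) {
    if (r <= prev_r) next
    p_int <- max(prec[rec >= r - 1e-12])
    ap <- ap + (r - prev_r) * p_int
    prev_r <- r
  }
  ap
}

rand_boxes_df <- function(n, size = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(cx = runif(n, 10, size - 10), cy = runif(n, 10, size - 10),
             w = runif(n, 4, 30), h = runif(n, 4, 30),
             score = runif(n), class_id = sample(0:1, n, replace = TRUE))
}

# small seeded sample cache so several test files can share fixtures
easy_samples <- local({
  cache <- NULL
  function(n = 8L, seed0 = 5000L) {
    if (is.null(cache) || length(cache) < n) {
      p <- feedtray::scene_params_easy()
      cache <<- lapply(seq_len(n), function(i)
        feedtray::generate_sample(p, seed = seed0 + i))
    }
    cache[seq_len(n)]
  }
})
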
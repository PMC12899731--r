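#' @title Structural architecture specifications and complexity profiling
#' @description
#' A `detector_spec` is an exact, layer-by-layer enumeration of every
#' convolution, batch-normalization and attention site in a detector
#' architecture, together with the spatial size each layer sees at a stated
#' input resolution. It carries no weights: it exists so that learnable
#' parameter counts and floating-point operation counts can be computed
#' exactly and deterministically, without instantiating or running the
#' network.
#'
#' Complexity conventions (chosen once, stated here and in `count_flops`):
#' * parameters = learnable scalars only (conv weights, biases, BN scale and
#'   shift). Fixed-weight layers (e.g. the distribution-focal decoding conv)
#'   are excluded.
#' * FLOPs = 2 x multiply-accumulates of convolution/linear layers plus
#'   2 FLOPs per element normalized by an affine batch-normalization layer,
#'   at the stated input size (the convention of the thop profiler behind
#'   most detector model cards). Pooling, activation, upsampling and the
#'   parameter-free attention sites count zero.
#' @name arch-spec
NULL

# internal accumulator for layer records
.arch_env <- function(input_size) {
  e <- new.env(parent = emptyenv())
  e$records <- list()
  e$input_size <- input_size
  e
}

# append one layer record; returns the output spatial size
.rec <- function(E, module, kind, cin, cout, k = 1L, stride = 1L, groups = 1L,
                 hw, bn = TRUE, bias = !bn, learnable = TRUE, npos = NA_real_) {
  hw_out <- if (kind == "conv") (hw + 2L * (k %/% 2L) - k) %/% stride + 1L else hw
  E$records[[length(E$records) + 1L]] <- data.frame(
    module = module, kind = kind, cin = cin, cout = cout, k = k,
    stride = stride, groups = groups, hw_in = hw, hw_out = hw_out,
    bn = bn, bias = bias, learnable = learnable,
    npos = if (is.na(npos)) as.numeric(hw_out)^2 else npos,
    stringsAsFactors = FALSE
  )
  hw_out
}

# Conv = conv2d (no bias) + BN + activation
.cv <- function(E, m, c1, c2, k = 1L, s = 1L, g = 1L, hw) {
  list(c = c2, hw = .rec(E, m, "conv", c1, c2, k, s, g, hw))
}

# Ghost module, ratio s = 2: primary conv to c2/2 intrinsic channels,
# cheap depthwise 3x3 producing the ghost half, plus (training form) a
# fusible BN-only shortcut on the cheap path.
.ghost <- function(E, m, c1, c2, k = 1L, s = 1L, hw, identity_branch = TRUE) {
  mc <- c2 %/% 2L
  stopifnot(mc * 2L == c2)
  out <- .cv(E, m, c1, mc, k, s, 1L, hw)
  .cv(E, m, mc, mc, 3L, 1L, mc, out$hw)
  if (identity_branch) .rec(E, m, "bn", mc, mc, hw = out$hw)
  list(c = c2, hw = out$hw)
}

# conv that may be replaced by a ghost module (downsampling uses a strided
# 3x3 primary; unit-stride replacements use a 1x1 primary + depthwise 3x3)
.cvg <- function(E, m, c1, c2, k = 1L, s = 1L, hw, ghost = FALSE) {
  if (!ghost) return(.cv(E, m, c1, c2, k, s, 1L, hw))
  .ghost(E, m, c1, c2, k = if (s > 1L) k else 1L, s = s, hw = hw)
}

.sppf_ghost <- function(E, m, c1, c2, hw) {
  ch <- c1 %/% 2L
  .ghost(E, m, c1, ch, 1L, 1L, hw)
  .ghost(E, m, ch * 4L, c2, 1L, 1L, hw)
  list(c = c2, hw = hw)
}

.bottleneck <- function(E, m, c1, c2, e = 0.5, hw, ghost = FALSE) {
  ch <- as.integer(c2 * e)
  if (ghost) {
    a <- .ghost(E, m, c1, ch, 1L, 1L, hw)
    .ghost(E, m, ch, c2, 1L, 1L, a$hw)
  } else {
    a <- .cv(E, m, c1, ch, 3L, 1L, 1L, hw)
    .cv(E, m, ch, c2, 3L, 1L, 1L, a$hw)
  }
  list(c = c2, hw = hw)
}

.c3k <- function(E, m, c1, c2, n = 2L, e = 0.5, hw, ghost = FALSE) {
  ch <- as.integer(c2 * e)
  .cv(E, m, c1, ch, 1L, 1L, 1L, hw)
  .cv(E, m, c1, ch, 1L, 1L, 1L, hw)
  for (i in seq_len(n)) .bottleneck(E, m, ch, ch, e = 1.0, hw = hw, ghost = ghost)
  .cv(E, m, 2L * ch, c2, 1L, 1L, 1L, hw)
  list(c = c2, hw = hw)
}

.c3k2 <- function(E, m, c1, c2, n = 1L, c3k = FALSE, e = 0.5, hw, ghost = FALSE) {
  ch <- as.integer(c2 * e)
  .cvg(E, m, c1, 2L * ch, 1L, 1L, hw, ghost = ghost)
  for (i in seq_len(n)) {
    if (c3k) .c3k(E, m, ch, ch, 2L, 0.5, hw, ghost = ghost)
    else .bottleneck(E, m, ch, ch, 0.5, hw, ghost = ghost)
  }
  .cvg(E, m, (2L + n) * ch, c2, 1L, 1L, hw, ghost = ghost)
  list(c = c2, hw = hw)
}

.sppf <- function(E, m, c1, c2, hw) {
  ch <- c1 %/% 2L
  .cv(E, m, c1, ch, 1L, 1L, 1L, hw)
  .cv(E, m, ch * 4L, c2, 1L, 1L, 1L, hw)
  list(c = c2, hw = hw)
}

# position-sensitive attention block of the C2PSA stage: qkv/proj 1x1 convs,
# depthwise positional conv, and a 1x1 feed-forward pair
.psablock <- function(E, m, d, hw) {
  heads <- max(1L, d %/% 64L)
  key_dim <- as.integer((d %/% heads) * 0.5)
  h <- d + 2L * key_dim * heads
  .cv(E, m, d, h, 1L, 1L, 1L, hw)       # qkv
  .cv(E, m, d, d, 1L, 1L, 1L, hw)       # proj
  .cv(E, m, d, d, 3L, 1L, d, hw)        # positional (depthwise)
  .cv(E, m, d, 2L * d, 1L, 1L, 1L, hw)  # ffn expand
  .cv(E, m, 2L * d, d, 1L, 1L, 1L, hw)  # ffn project
}

.c2psa <- function(E, m, c1, n = 1L, hw) {
  ch <- c1 %/% 2L
  .cv(E, m, c1, 2L * ch, 1L, 1L, 1L, hw)
  for (i in seq_len(n)) .psablock(E, m, ch, hw)
  .cv(E, m, 2L * ch, c1, 1L, 1L, 1L, hw)
  list(c = c1, hw = hw)
}

.detect_head <- function(E, num_classes, chs, hws, reg_max = 16L) {
  c2 <- max(16L, chs[1L] %/% 4L, 4L * reg_max)
  c3 <- max(chs[1L], min(num_classes, 100L))
  for (i in seq_along(chs)) {
    ch <- chs[i]; hw <- hws[i]; m <- sprintf("detect.p%d", i + 2L)
    # box regression branch
    a <- .cv(E, m, ch, c2, 3L, 1L, 1L, hw)
    .cv(E, m, c2, c2, 3L, 1L, 1L, a$hw)
    .rec(E, m, "conv", c2, 4L * reg_max, 1L, 1L, 1L, hw, bn = FALSE, bias = TRUE)
    # classification branch (depthwise-separable)
    .cv(E, m, ch, ch, 3L, 1L, ch, hw)
    .cv(E, m, ch, c3, 1L, 1L, 1L, hw)
    .cv(E, m, c3, c3, 3L, 1L, c3, hw)
    .cv(E, m, c3, c3, 1L, 1L, 1L, hw)
    .rec(E, m, "conv", c3, num_classes, 1L, 1L, 1L, hw, bn = FALSE, bias = TRUE)
  }
  # distribution-focal decoding conv: fixed (non-learnable) weights, applied
  # to each of the 4 box sides at every anchor position
  .rec(E, "detect.dfl", "conv", reg_max, 1L, 1L, 1L, 1L, hws[1L],
       bn = FALSE, bias = FALSE, learnable = FALSE,
       npos = 4 * sum(as.numeric(hws)^2))
}

#' Build the structural specification of the nano-scale tray-feed detector
#'
#' Enumerates, convolution by convolution, the nano detector layout this
#' package profiles: a CSP-style backbone (stem, four downsampling stages
#' each followed by a split-bottleneck stage, spatial-pyramid pooling and a
#' position-sensitive attention stage), a PAN feature-fusion neck, and a
#' decoupled anchor-free head with distribution-focal box regression over
#' three strides (8/16/32).
#'
#' With `repghost = TRUE` the backbone is rebuilt with ghost-feature
#' modules: every convolution inside the four backbone split-bottleneck
#' stages (the bottleneck 3x3 pairs and the stage transition 1x1s), the
#' deepest (stride-32) downsampling convolution, and the two
#' pyramid-pooling projection convolutions are each replaced by a ghost
#' module of ratio 2 (primary convolution producing half the output
#' channels, a cheap depthwise 3x3 producing the other half, plus a fusible
#' normalization shortcut). The stem, the earlier downsampling convolutions,
#' the backbone attention stage, the neck and the head are untouched. The
#' methods vignette explains how this mapping is reconstructed from the
#' complexity budget the replacement is meant to achieve.
#'
#' With `ensimam = TRUE` parameter-free attention sites are inserted after
#' each neck fusion stage. They add zero learnable parameters and, by the
#' stated profiling convention, zero counted FLOPs.
#'
#' @param num_classes number of object classes (default 1: residual feed).
#' @param input_size square input resolution in pixels, multiple of 32.
#' @param repghost replace backbone convolutions with ghost modules?
#' @param ensimam insert parameter-free attention in the neck?
#' @param width_multiple,depth_multiple,max_channels nano scaling constants.
#' @return an object of class `detector_spec`.
#' @examples
#' spec <- nano_detector_spec(repghost = TRUE, ensimam = TRUE)
#' count_params(spec)
#' count_flops(spec)
#' @export
nano_detector_spec <- function(num_classes = 1L, input_size = 640L,
                               repghost = FALSE, ensimam = FALSE,
                               width_multiple = 0.25, depth_multiple = 0.50,
                               max_channels = 1024L) {
  if (input_size %% 32L != 0L) stop("input_size must be a multiple of 32")
  ch <- function(x) {
    x <- min(x, max_channels) * width_multiple
    as.integer(ceiling(x / 8) * 8)
  }
  nrep <- max(1L, as.integer(round(2L * depth_multiple)))
  E <- .arch_env(input_size)
  g <- repghost

  x0 <- .cv(E, "stem", 3L, ch(64), 3L, 2L, 1L, input_size)
  x1 <- .cv(E, "down.p2", x0$c, ch(128), 3L, 2L, 1L, x0$hw)
  x2 <- .c3k2(E, "stage.p2", x1$c, ch(256), nrep, FALSE, 0.25, x1$hw, ghost = g)
  x3 <- .cv(E, "down.p3", x2$c, ch(256), 3L, 2L, 1L, x2$hw)
  x4 <- .c3k2(E, "stage.p3", x3$c, ch(512), nrep, FALSE, 0.25, x3$hw, ghost = g)
  x5 <- .cv(E, "down.p4", x4$c, ch(512), 3L, 2L, 1L, x4$hw)
  x6 <- .c3k2(E, "stage.p4", x5$c, ch(512), nrep, TRUE, 0.5, x5$hw, ghost = g)
  x7 <- .cvg(E, "down.p5", x6$c, ch(1024), 3L, 2L, x6$hw, ghost = g)
  x8 <- .c3k2(E, "stage.p5", x7$c, ch(1024), nrep, TRUE, 0.5, x7$hw, ghost = g)
  x9 <- if (g) .sppf_ghost(E, "sppf", x8$c, ch(1024), x8$hw)
        else .sppf(E, "sppf", x8$c, ch(1024), x8$hw)
  x10 <- .c2psa(E, "c2psa", x9$c, nrep, x9$hw)

  attn <- function(m, c, hw) if (ensimam) .rec(E, m, "attention", c, c, hw = hw,
                                               bn = FALSE, bias = FALSE,
                                               learnable = FALSE)
  # top-down path
  x13 <- .c3k2(E, "neck.td.p4", x10$c + x6$c, ch(512), nrep, FALSE, 0.5, x6$hw)
  attn("neck.attn.td.p4", x13$c, x6$hw)
  x16 <- .c3k2(E, "neck.td.p3", x13$c + x4$c, ch(256), nrep, FALSE, 0.5, x4$hw)
  attn("neck.attn.td.p3", x16$c, x4$hw)
  # bottom-up path
  x17 <- .cv(E, "neck.bu.down.p4", x16$c, ch(256), 3L, 2L, 1L, x4$hw)
  x19 <- .c3k2(E, "neck.bu.p4", x17$c + x13$c, ch(512), nrep, FALSE, 0.5, x17$hw)
  attn("neck.attn.bu.p4", x19$c, x17$hw)
  x20 <- .cv(E, "neck.bu.down.p5", x19$c, ch(512), 3L, 2L, 1L, x17$hw)
  x22 <- .c3k2(E, "neck.bu.p5", x20$c + x10$c, ch(1024), nrep, TRUE, 0.5, x20$hw)
  attn("neck.attn.bu.p5", x22$c, x20$hw)

  .detect_head(E, as.integer(num_classes),
               chs = c(x16$c, x19$c, x22$c),
               hws = c(x4$hw, x17$hw, x20$hw))

  structure(list(
    records = do.call(rbind, E$records),
    num_classes = as.integer(num_classes),
    input_size = as.integer(input_size),
    repghost = repghost, ensimam = ensimam
  ), class = "detector_spec")
}

#' Count learnable parameters
#'
#' Exact count of learnable scalars: convolution weights (`cin/groups *
#' cout * k^2`), biases, and batch-normalization scale/shift pairs.
#' Fixed-weight layers and parameter-free attention sites count zero.
#'
#' @param model a `detector_spec` or a runnable `feed_detector` model.
#' @param ... unused.
#' @return integer parameter count.
#' @export
count_params <- function(model, ...) UseMethod("count_params")

#' @export
count_params.detector_spec <- function(model, ...) {
  r <- model$records
  r <- r[r$learnable, , drop = FALSE]
  w <- ifelse(r$kind == "conv", (r$cin / r$groups) * r$cout * r$k^2, 0)
  b <- ifelse(r$kind == "conv" & r$bias, r$cout, 0)
  bn <- ifelse((r$kind == "conv" & r$bn) | r$kind == "bn", 2 * r$cout, 0)
  as.integer(round(sum(w + b + bn)))
}

#' Count floating-point operations
#'
#' FLOPs = 2 x convolution/linear multiply-accumulates plus 2 FLOPs per
#' element normalized by an affine batch-normalization layer, at the
#' specification's input size (the thop profiler convention behind the
#' usual detector model cards). Activation, pooling, upsampling and
#' parameter-free attention count zero.
#'
#' @param model a `detector_spec` or a runnable `feed_detector` model.
#' @param ... unused.
#' @return FLOP count in GFLOPs (numeric).
#' @export
count_flops <- function(model, ...) UseMethod("count_flops")

#' @export
count_flops.detector_spec <- function(model, ...) {
  r <- model$records
  conv <- r[r$kind == "conv", , drop = FALSE]
  macs <- sum((conv$cin / conv$groups) * conv$cout * conv$k^2 * conv$npos)
  bn_elts <- sum(ifelse(conv$bn, conv$cout * conv$npos, 0)) +
    sum(ifelse(r$kind == "bn", r$cout * r$npos, 0))
  (2 * macs + 2 * bn_elts) / 1e9
}

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf(
    "<detector_spec> nano layout, %d class(es), %dpx input\n  ghost backbone: %s | neck attention: %s\n  %d layer records | %.3fM params | %.2f GFLOPs\n",
    x$num_classes, x$input_size,
    if (x$repghost) "yes" else "no", if (x$ensimam) "yes" else "no",
    nrow(x$records), count_params(x) / 1e6, count_flops(x)))
  invisible(x)
}
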
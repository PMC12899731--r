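#' @title Re-parameterizable ghost-feature convolution blocks
#' @description
#' A ghost module produces `n` output channels from `c` input channels at a
#' fraction of the cost of an ordinary convolution: a primary convolution
#' generates `m = n / s` *intrinsic* channels, and cheap depthwise `d x d`
#' transforms spawn the remaining `(s - 1) * m` *ghost* channels from them;
#' the output concatenates intrinsics first, then ghosts.
#'
#' The re-parameterizable variant trains with a multi-branch cheap path
#' (depthwise conv + batch norm, plus an optional norm-only shortcut) and
#' fuses it, at inference time, into a single depthwise convolution with
#' bias — arithmetically equivalent in evaluation mode because every branch
#' is linear. [fuse_ghost()] performs the folding; [theoretical_cost()]
#' evaluates the multiply-accumulate budget of the ordinary vs ghost
#' formulation.
#' @name repghost
NULL

#' Configuration of a ghost block
#'
#' @param in_channels,out_channels channel counts (`out_channels` must be
#'   divisible by `ratio`).
#' @param ratio ghost ratio `s >= 1`: intrinsic channels are
#'   `out_channels / s`. `s = 1` degenerates to an ordinary convolution.
#' @param primary_kernel odd kernel size of the primary convolution.
#' @param cheap_kernel odd kernel size `d` of the depthwise cheap transform.
#' @param stride stride of the primary convolution.
#' @param use_identity_branch add the norm-only shortcut on the cheap path
#'   (training form; requires `ratio = 2`).
#' @param merge `"concat"` (default: output `[intrinsic, ghost]`) or
#'   `"add"` (sum, output has `out_channels / ratio` channels; requires
#'   `ratio = 2`).
#' @param cheap_act apply the activation after the cheap-path branch sum
#'   (default `TRUE`).
#' @return an object of class `ghost_config`.
#' @export
ghost_config <- function(in_channels, out_channels, ratio = 2L,
                         primary_kernel = 1L, cheap_kernel = 3L,
                         stride = 1L, use_identity_branch = TRUE,
                         merge = c("concat", "add"), cheap_act = TRUE) {
  merge <- match.arg(merge)
  if (out_channels %% ratio != 0L)
    stop("out_channels must be divisible by ratio")
  if (primary_kernel %% 2L == 0L || cheap_kernel %% 2L == 0L)
    stop("kernels must be odd")
  if (ratio == 1L) use_identity_branch <- FALSE  # no cheap path to shortcut
  if (ratio > 2L && (use_identity_branch || merge == "add"))
    stop("identity branch and additive merge require ratio = 2")
  if (ratio == 1L && merge == "add")
    stop("additive merge requires ratio = 2")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 ratio = as.integer(ratio),
                 intrinsic = as.integer(out_channels %/% ratio),
                 primary_kernel = as.integer(primary_kernel),
                 cheap_kernel = as.integer(cheap_kernel),
                 stride = as.integer(stride),
                 use_identity_branch = isTRUE(use_identity_branch),
                 merge = merge, cheap_act = isTRUE(cheap_act)),
            class = "ghost_config")
}

#' Create a ghost block (training-time multi-branch form)
#'
#' @param cfg a [ghost_config()].
#' @return a ghost block (mutable environment), mode
#'   `"training_multibranch"`.
#' @export
ghost_block <- function(cfg) {
  stopifnot(inherits(cfg, "ghost_config"))
  e <- new.env(parent = emptyenv())
  e$type <- "ghost"
  e$cfg <- cfg
  e$mode <- "training_multibranch"
  m <- cfg$intrinsic
  s <- cfg$ratio
  e$sub <- list(
    primary_conv = nn_conv(cfg$in_channels, m, cfg$primary_kernel,
                           cfg$stride),
    primary_bn = nn_bn(m),
    primary_act = nn_act("silu")
  )
  if (s > 1L) {
    e$sub$cheap_conv <- nn_conv(m, m * (s - 1L), cfg$cheap_kernel,
                                1L, groups = m)
    e$sub$cheap_bn <- nn_bn(m * (s - 1L))
    if (cfg$use_identity_branch) e$sub$id_bn <- nn_bn(m)
    if (cfg$cheap_act) e$sub$cheap_out_act <- nn_act("silu")
  }
  e$param_names <- character()
  class(e) <- c("ghost_block", "environment")
  e
}

.vcat <- function(a, b) .val(lapply(seq_along(a$maps), function(n)
  rbind(a$maps[[n]], b$maps[[n]])), a$c + b$c, a$h, a$w)

.vslice <- function(v, rows) .val(lapply(v$maps, function(m)
  m[rows, , drop = FALSE]), length(rows), v$h, v$w)

.vadd <- function(a, b) .val(lapply(seq_along(a$maps), function(n)
  a$maps[[n]] + b$maps[[n]]), a$c, a$h, a$w)

.ghost_forward_block <- function(e, v, train) {
  cfg <- e$cfg
  if (e$mode == "fused_inference") {
    if (train) stop("cannot train a fused block")
    y1 <- .act_forward(nn_act("silu"),
                       .conv_forward(e$fused$primary, v, FALSE), FALSE)
    if (cfg$ratio == 1L) return(y1)
    z <- .conv_forward(e$fused$cheap, y1, FALSE)
    y2 <- if (cfg$cheap_act) .act_forward(nn_act("silu"), z, FALSE) else z
    return(if (cfg$merge == "add") .vadd(y1, y2) else .vcat(y1, y2))
  }
  s <- e$sub
  y1 <- layer_forward(s$primary_act,
                      layer_forward(s$primary_bn,
                                    layer_forward(s$primary_conv, v, train),
                                    train), train)
  if (cfg$ratio == 1L) return(y1)
  z <- layer_forward(s$cheap_bn, layer_forward(s$cheap_conv, y1, train),
                     train)
  if (cfg$use_identity_branch)
    z <- .vadd(z, layer_forward(s$id_bn, y1, train))
  y2 <- if (cfg$cheap_act) layer_forward(s$cheap_out_act, z, train) else z
  if (cfg$merge == "add") .vadd(y1, y2) else .vcat(y1, y2)
}

.ghost_backward_block <- function(e, dv) {
  cfg <- e$cfg
  if (e$mode == "fused_inference") stop("cannot backprop a fused block")
  s <- e$sub
  m <- cfg$intrinsic
  if (cfg$ratio == 1L) {
    dy1 <- dv
  } else {
    if (cfg$merge == "add") {
      dy1a <- dv; dy2 <- dv
    } else {
      dy1a <- .vslice(dv, seq_len(m))
      dy2 <- .vslice(dv, (m + 1L):dv$c)
    }
    dz <- if (cfg$cheap_act) layer_backward(s$cheap_out_act, dy2) else dy2
    dy1b <- layer_backward(s$cheap_conv, layer_backward(s$cheap_bn, dz))
    dy1 <- .vadd(dy1a, dy1b)
    if (cfg$use_identity_branch)
      dy1 <- .vadd(dy1, layer_backward(s$id_bn, dz))
  }
  layer_backward(s$primary_conv,
                 layer_backward(s$primary_bn,
                                layer_backward(s$primary_act, dy1)))
}

#' Run a ghost block on a feature map
#'
#' @param block a [ghost_block()].
#' @param x numeric array `(C,H,W)` or `(N,C,H,W)`.
#' @param train training mode (batch statistics, caches for backward)?
#' @return output array, `(N, n, H', W')` with intrinsics concatenated
#'   before ghosts.
#' @export
ghost_forward <- function(block, x, train = FALSE) {
  if (!is.array(x)) stop("x must be an array")
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  if (dim(x)[2L] != block$cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d",
                 block$cfg$in_channels, dim(x)[2L]))
  .val_to_array(.ghost_forward_block(block, .val_from_array(x), train))
}

# fold a batch norm (running statistics) into conv weights: returns the
# per-output-channel scale and shift
.bn_fold <- function(bn) {
  sd <- sqrt(bn$running_var + bn$eps)
  list(scale = bn$gamma / sd, shift = bn$beta - bn$gamma * bn$running_mean / sd)
}

#' Fuse a ghost block into its single-path inference form
#'
#' Folds each batch norm into the preceding convolution and merges the
#' norm-only shortcut into the depthwise cheap kernel (a center-tap
#' addition), leaving one convolution with bias per path segment. In
#' evaluation mode the fused block computes the same function as the
#' multi-branch form (agreement checked to 1e-5 elementwise in the test
#' suite). Fusing an already-fused block warns and returns it unchanged.
#'
#' @param block a [ghost_block()].
#' @return the same block, mode `"fused_inference"`.
#' @export
fuse_ghost <- function(block) {
  if (block$mode == "fused_inference") {
    warning("block is already fused; no-op")
    return(invisible(block))
  }
  cfg <- block$cfg
  s <- block$sub
  m <- cfg$intrinsic

  fp <- .bn_fold(s$primary_bn)
  primary <- nn_conv(cfg$in_channels, m, cfg$primary_kernel, cfg$stride,
                     bias = TRUE)
  primary$W <- s$primary_conv$W * fp$scale
  primary$b <- fp$shift
  fused <- list(primary = primary)

  if (cfg$ratio > 1L) {
    fc <- .bn_fold(s$cheap_bn)
    cheap <- nn_conv(m, m * (cfg$ratio - 1L), cfg$cheap_kernel, 1L,
                     groups = m, bias = TRUE)
    cheap$W <- s$cheap_conv$W * fc$scale
    cheap$b <- fc$shift
    if (cfg$use_identity_branch) {
      fi <- .bn_fold(s$id_bn)
      center <- (cfg$cheap_kernel^2 + 1L) %/% 2L
      cheap$W[, center] <- cheap$W[, center] + fi$scale
      cheap$b <- cheap$b + fi$shift
    }
    fused$cheap <- cheap
  }
  block$fused <- fused
  block$mode <- "fused_inference"
  invisible(block)
}

#' @export
count_params.ghost_block <- function(model, ...) {
  if (model$mode == "fused_inference")
    as.integer(.n_params_layers(unname(model$fused)))
  else as.integer(.n_params_layers(list(model)))
}

#' Theoretical multiply-accumulate cost of ghost vs ordinary convolution
#'
#' Evaluates, at an `h x w` output resolution, the MAC count of an ordinary
#' convolution (`n * c * k^2 * h * w`) and of the ghost formulation
#' (`m * c * k^2 * h * w + (s - 1) * m * d^2 * h * w`). Biases and
#' normalization are excluded.
#'
#' @param cfg a [ghost_config()].
#' @param h,w output spatial size.
#' @return list with integer-valued `ordinary_macs` and `ghost_macs`.
#' @examples
#' theoretical_cost(ghost_config(16, 32, ratio = 2, primary_kernel = 1), 8, 8)
#' @export
theoretical_cost <- function(cfg, h, w) {
  stopifnot(inherits(cfg, "ghost_config"), h > 0, w > 0)
  n <- cfg$out_channels; c <- cfg$in_channels
  m <- cfg$intrinsic; s <- cfg$ratio
  k <- cfg$primary_kernel; d <- cfg$cheap_kernel
  list(ordinary_macs = n * c * k^2 * h * w,
       ghost_macs = m * c * k^2 * h * w + (s - 1) * m * d^2 * h * w)
}
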
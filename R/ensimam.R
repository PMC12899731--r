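#' @title Parameter-free three-branch attention for feature maps
#' @description
#' An attention mechanism in the SimAM family, extended for dense
#' small-object feature maps. Three parallel branches score every position
#' of a `C x H x W` feature map:
#'
#' * **global**: the closed-form SimAM energy. For a channel with mean
#'   `mu` and variance `sigma2`, the inverse energy of a neuron with value
#'   `t` is `1/e* = (t - mu)^2 / (4 (sigma2 + lambda)) + 1/2`, and the
#'   branch weight is `sigmoid(1/e*)`. Distinctive neurons (far from the
#'   channel mean) score high.
#' * **local**: the variance of the 3x3 neighborhood (fixed divisor 9),
#'   `sigmoid(alpha * sigma2_local)`, emphasizing fine local contrast.
#' * **edge**: the Sobel gradient magnitude `G = sqrt(Gx^2 + Gy^2)`
#'   computed per channel, `sigmoid(beta * G)`.
#'
#' The branches are fused with data-derived weights: per channel,
#' `w_global = ||X||_2 / (||X||_2 + eps)` and
#' `w_local = w_edge = (1 - w_global) / 2`, so the weights always sum to 1
#' and nothing is learned. The fused map modulates the input
#' multiplicatively (`X * A`), so the operation preserves shape and carries
#' zero learnable parameters.
#'
#' Feature maps are numeric arrays of dimension `c(C, H, W)` (a single
#' sample) or `c(N, C, H, W)` (a batch; samples are processed
#' independently).
#' @name ensimam
NULL

#' Configuration for the three-branch attention
#'
#' @param lambda_reg regularization constant of the global energy
#'   denominator (> 0). Default `1e-4`, the usual SimAM setting.
#' @param alpha_local scaling of the local-variance response (> 0).
#' @param beta_edge scaling of the edge response (> 0).
#' @param eps_fusion guard constant in the fusion weights (> 0).
#' @param variance_correction `"M_minus_1"` (sample variance, default,
#'   matching the reference SimAM implementation) or `"M"` (population).
#' @param padding_mode `"zero"` (default) or `"replicate"` border handling
#'   for the 3x3 pooling and Sobel windows.
#' @param fusion_norm `"l2"` (default; the literal channel L2 norm, which
#'   saturates `w_global` toward 1 for any non-tiny map) or `"rms"`
#'   (divides the norm by `sqrt(H*W)` first, avoiding the saturation).
#' @return an object of class `ensimam_config`.
#' @export
ensimam_config <- function(lambda_reg = 1e-4, alpha_local = 1.0,
                           beta_edge = 1.0, eps_fusion = 1e-4,
                           variance_correction = c("M_minus_1", "M"),
                           padding_mode = c("zero", "replicate"),
                           fusion_norm = c("l2", "rms")) {
  variance_correction <- match.arg(variance_correction)
  padding_mode <- match.arg(padding_mode)
  fusion_norm <- match.arg(fusion_norm)
  for (v in c(lambda_reg, alpha_local, beta_edge, eps_fusion))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("ensimam_config scalars must be finite and strictly positive")
  structure(list(lambda_reg = lambda_reg, alpha_local = alpha_local,
                 beta_edge = beta_edge, eps_fusion = eps_fusion,
                 variance_correction = variance_correction,
                 padding_mode = padding_mode, fusion_norm = fusion_norm),
            class = "ensimam_config")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.check_fmap <- function(x) {
  if (!is.array(x) || !(length(dim(x)) %in% c(3L, 4L)))
    stop("feature map must be an array of dim (C,H,W) or (N,C,H,W)")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  invisible(x)
}

# iterate a function over channels of a (C,H,W) array, f(matrix HxW) -> matrix
.per_channel <- function(x, f) {
  out <- x
  for (ci in seq_len(dim(x)[1L])) out[ci, , ] <- f(matrix(x[ci, , ], dim(x)[2L], dim(x)[3L]))
  out
}

# dispatch (N,C,H,W) batches onto the (C,H,W) implementation
.per_sample <- function(x, f) {
  if (length(dim(x)) == 3L) return(f(x))
  out <- x
  for (ni in seq_len(dim(x)[1L])) {
    xi <- array(x[ni, , , ], dim(x)[-1L])
    out[ni, , , ] <- f(xi)
  }
  out
}

#' Mean and variance of one channel
#'
#' @param channel a numeric matrix (one `H x W` channel).
#' @param correction `"M_minus_1"` (divisor `M - 1`, default) or `"M"`.
#' @return list with `mean` and `variance`.
#' @export
channel_stats <- function(channel, correction = c("M_minus_1", "M")) {
  correction <- match.arg(correction)
  if (length(channel) == 0L) stop("channel is empty")
  m <- length(channel)
  mu <- mean(channel)
  ss <- sum((channel - mu)^2)
  v <- if (correction == "M_minus_1") {
    if (m == 1L) stop("variance divisor M - 1 is degenerate for a single-element channel")
    ss / (m - 1)
  } else ss / m
  list(mean = mu, variance = v)
}

# pad a matrix by one pixel on each side
.pad1 <- function(m, mode) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  if (mode == "replicate") {
    p[1L, 2:(w + 1L)] <- m[1L, ]; p[h + 2L, 2:(w + 1L)] <- m[h, ]
    p[2:(h + 1L), 1L] <- m[, 1L]; p[2:(h + 1L), w + 2L] <- m[, w]
    p[1L, 1L] <- m[1L, 1L]; p[1L, w + 2L] <- m[1L, w]
    p[h + 2L, 1L] <- m[h, 1L]; p[h + 2L, w + 2L] <- m[h, w]
  }
  p
}

# 3x3 cross-correlation of a channel with a kernel, border per padding mode
.xcorr3 <- function(m, kern, mode) {
  h <- nrow(m); w <- ncol(m)
  p <- .pad1(m, mode)
  out <- matrix(0, h, w)
  for (di in -1:1) for (dj in -1:1) {
    kv <- kern[di + 2L, dj + 2L]
    if (kv != 0) out <- out + kv * p[(2:(h + 1L)) + di, (2:(w + 1L)) + dj, drop = FALSE]
  }
  out
}

#' Global (SimAM energy) attention branch
#'
#' Per channel, computes `sigmoid((t - mu)^2 / (4 (sigma2 + lambda)) + 1/2)`
#' at every position.
#'
#' @param x feature map array, `(C,H,W)` or `(N,C,H,W)`.
#' @param cfg an [ensimam_config()].
#' @return attention array of the same shape, all weights in (0, 1).
#' @export
global_attention <- function(x, cfg = ensimam_config()) {
  .check_fmap(x)
  .per_sample(x, function(xi) .per_channel(xi, function(ch) {
    st <- channel_stats(ch, cfg$variance_correction)
    .sigmoid((ch - st$mean)^2 / (4 * (st$variance + cfg$lambda_reg)) + 0.5)
  }))
}

#' Local-variance attention branch
#'
#' Computes the 3x3 neighborhood variance with the fixed divisor 9 (mean of
#' squares minus square of mean over the window), then
#' `sigmoid(alpha * sigma2_local)`. Borders are handled per the config's
#' padding mode. Constant regions receive weight `sigmoid(0) = 0.5`.
#'
#' @inheritParams global_attention
#' @return attention array of the same shape, weights in (0, 1).
#' @export
local_attention <- function(x, cfg = ensimam_config()) {
  .check_fmap(x)
  box <- matrix(1 / 9, 3L, 3L)
  .per_sample(x, function(xi) .per_channel(xi, function(ch) {
    mu <- .xcorr3(ch, box, cfg$padding_mode)
    musq <- .xcorr3(ch^2, box, cfg$padding_mode)
    v <- pmax(musq - mu^2, 0)
    .sigmoid(cfg$alpha_local * v)
  }))
}

# standard Sobel kernels (cross-correlation form)
.sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
.sobel_y <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L, byrow = TRUE)

#' Edge-response attention branch
#'
#' Per channel (no inter-channel mixing), cross-correlates with the Sobel
#' kernels, computes the gradient magnitude `G = sqrt(Gx^2 + Gy^2)` and
#' returns `sigmoid(beta * G)`: exactly 0.5 where `G = 0`, in (0.5, 1)
#' elsewhere.
#'
#' @inheritParams global_attention
#' @return attention array of the same shape.
#' @export
edge_attention <- function(x, cfg = ensimam_config()) {
  .check_fmap(x)
  .per_sample(x, function(xi) .per_channel(xi, function(ch) {
    gx <- .xcorr3(ch, .sobel_x, cfg$padding_mode)
    gy <- .xcorr3(ch, .sobel_y, cfg$padding_mode)
    .sigmoid(cfg$beta_edge * sqrt(gx^2 + gy^2))
  }))
}

#' Data-derived fusion weights
#'
#' Per channel, `w_global = n / (n + eps)` where `n` is the channel L2 norm
#' over spatial positions (or the RMS-normalized norm when
#' `cfg$fusion_norm == "rms"`), and `w_local = w_edge = (1 - w_global) / 2`.
#' The three weights always sum to 1.
#'
#' @inheritParams global_attention
#' @return for a `(C,H,W)` input, a list with numeric vectors `w_global`,
#'   `w_local`, `w_edge` of length `C`; for a batch, a list of such lists.
#' @export
fusion_weights <- function(x, cfg = ensimam_config()) {
  .check_fmap(x)
  one <- function(xi) {
    C <- dim(xi)[1L]
    wg <- numeric(C)
    for (ci in seq_len(C)) {
      n2 <- sqrt(sum(xi[ci, , ]^2))
      if (cfg$fusion_norm == "rms") n2 <- n2 / sqrt(prod(dim(xi)[2:3]))
      wg[ci] <- n2 / (n2 + cfg$eps_fusion)
    }
    list(w_global = wg, w_local = (1 - wg) / 2, w_edge = (1 - wg) / 2)
  }
  if (length(dim(x)) == 3L) return(one(x))
  lapply(seq_len(dim(x)[1L]), function(ni) one(array(x[ni, , , ], dim(x)[-1L])))
}

#' Fused attention map (the weights only)
#'
#' `A = w_g * A_global + w_l * A_local + w_e * A_edge`, with per-channel
#' fusion weights. All entries lie strictly in (0, 1).
#'
#' @inheritParams global_attention
#' @return attention array of the same shape as `x`.
#' @export
ensimam_weights <- function(x, cfg = ensimam_config()) {
  .check_fmap(x)
  .per_sample(x, function(xi) {
    ag <- global_attention(xi, cfg)
    al <- local_attention(xi, cfg)
    ae <- edge_attention(xi, cfg)
    if (!identical(dim(ag), dim(xi)) || !identical(dim(al), dim(xi)) ||
        !identical(dim(ae), dim(xi)))
      stop("internal error: attention branch shape mismatch")
    fw <- fusion_weights(xi, cfg)
    a <- xi
    for (ci in seq_len(dim(xi)[1L]))
      a[ci, , ] <- fw$w_global[ci] * ag[ci, , ] +
        fw$w_local[ci] * al[ci, , ] + fw$w_edge[ci] * ae[ci, , ]
    a
  })
}

#' Apply the three-branch attention to a feature map
#'
#' Returns `x * A` (elementwise modulation, the SimAM application
#' convention), preserving the input shape exactly. The operation has no
#' learnable parameters and is deterministic given `x` and `cfg`.
#'
#' @inheritParams global_attention
#' @return modulated feature map, same shape as `x`.
#' @examples
#' x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
#' y <- apply_ensimam(x)
#' stopifnot(identical(dim(y), dim(x)))
#' @export
apply_ensimam <- function(x, cfg = ensimam_config()) {
  .check_fmap(x)
  x * ensimam_weights(x, cfg)
}
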
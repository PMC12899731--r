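# Minimal neural-network engine used by the runnable compact detector.
#
# Activations flow through the network as "value" objects: a list with
# `maps` (one C x (H*W) matrix per sample, spatial positions flattened
# column-major), `h`, `w`, `c`. Layers are environments holding their
# parameters (`W`, `b`, `gamma`, `beta`, ...), accumulated gradients
# (`dW`, ...), batch-norm running statistics, and a cache for backward.
# The engine implements exactly what the compact detector needs: strided
# and grouped (depthwise) 2-D convolution via im2col + BLAS, batch
# normalization with running statistics, SiLU/sigmoid activations, the
# parameter-free attention site, branch sums and channel concatenation,
# and an Adam optimizer.

.val <- function(maps, c, h, w) list(maps = maps, c = c, h = h, w = w)

.val_from_array <- function(x) {
  # x: (C,H,W) or (N,C,H,W) array -> value object
  if (length(dim(x)) == 3L) x <- array(x, c(1L, dim(x)))
  d <- dim(x)
  # a (C,H,W) array flattened column-major is channel-fastest, so
  # matrix(., C, H*W) yields exactly the C x (H*W) map layout
  maps <- lapply(seq_len(d[1L]), function(n)
    matrix(array(x[n, , , ], d[-1L]), d[2L], d[3L] * d[4L]))
  .val(maps, d[2L], d[3L], d[4L])
}

.val_to_array <- function(v) {
  # value object -> (N,C,H,W) array
  n <- length(v$maps)
  out <- array(0, c(n, v$c, v$h, v$w))
  for (i in seq_len(n))
    out[i, , , ] <- array(v$maps[[i]], c(v$c, v$h, v$w))
  out
}

# spatial gather index for im2col: k2 x (Ho*Wo) matrix of positions into the
# zero-padded plane (hp x wp, column-major), kernel row offset fastest
.conv_index <- function(h, w, k, stride, pad) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  io <- rep(seq_len(ho), times = wo)
  jo <- rep(seq_len(wo), each = ho)
  base_r <- (io - 1L) * stride
  base_c <- (jo - 1L) * stride
  idx <- matrix(0L, k * k, ho * wo)
  o <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    o <- o + 1L
    idx[o, ] <- (base_r + di + 1L) + (base_c + dj) * hp
  }
  list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp)
}

.pad_map <- function(m, h, w, pad) {
  if (pad == 0L) return(m)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  p <- matrix(0, nrow(m), hp * wp)
  inside <- as.vector(outer((pad + 1L):(pad + h), (pad + (1:w) - 1L) * hp, "+"))
  p[, inside] <- m
  p
}

.unpad_grad <- function(dp, h, w, pad) {
  if (pad == 0L) return(dp)
  hp <- h + 2L * pad
  inside <- as.vector(outer((pad + 1L):(pad + h), (pad + (1:w) - 1L) * hp, "+"))
  dp[, inside, drop = FALSE]
}

# ---- layers ------------------------------------------------------------

nn_conv <- function(cin, cout, k = 3L, stride = 1L, groups = 1L,
                    bias = FALSE, init_gain = sqrt(2)) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$cin <- as.integer(cin); e$cout <- as.integer(cout)
  e$k <- as.integer(k); e$stride <- as.integer(stride)
  e$groups <- as.integer(groups); e$pad <- as.integer(k %/% 2L)
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop("channels must be divisible by groups")
  fan_in <- (cin / groups) * k * k
  # weight matrix: cout x (cin/groups * k^2), input channel fastest
  e$W <- matrix(stats::rnorm(cout * fan_in, sd = init_gain / sqrt(fan_in)),
                cout, fan_in)
  e$b <- if (bias) numeric(cout) else NULL
  e$param_names <- c("W", if (bias) "b")
  e
}

.conv_forward <- function(e, v, train) {
  # the gather index depends only on the input size; cache it on the layer
  if (is.null(e$ci_cache) || e$ci_cache_h != v$h || e$ci_cache_w != v$w) {
    e$ci_cache <- .conv_index(v$h, v$w, e$k, e$stride, e$pad)
    e$ci_cache_h <- v$h; e$ci_cache_w <- v$w
  }
  ci <- e$ci_cache
  k2 <- e$k^2
  cpg_in <- e$cin %/% e$groups; cpg_out <- e$cout %/% e$groups
  maps <- vector("list", length(v$maps))
  cache_cols <- if (train) vector("list", length(v$maps))
  for (n in seq_along(v$maps)) {
    p <- .pad_map(v$maps[[n]], v$h, v$w, e$pad)
    y <- matrix(0, e$cout, ncol(ci$idx))
    cols_g <- if (train) vector("list", e$groups)
    for (g in seq_len(e$groups)) {
      rows_in <- ((g - 1L) * cpg_in + 1L):(g * cpg_in)
      rows_out <- ((g - 1L) * cpg_out + 1L):(g * cpg_out)
      xg <- p[rows_in, , drop = FALSE]
      xcol <- xg[, as.vector(ci$idx), drop = FALSE]       # cpg_in x (k2*Npos)
      dim(xcol) <- c(cpg_in * k2, ncol(ci$idx))           # channel fastest? no:
      # xg[, vec(idx)] lays out k2 blocks of Npos columns? vec(idx) is
      # column-major over (k2, Npos): offset fastest -> columns grouped by
      # position, offset varying fastest. After dim<-, rows are
      # (cpg_in, k2) with channel fastest, matching the weight layout.
      y[rows_out, ] <- e$W[rows_out, , drop = FALSE] %*% xcol
      if (train) cols_g[[g]] <- xcol
    }
    if (!is.null(e$b)) y <- y + e$b
    maps[[n]] <- y
    if (train) cache_cols[[n]] <- cols_g
  }
  if (train) {
    e$cache <- list(cols = cache_cols, ci = ci, h = v$h, w = v$w)
  }
  .val(maps, e$cout, ci$ho, ci$wo)
}

.conv_backward <- function(e, dv) {
  ca <- e$cache
  ci <- ca$ci
  k2 <- e$k^2
  cpg_in <- e$cin %/% e$groups; cpg_out <- e$cout %/% e$groups
  if (is.null(e$dW)) e$dW <- matrix(0, nrow(e$W), ncol(e$W))
  if (!is.null(e$b) && is.null(e$db)) e$db <- numeric(e$cout)
  dmaps <- vector("list", length(dv$maps))
  npos <- ncol(ci$idx)
  for (n in seq_along(dv$maps)) {
    dy <- dv$maps[[n]]
    dp <- matrix(0, e$cin, ci$hp * ci$wp)
    for (g in seq_len(e$groups)) {
      rows_in <- ((g - 1L) * cpg_in + 1L):(g * cpg_in)
      rows_out <- ((g - 1L) * cpg_out + 1L):(g * cpg_out)
      dyg <- dy[rows_out, , drop = FALSE]
      xcol <- ca$cols[[n]][[g]]
      e$dW[rows_out, ] <- e$dW[rows_out, , drop = FALSE] +
        tcrossprod(dyg, xcol)
      dxcol <- crossprod(e$W[rows_out, , drop = FALSE], dyg) # (cpg_in*k2) x Npos
      dim(dxcol) <- c(cpg_in, k2, npos)
      for (o in seq_len(k2)) {
        cols <- ci$idx[o, ]
        dp[rows_in, cols] <- dp[rows_in, cols, drop = FALSE] + dxcol[, o, ]
      }
    }
    if (!is.null(e$b)) e$db <- e$db + rowSums(dy)
    dmaps[[n]] <- .unpad_grad(dp, ca$h, ca$w, e$pad)
  }
  .val(dmaps, e$cin, ca$h, ca$w)
}

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"; e$c <- as.integer(c)
  e$gamma <- rep(1, c); e$beta <- numeric(c)
  e$running_mean <- numeric(c); e$running_var <- rep(1, c)
  e$eps <- eps; e$momentum <- momentum
  e$param_names <- c("gamma", "beta")
  e
}

.bn_forward <- function(e, v, train) {
  xcat <- do.call(cbind, v$maps)
  if (train) {
    ntot <- ncol(xcat)
    mu <- rowMeans(xcat)
    varp <- rowMeans(xcat^2) - mu^2
    varp <- pmax(varp, 0)
    e$running_mean <- (1 - e$momentum) * e$running_mean + e$momentum * mu
    var_unb <- if (ntot > 1L) varp * ntot / (ntot - 1L) else varp
    e$running_var <- (1 - e$momentum) * e$running_var + e$momentum * var_unb
  } else {
    mu <- e$running_mean
    varp <- e$running_var
  }
  sd <- sqrt(varp + e$eps)
  maps <- lapply(v$maps, function(m) ((m - mu) / sd) * e$gamma + e$beta)
  if (train) e$cache <- list(mu = mu, sd = sd, maps_in = v$maps)
  .val(maps, v$c, v$h, v$w)
}

.bn_backward <- function(e, dv) {
  ca <- e$cache
  if (is.null(e$dgamma)) { e$dgamma <- numeric(e$c); e$dbeta <- numeric(e$c) }
  xhat_all <- lapply(seq_along(ca$maps_in),
                     function(n) (ca$maps_in[[n]] - ca$mu) / ca$sd)
  dy_cat <- do.call(cbind, dv$maps)
  xhat_cat <- do.call(cbind, xhat_all)
  ntot <- ncol(dy_cat)
  e$dgamma <- e$dgamma + rowSums(dy_cat * xhat_cat)
  e$dbeta <- e$dbeta + rowSums(dy_cat)
  mean_dy <- rowMeans(dy_cat)
  mean_dyxhat <- rowMeans(dy_cat * xhat_cat)
  dmaps <- lapply(seq_along(dv$maps), function(n) {
    (e$gamma / ca$sd) *
      (dv$maps[[n]] - mean_dy - xhat_all[[n]] * mean_dyxhat)
  })
  .val(dmaps, dv$c, dv$h, dv$w)
}

nn_act <- function(kind = c("silu", "sigmoid")) {
  e <- new.env(parent = emptyenv())
  e$type <- "act"; e$kind <- match.arg(kind)
  e$param_names <- character()
  e
}

.act_forward <- function(e, v, train) {
  maps <- lapply(v$maps, function(m) {
    s <- 1 / (1 + exp(-m))
    if (e$kind == "silu") m * s else s
  })
  if (train) e$cache <- v$maps
  .val(maps, v$c, v$h, v$w)
}

.act_backward <- function(e, dv) {
  dmaps <- lapply(seq_along(dv$maps), function(n) {
    x <- e$cache[[n]]
    s <- 1 / (1 + exp(-x))
    d <- if (e$kind == "silu") s * (1 + x * (1 - s)) else s * (1 - s)
    dv$maps[[n]] * d
  })
  .val(dmaps, dv$c, dv$h, dv$w)
}

# parameter-free attention site: y = x * A(x); A is treated as a constant
# in backward (the modulation gradient path only)
nn_attention <- function(cfg = ensimam_config()) {
  e <- new.env(parent = emptyenv())
  e$type <- "attention"; e$cfg <- cfg
  e$param_names <- character()
  e
}

.attention_forward <- function(e, v, train) {
  amaps <- lapply(v$maps, function(m) {
    a <- ensimam_weights(array(m, c(v$c, v$h, v$w)), e$cfg)
    matrix(a, v$c, v$h * v$w)
  })
  if (train) e$cache <- amaps
  .val(lapply(seq_along(v$maps), function(n) v$maps[[n]] * amaps[[n]]),
       v$c, v$h, v$w)
}

.attention_backward <- function(e, dv) {
  .val(lapply(seq_along(dv$maps), function(n) dv$maps[[n]] * e$cache[[n]]),
       dv$c, dv$h, dv$w)
}

# ---- dispatch ----------------------------------------------------------

layer_forward <- function(e, v, train = FALSE) {
  switch(e$type,
         conv = .conv_forward(e, v, train),
         bn = .bn_forward(e, v, train),
         act = .act_forward(e, v, train),
         attention = .attention_forward(e, v, train),
         ghost = .ghost_forward_block(e, v, train),
         stop("unknown layer type: ", e$type))
}

layer_backward <- function(e, dv) {
  switch(e$type,
         conv = .conv_backward(e, dv),
         bn = .bn_backward(e, dv),
         act = .act_backward(e, dv),
         attention = .attention_backward(e, dv),
         ghost = .ghost_backward_block(e, dv),
         stop("unknown layer type: ", e$type))
}

# all layers of a layer tree (ghost blocks contain sub-layers)
.flatten_layers <- function(layers) {
  out <- list()
  for (e in layers) {
    if (e$type == "ghost") out <- c(out, .flatten_layers(e$sub))
    else out <- c(out, list(e))
  }
  out
}

.n_params_layers <- function(layers) {
  sum(vapply(.flatten_layers(layers), function(e)
    sum(vapply(e$param_names, function(nm) length(e[[nm]]), numeric(1L))),
    numeric(1L)))
}

.zero_grads <- function(layers) {
  for (e in .flatten_layers(layers))
    for (nm in e$param_names) e[[paste0("d", nm)]] <- NULL
  invisible(NULL)
}

# finite check + collection of all gradients (diagnostics and tests)
.collect_grads <- function(layers) {
  g <- list()
  for (e in .flatten_layers(layers))
    for (nm in e$param_names) {
      dn <- paste0("d", nm)
      if (!is.null(e[[dn]])) g[[length(g) + 1L]] <- e[[dn]]
    }
  g
}

# ---- Adam --------------------------------------------------------------

adam_state <- function(layers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  list(layers = .flatten_layers(layers), lr = lr, beta1 = beta1,
       beta2 = beta2, eps = eps, t = 0L)
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (e in opt$layers) {
    for (nm in e$param_names) {
      dn <- paste0("d", nm)
      g <- e[[dn]]
      if (is.null(g)) next
      mn <- paste0("adam_m_", nm); vn <- paste0("adam_v_", nm)
      if (is.null(e[[mn]])) { e[[mn]] <- g * 0; e[[vn]] <- g * 0 }
      e[[mn]] <- opt$beta1 * e[[mn]] + (1 - opt$beta1) * g
      e[[vn]] <- opt$beta2 * e[[vn]] + (1 - opt$beta2) * g^2
      e[[nm]] <- e[[nm]] - opt$lr * (e[[mn]] / bc1) /
        (sqrt(e[[vn]] / bc2) + opt$eps)
    }
  }
  opt
}
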
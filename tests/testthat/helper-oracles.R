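# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package internals: scalar loops and
# shift-and-add convolution instead of im2col + GEMM, pmax pooling, explicit
# index-grid bilinear interpolation.

# scalar-loop channel attention (one value at a time)
oracle_channel_attention <- function(x, state) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- if (length(d) == 4) d[4] else 1
  x4 <- array(x, c(H, W, C, N))
  wsum <- sum(state$scale)
  y <- array(0, c(H, W, C, N))
  for (n in 1:N) for (c in 1:C) for (i in 1:H) for (j in 1:W) {
    xv <- x4[i, j, c, n]
    xhat <- (xv - state$mean[c]) / sqrt(state$variance[c] + state$epsilon)
    wc <- state$scale[c] / wsum
    z <- if (isTRUE(state$nam_style)) wc * (state$scale[c] * xhat + state$shift[c])
         else wc * state$scale[c] * xhat + state$shift[c]
    y[i, j, c, n] <- xv / (1 + exp(-z))
  }
  if (length(d) == 3) array(y, d) else y
}

# direct sliding-window spatial attention
oracle_spatial_attention <- function(x, state) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- if (length(d) == 4) d[4] else 1
  x4 <- array(x, c(H, W, C, N))
  y <- array(0, c(H, W, C, N))
  for (n in 1:N) {
    A <- apply(x4[, , , n, drop = FALSE], c(1, 2), mean)
    M <- apply(x4[, , , n, drop = FALSE], c(1, 2), max)
    planes <- list(A, M)
    for (i in 1:H) for (j in 1:W) {
      acc <- state$bias
      for (ki in -3:3) for (kj in -3:3) {
        ii <- i + ki; jj <- j + kj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          for (p in 1:2)
            acc <- acc + planes[[p]][ii, jj] * state$kernel[ki + 4, kj + 4, p, 1]
      }
      g <- 1 / (1 + exp(-acc))
      y[i, j, , n] <- x4[i, j, , n] * g
    }
  }
  if (length(d) == 3) array(y, d) else y
}

# per-pixel confusion counting with explicit loops
oracle_confusion <- function(pred, truth, C) {
  tp <- fp <- fn <- rep(0, C + 1)
  for (i in seq_along(pred)) {
    p <- pred[i]; t <- truth[i]
    if (p == t) tp[p + 1] <- tp[p + 1] + 1
    else {
      fp[p + 1] <- fp[p + 1] + 1
      fn[t + 1] <- fn[t + 1] + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# shift-and-add convolution (valid for any stride/pad), independent of im2col
ref_conv <- function(x, w, b = NULL, stride = 1, pad = 0) {
  d <- dim(x); wd <- dim(w)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  kh <- wd[1]; kw <- wd[2]; Cout <- wd[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, Cin, N))
  xp[pad + 1:H, pad + 1:W, , ] <- x
  y <- array(0, c(Ho, Wo, Cout, N))
  rows <- function(ki) seq(ki, by = stride, length.out = Ho)
  cols <- function(kj) seq(kj, by = stride, length.out = Wo)
  for (co in 1:Cout) {
    acc <- array(if (is.null(b)) 0 else b[co], c(Ho, Wo, N))
    for (ci in 1:Cin) for (ki in 1:kh) for (kj in 1:kw) {
      wv <- w[ki, kj, ci, co]
      if (wv != 0)
        acc <- acc + wv * array(xp[rows(ki), cols(kj), ci, ], c(Ho, Wo, N))
    }
    y[, , co, ] <- acc
  }
  y
}

ref_bn <- function(x, g, b, mean, var, eps = 1e-5) {
  d <- dim(x)
  for (c in seq_len(d[3]))
    x[, , c, ] <- g[c] * (x[, , c, ] - mean[c]) / sqrt(var[c] + eps) + b[c]
  x
}

ref_relu <- function(x) pmax(x, 0)

ref_maxpool2 <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  pmax(x[io, jo, , , drop = FALSE], x[io + 1, jo, , , drop = FALSE],
       x[io, jo + 1, , , drop = FALSE], x[io + 1, jo + 1, , , drop = FALSE])
}

ref_up2 <- function(x) {
  d <- dim(x)
  coeff <- function(Hi) {
    s <- pmin(pmax((seq_len(2 * Hi) - 0.5) / 2 - 0.5, 0), Hi - 1)
    i0 <- floor(s)
    list(i0 = i0 + 1, i1 = pmin(i0 + 1, Hi - 1) + 1, t = s - i0)
  }
  rc <- coeff(d[1]); cc <- coeff(d[2])
  tmat <- array(rep(rc$t, times = 2 * d[2]), c(2 * d[1], 2 * d[2]))
  umat <- array(rep(cc$t, each = 2 * d[1]), c(2 * d[1], 2 * d[2]))
  y <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  for (c in seq_len(d[3])) for (n in seq_len(d[4])) {
    x00 <- x[rc$i0, cc$i0, c, n]; x10 <- x[rc$i1, cc$i0, c, n]
    x01 <- x[rc$i0, cc$i1, c, n]; x11 <- x[rc$i1, cc$i1, c, n]
    y[, , c, n] <- (1 - tmat) * (1 - umat) * x00 + tmat * (1 - umat) * x10 +
      (1 - tmat) * umat * x01 + tmat * umat * x11
  }
  y
}

# reference forward pass of the toggles-off residual U-Net, computed with the
# primitives above directly from a model's parameter and buffer lists
ref_model_forward <- function(model, x) {
  cfg <- model$config
  stopifnot(!cfg$use_channel_attention, !cfg$use_spatial_bridge,
            cfg$upsample_mode == "bilinear")
  P <- model$params; B <- model$buffers
  cbr <- function(x, pre, stride, pad, act = TRUE) {
    h <- ref_conv(x, P[[paste0(pre, ".conv.w")]], stride = stride, pad = pad)
    h <- ref_bn(h, P[[paste0(pre, ".bn.g")]], P[[paste0(pre, ".bn.b")]],
                B[[paste0(pre, ".bn.mean")]], B[[paste0(pre, ".bn.var")]])
    if (act) ref_relu(h) else h
  }
  bn_named <- function(x, pre)
    ref_bn(x, P[[paste0(pre, ".g")]], P[[paste0(pre, ".b")]],
           B[[paste0(pre, ".mean")]], B[[paste0(pre, ".var")]])
  block <- function(x, pre, stride, has_proj) {
    b <- ref_relu(bn_named(ref_conv(x, P[[paste0(pre, ".conv1.w")]]), paste0(pre, ".bn1")))
    b <- ref_relu(bn_named(ref_conv(b, P[[paste0(pre, ".conv2.w")]], stride = stride, pad = 1),
                           paste0(pre, ".bn2")))
    b <- bn_named(ref_conv(b, P[[paste0(pre, ".conv3.w")]]), paste0(pre, ".bn3"))
    sc <- if (has_proj) cbr(x, paste0(pre, ".down"), stride, 0, act = FALSE) else x
    ref_relu(sc + b)
  }
  bw <- cfg$base_width
  planes <- bw * c(1, 2, 4, 8); outw <- planes * 4
  strides <- c(1, 2, 2, 2)
  s0 <- cbr(x, "stem", 2, 1)
  h <- ref_maxpool2(s0)
  skips <- list(s0)
  cin <- bw
  for (s in 1:4) {
    for (b in seq_len(cfg$stage_blocks[s])) {
      pre <- sprintf("stage%d.block%d", s, b)
      stride <- if (b == 1) strides[s] else 1
      has_proj <- b == 1 && (cin != outw[s] || strides[s] > 1)
      h <- block(h, pre, stride, has_proj)
      cin <- outw[s]
    }
    if (s < 4) skips[[s + 1]] <- h
  }
  for (i in 1:4) {
    pre <- sprintf("dec%d", i)
    u <- cbr(ref_up2(h), paste0(pre, ".up"), 1, 1)
    skip <- skips[[5 - i]]
    dcat <- array(0, c(dim(u)[1], dim(u)[2], dim(u)[3] + dim(skip)[3], dim(u)[4]))
    dcat[, , seq_len(dim(u)[3]), ] <- u
    dcat[, , dim(u)[3] + seq_len(dim(skip)[3]), ] <- skip
    h <- cbr(dcat, paste0(pre, ".conv1"), 1, 1)
    h <- cbr(h, paste0(pre, ".conv2"), 1, 1)
  }
  h <- cbr(ref_up2(h), "final.up", 1, 1)
  ref_conv(h, P[["head.w"]], b = P[["head.b"]])
}

# small fully-specified synthetic config for fast tests
tiny_synth_config <- function(n_images, seed = 0, image_size = 32,
                              include_prob = c(0.9, 0.5, 0.6, 0.12)) {
  synthetic_config(
    n_images = n_images, image_size = image_size,
    include_prob = include_prob,
    instances_range = rbind(c(1, 1), c(1, 2), c(1, 2), c(1, 3)),
    radius_range = rbind(c(5, 8), c(2, 4), c(3, 5), c(1, 2)),
    class_intensity = c(0.55, 0.75, 0.4, 0.9),
    seed = seed)
}

tiny_net_config <- function(...) {
  network_config(num_foreground_classes = 4, stage_blocks = c(1, 1, 1, 1),
                 base_width = 4, ...)
}
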
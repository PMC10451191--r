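# Minimal reverse-mode tape over dense arrays.
#
# A node is an environment holding `value`, an accumulated `grad`, its parent
# nodes and a backward closure. The tape (`ctx`) records creation order, so
# backpropagation is a single reverse sweep. Gradients flow only into nodes
# that carry a backward closure or are marked as parameters, which keeps the
# inference path free of bookkeeping.

ag_ctx <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ag_node <- function(ctx, value, parents = list(), backward = NULL,
                    requires_grad = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$requires_grad <- requires_grad
  ctx$n <- ctx$n + 1L
  if (ctx$n > length(ctx$nodes)) length(ctx$nodes) <- 2L * length(ctx$nodes)
  ctx$nodes[[ctx$n]] <- nd
  nd
}

ag_leaf <- function(ctx, value, requires_grad = TRUE)
  ag_node(ctx, value, requires_grad = requires_grad)

ag_accum <- function(nd, g) {
  if (is.null(nd$backward) && !nd$requires_grad) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# seed the output node with `grad` and sweep the tape in reverse
ag_backward <- function(ctx, out, grad) {
  out$grad <- grad
  for (i in seq.int(ctx$n, 1L)) {
    nd <- ctx$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- elementwise ops --------------------------------------------------------

ag_relu <- function(ctx, x) {
  v <- cpp_relu_fwd(x$value)
  ag_node(ctx, v, list(x), function(nd)
    ag_accum(x, cpp_relu_bwd(nd$grad, v)))
}

ag_sigmoid <- function(ctx, x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(ctx, s, list(x), function(nd) ag_accum(x, nd$grad * s * (1 - s)))
}

ag_add <- function(ctx, x, y)
  ag_node(ctx, x$value + y$value, list(x, y), function(nd) {
    ag_accum(x, nd$grad)
    ag_accum(y, nd$grad)
  })

ag_mul <- function(ctx, x, y)
  ag_node(ctx, x$value * y$value, list(x, y), function(nd) {
    ag_accum(x, nd$grad * y$value)
    ag_accum(y, nd$grad * x$value)
  })

# ---- structural ops ---------------------------------------------------------

ag_concat_c <- function(ctx, x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  v <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  v[, , seq_len(dx[3]), ] <- x$value
  v[, , dx[3] + seq_len(dy[3]), ] <- y$value
  ag_node(ctx, v, list(x, y), function(nd) {
    ag_accum(x, nd$grad[, , seq_len(dx[3]), , drop = FALSE])
    ag_accum(y, nd$grad[, , dx[3] + seq_len(dy[3]), , drop = FALSE])
  })
}

# ---- compiled kernels -------------------------------------------------------

ag_conv2d <- function(ctx, x, w, b = NULL, stride = 1L, pad = 0L) {
  bv <- if (is.null(b)) numeric(0) else b$value
  fw <- cpp_conv2d_fwd_cache(x$value, w$value, bv, as.integer(stride),
                             as.integer(pad))
  xd <- dim(x$value)
  want_dx <- !is.null(x$backward) || x$requires_grad
  ag_node(ctx, fw$y, c(list(x, w), if (!is.null(b)) list(b)), function(nd) {
    r <- cpp_conv2d_bwd_cache(fw$col, w$value, nd$grad, xd, as.integer(stride),
                              as.integer(pad), !is.null(b), want_dx)
    if (want_dx) ag_accum(x, r$dx)
    ag_accum(w, r$dw)
    if (!is.null(b)) ag_accum(b, r$db)
  })
}

ag_convt2 <- function(ctx, x, w) {
  v <- cpp_convt2_fwd(x$value, w$value)
  ag_node(ctx, v, list(x, w), function(nd) {
    r <- cpp_convt2_bwd(x$value, w$value, nd$grad)
    ag_accum(x, r$dx)
    ag_accum(w, r$dw)
  })
}

ag_maxpool2 <- function(ctx, x) {
  r <- cpp_maxpool2_fwd(x$value)
  xd <- dim(x$value)
  ag_node(ctx, r$y, list(x), function(nd)
    ag_accum(x, cpp_maxpool2_bwd(nd$grad, r$idx, xd)))
}

ag_up2 <- function(ctx, x) {
  xd <- dim(x$value)
  ag_node(ctx, cpp_up2_fwd(x$value), list(x), function(nd)
    ag_accum(x, cpp_up2_bwd(nd$grad, xd)))
}

# ---- per-channel helpers ----------------------------------------------------

# sum / mean over (H, W, N) for each channel
ch_sum <- function(x) {
  d <- dim(x)
  m <- colSums(matrix(x, d[1] * d[2]))
  dim(m) <- c(d[3], d[4])
  rowSums(m)
}
ch_mean <- function(x) ch_sum(x) / (dim(x)[1] * dim(x)[2] * dim(x)[4])

# broadcast a length-C vector over an (H, W, C, N) array
bc_ch <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

# ---- batch normalization ----------------------------------------------------

# `buf` is an environment holding running statistics under `<key>.mean` /
# `<key>.var`; they are updated in place when training.
bn_batch_stats <- function(xv, buf, key, M, momentum) {
  mu <- cpp_ch_sum(xv) / M
  va <- cpp_ch_dot(xv, xv) / M - mu^2
  va[va < 0] <- 0
  if (M > 1) {
    buf[[paste0(key, ".mean")]] <- (1 - momentum) * buf[[paste0(key, ".mean")]] + momentum * mu
    buf[[paste0(key, ".var")]] <- (1 - momentum) * buf[[paste0(key, ".var")]] +
      momentum * va * M / (M - 1)
  }
  list(mu = mu, va = va)
}

ag_bn <- function(ctx, x, gamma, beta, buf, key, training,
                  eps = 1e-5, momentum = 0.1) {
  d <- dim(x$value)
  M <- d[1] * d[2] * d[4]
  C <- d[3]
  if (training) {
    st <- bn_batch_stats(x$value, buf, key, M, momentum)
    mu <- st$mu; va <- st$va
  } else {
    mu <- buf[[paste0(key, ".mean")]]
    va <- buf[[paste0(key, ".var")]]
  }
  istd <- 1 / sqrt(va + eps)
  fw <- cpp_bn_fwd(x$value, mu, istd, gamma$value, beta$value)
  ag_node(ctx, fw$y, list(x, gamma, beta), function(nd) {
    r <- cpp_bn_bwd(nd$grad, fw$xhat, gamma$value, istd, training)
    ag_accum(gamma, r$dgamma)
    ag_accum(beta, r$dbeta)
    ag_accum(x, r$dx)
  })
}

# ---- normalized channel attention gate --------------------------------------

# gate_c = sigmoid(W_c * alpha_c * xhat + beta_c) with W_c = alpha_c / sum(alpha)
# (nam_style scales the shift as well: sigmoid(W_c * (alpha_c * xhat + beta_c)));
# output = input (*) gate. Batch statistics during training, running averages
# at inference.
ag_ca <- function(ctx, x, alpha, beta, buf, key, training,
                  eps = 1e-5, momentum = 0.1, nam_style = FALSE) {
  d <- dim(x$value)
  M <- d[1] * d[2] * d[4]
  C <- d[3]
  if (training) {
    st <- bn_batch_stats(x$value, buf, key, M, momentum)
    mu <- st$mu; va <- st$va
  } else {
    mu <- buf[[paste0(key, ".mean")]]
    va <- buf[[paste0(key, ".var")]]
  }
  a <- alpha$value
  S <- sum(a)
  if (abs(S) < 1e-12)
    wa_stop_data("channel attention: the scale factors sum to zero; the normalized channel weights are undefined")
  istd <- 1 / sqrt(va + eps)
  slope <- a^2 / S
  shift <- if (nam_style) (a / S) * beta$value else beta$value
  fw <- cpp_ca_fwd(x$value, mu, istd, slope, shift)
  ag_node(ctx, fw$y, list(x, alpha, beta), function(nd) {
    r <- cpp_ca_bwd(nd$grad, x$value, fw$xhat, fw$gate, slope, istd, training)
    ag_accum(x, r$dx)
    dslope <- r$dslope
    dshift <- r$dshift
    dalpha <- 2 * a * dslope / S - sum(dslope * a^2) / S^2
    if (nam_style) {
      dalpha <- dalpha + dshift * beta$value / S - sum(dshift * a * beta$value) / S^2
      ag_accum(beta, dshift * a / S)
    } else {
      ag_accum(beta, dshift)
    }
    ag_accum(alpha, dalpha)
  })
}

# ---- spatial attention gate -------------------------------------------------

# map = sigmoid(conv7x7([channel-mean; channel-max]) + bias), broadcast over
# channels; output = input (*) map.
ag_sa <- function(ctx, x, kernel, bias) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- aperm(x$value, c(1, 2, 4, 3))    # (H, W, N, C)
  m <- matrix(xp, ncol = C)
  A <- rowMeans(m)
  amax <- max.col(m, ties.method = "first")
  Mx <- m[cbind(seq_len(nrow(m)), amax)]
  st <- array(0, c(H, W, 2L, N))
  st[, , 1L, ] <- array(A, c(H, W, N))
  st[, , 2L, ] <- array(Mx, c(H, W, N))
  u <- cpp_conv2d_fwd(st, kernel$value, bias$value, 1L, 3L)
  map <- 1 / (1 + exp(-u))               # (H, W, 1, N)
  map3 <- array(map, c(H, W, N))
  mf <- aperm(array(map3, c(H, W, N, C)), c(1, 2, 4, 3))
  v <- x$value * mf
  dim(v) <- d
  ag_node(ctx, v, list(x, kernel, bias), function(nd) {
    G <- nd$grad
    gp <- aperm(G * x$value, c(1, 2, 4, 3))
    dmap3 <- rowSums(matrix(gp, ncol = C))              # over channels, (H*W*N)
    du <- dmap3 * as.vector(map3) * (1 - as.vector(map3))
    du <- array(du, c(H, W, 1L, N))
    r <- cpp_conv2d_bwd(st, kernel$value, du, 1L, 3L, TRUE)
    ag_accum(kernel, r$dw)
    ag_accum(bias, r$db)
    dst <- r$dx
    dA <- as.vector(dst[, , 1L, ])
    dM <- as.vector(dst[, , 2L, ])
    dx <- G * mf
    # mean plane spreads 1/C to every channel; max plane goes to the argmax
    dAf <- aperm(array(array(dA / C, c(H, W, N)), c(H, W, N, C)), c(1, 2, 4, 3))
    dx <- dx + dAf
    r0 <- seq_len(H * W * N) - 1L
    hh <- r0 %% H
    ww <- (r0 %/% H) %% W
    nn <- r0 %/% (H * W)
    lin <- hh + H * (ww + W * ((amax - 1L) + C * nn)) + 1L
    add <- numeric(length(dx))
    add[lin] <- dM
    dx <- dx + array(add, d)
    ag_accum(x, dx)
  })
}
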
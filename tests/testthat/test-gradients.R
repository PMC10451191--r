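# Finite-difference checks of the backward pass, layer by layer and end to end.

ns <- asNamespace("waresunet")

fd_grad <- function(f, z, eps = 1e-6) {
  g <- z * 0
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    g[i] <- (f(zp) - f(zm)) / (2 * eps)
  }
  g
}

mkbuf <- function(C) list2env(list(k.mean = rep(0, C), k.var = rep(1, C)),
                              parent = emptyenv())

test_that("batch normalization gradients match finite differences", {
  set.seed(31)
  x <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  gm <- runif(3, 0.5, 1.5); bt <- rnorm(3)
  gy <- array(rnorm(length(x)), dim(x))
  run <- function(x, gm, bt) {
    ctx <- ns$ag_ctx()
    xn <- ns$ag_leaf(ctx, x); g <- ns$ag_leaf(ctx, gm); b <- ns$ag_leaf(ctx, bt)
    out <- ns$ag_bn(ctx, xn, g, b, mkbuf(3), "k", training = TRUE)
    list(ctx = ctx, out = out, xn = xn, g = g, b = b)
  }
  r <- run(x, gm, bt)
  ns$ag_backward(r$ctx, r$out, gy)
  expect_equal(r$xn$grad, fd_grad(function(z) sum(run(z, gm, bt)$out$value * gy), x),
               tolerance = 1e-5)
  expect_equal(r$g$grad, fd_grad(function(z) sum(run(x, z, bt)$out$value * gy), gm),
               tolerance = 1e-5)
  expect_equal(r$b$grad, fd_grad(function(z) sum(run(x, gm, z)$out$value * gy), bt),
               tolerance = 1e-5)
})

test_that("channel-gate gradients match finite differences in all four variants", {
  set.seed(32)
  x <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  al <- runif(3, 0.5, 1.5); be <- rnorm(3)
  gy <- array(rnorm(length(x)), dim(x))
  run <- function(x, al, be, tr, nam) {
    ctx <- ns$ag_ctx()
    xn <- ns$ag_leaf(ctx, x); a <- ns$ag_leaf(ctx, al); b <- ns$ag_leaf(ctx, be)
    out <- ns$ag_ca(ctx, xn, a, b, mkbuf(3), "k", tr, nam_style = nam)
    list(ctx = ctx, out = out, xn = xn, a = a, b = b)
  }
  for (nam in c(FALSE, TRUE)) for (tr in c(TRUE, FALSE)) {
    r <- run(x, al, be, tr, nam)
    ns$ag_backward(r$ctx, r$out, gy)
    expect_equal(r$xn$grad,
                 fd_grad(function(z) sum(run(z, al, be, tr, nam)$out$value * gy), x),
                 tolerance = 1e-5)
    expect_equal(r$a$grad,
                 fd_grad(function(z) sum(run(x, z, be, tr, nam)$out$value * gy), al),
                 tolerance = 1e-5)
    expect_equal(r$b$grad,
                 fd_grad(function(z) sum(run(x, al, z, tr, nam)$out$value * gy), be),
                 tolerance = 1e-5)
  }
})

test_that("spatial-gate gradients match finite differences", {
  set.seed(33)
  x <- array(rnorm(7 * 6 * 3 * 2), c(7, 6, 3, 2))
  k <- array(rnorm(7 * 7 * 2, sd = 0.2), c(7, 7, 2, 1)); bs <- 0.1
  gy <- array(rnorm(length(x)), dim(x))
  run <- function(x, k, bs) {
    ctx <- ns$ag_ctx()
    xn <- ns$ag_leaf(ctx, x); kn <- ns$ag_leaf(ctx, k); bn <- ns$ag_leaf(ctx, bs)
    out <- ns$ag_sa(ctx, xn, kn, bn)
    list(ctx = ctx, out = out, xn = xn, kn = kn, bn = bn)
  }
  r <- run(x, k, bs)
  ns$ag_backward(r$ctx, r$out, gy)
  expect_equal(r$xn$grad, fd_grad(function(z) sum(run(z, k, bs)$out$value * gy), x),
               tolerance = 1e-5)
  expect_equal(r$kn$grad, fd_grad(function(z) sum(run(x, z, bs)$out$value * gy), k),
               tolerance = 1e-5)
  expect_equal(as.numeric(r$bn$grad),
               as.numeric(fd_grad(function(z) sum(run(x, k, z)$out$value * gy), bs)),
               tolerance = 1e-5)
})

test_that("the end-to-end training gradient matches finite differences", {
  set.seed(34)
  m <- build_model(tiny_net_config(), seed = 3)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  y <- array(sample(0:4, 32 * 32 * 2, replace = TRUE), c(32, 32, 2))
  wfull <- c(1, 2, 1.5, 1, 3)
  loss_at <- function(params) {
    mm <- m; mm$params <- params
    buf <- list2env(mm$buffers, parent = emptyenv())
    run <- ns$net_apply(mm, x, buf, training = TRUE)
    ns$wce_core(run$out$value, y, wfull)$loss
  }
  buf <- list2env(m$buffers, parent = emptyenv())
  run <- ns$net_apply(m, x, buf, training = TRUE)
  lg <- ns$wce_core(run$out$value, y, wfull, want_grad = TRUE)
  ns$ag_backward(run$ctx, run$out, lg$grad)
  # probe a handful of parameters spread across the network
  probe <- c("stem.conv.w", "stage2.block1.conv2.w", "stage4.block1.ca.alpha",
             "dec2.sa.kernel", "dec4.conv1.bn.g", "head.b")
  for (nm in probe) {
    p <- m$params[[nm]]
    i <- sample(seq_along(p), 1)
    eps <- 1e-5
    p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
    fd <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    # loose tolerance: pooling/channel-max argmax switches make the loss only
    # piecewise smooth, so deep finite differences carry a few percent noise
    expect_equal(run$P[[nm]]$grad[i], fd, tolerance = 0.05,
                 label = sprintf("analytic gradient of %s[%d]", nm, i))
  }
})
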
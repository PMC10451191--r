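# Channel and spatial attention gates against scalar-loop oracles.

test_that("normalized channel weights divide by the scale sum", {
  expect_equal(normalized_channel_weights(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(normalized_channel_weights(c(1, 3)), c(0.25, 0.75))
  set.seed(1)
  for (i in 1:100) {
    v <- runif(sample(2:16, 1), 0.01, 5)
    w <- normalized_channel_weights(v)
    manual <- vapply(seq_along(v), function(k) v[k] / sum(v), numeric(1))
    expect_equal(w, manual, tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  expect_error(normalized_channel_weights(c(1, -1)), "degenerate", class = "wa_data_error")
})

test_that("channel attention reduces to x * sigmoid(x) for a unit single-channel state", {
  eps <- 1e-5
  st <- channel_attention_state(scale = 1, shift = 0, mean = 0, variance = 1 - eps,
                                epsilon = eps)
  x <- array(rnorm(7 * 5), c(7, 5, 1))
  expect_equal(channel_attention(x, st), x / (1 + exp(-x)), tolerance = 1e-12)
})

test_that("a saturating shift opens the channel gate completely", {
  st <- channel_attention_state(scale = c(1, 2), shift = c(1e4, 1e4))
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  expect_equal(channel_attention(x, st), x, tolerance = 1e-8)
})

test_that("channel attention matches a scalar triple-loop oracle", {
  set.seed(3)
  for (i in 1:50) {
    nam <- i %% 2 == 0
    st <- channel_attention_state(scale = runif(3, 0.2, 2), shift = rnorm(3),
                                  mean = rnorm(3), variance = runif(3, 0.1, 2),
                                  nam_style = nam)
    x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    expect_equal(channel_attention(x, st), oracle_channel_attention(x, st),
                 tolerance = 1e-6)
    # batched input gives the identical per-sample result
    xb <- array(c(x, x + 1), c(4, 4, 3, 2))
    yb <- channel_attention(xb, st)
    expect_equal(yb[, , , 1], channel_attention(x, st), tolerance = 1e-12)
    expect_equal(yb[, , , 2], channel_attention(x + 1, st), tolerance = 1e-12)
  }
})

test_that("channel gate maps zeros to zeros and shrinks magnitudes", {
  st <- channel_attention_state(scale = c(0.5, 1.5), shift = c(0.3, -0.2))
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  x[1:4, , ] <- 0
  y <- channel_attention(x, st)
  expect_true(all(y[1:4, , ] == 0))
  nz <- x != 0
  expect_true(all(abs(y[nz]) < abs(x[nz])))  # gate strictly inside (0, 1)
})

test_that("channel attention validates the channel count", {
  st <- channel_attention_state(scale = c(1, 1))
  expect_error(channel_attention(array(0, c(2, 2, 3)), st), "channel",
               class = "wa_config_error")
})

test_that("a zero spatial kernel gives a uniform 0.5 gate", {
  st <- spatial_attention_state(array(0, c(7, 7, 2, 1)), bias = 0)
  x <- array(rnorm(9 * 9 * 4), c(9, 9, 4))
  expect_equal(spatial_attention(x, st), 0.5 * x, tolerance = 1e-12)
  expect_true(all(spatial_attention_map(x, st) == 0.5))
})

test_that("for single-channel input the mean and max planes coincide", {
  set.seed(4)
  k <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1))
  x <- array(rnorm(8 * 8 * 1), c(8, 8, 1))
  st <- spatial_attention_state(k, bias = 0.2)
  # collapsing the two planes onto one kernel plane must give the same map
  k2 <- k
  k2[, , 1, 1] <- k[, , 1, 1] + k[, , 2, 1]
  k2[, , 2, 1] <- 0
  st2 <- spatial_attention_state(k2, bias = 0.2)
  expect_equal(spatial_attention(x, st), spatial_attention(x, st2), tolerance = 1e-12)
})

test_that("spatial attention matches a direct sliding-window oracle", {
  set.seed(5)
  for (i in 1:50) {
    st <- spatial_attention_state(array(rnorm(7 * 7 * 2, sd = 0.3), c(7, 7, 2, 1)),
                                  bias = rnorm(1))
    x <- array(rnorm(9 * 9 * 4), c(9, 9, 4))
    expect_equal(spatial_attention(x, st), oracle_spatial_attention(x, st),
                 tolerance = 1e-6)
  }
  # batched equals unbatched
  st <- spatial_attention_state(array(rnorm(7 * 7 * 2, sd = 0.3), c(7, 7, 2, 1)), 0.1)
  x1 <- array(rnorm(9 * 9 * 3), c(9, 9, 3))
  x2 <- array(rnorm(9 * 9 * 3), c(9, 9, 3))
  xb <- array(c(x1, x2), c(9, 9, 3, 2))
  yb <- spatial_attention(xb, st)
  expect_equal(yb[, , , 1], spatial_attention(x1, st), tolerance = 1e-12)
  expect_equal(yb[, , , 2], spatial_attention(x2, st), tolerance = 1e-12)
})

test_that("both gates preserve shape and stay strictly inside (0, 1)", {
  set.seed(6)
  x <- array(rnorm(8 * 8 * 3, sd = 2), c(8, 8, 3))
  ca <- channel_attention_state(scale = runif(3, 0.1, 2), shift = rnorm(3))
  sa <- spatial_attention_state(array(rnorm(7 * 7 * 2), c(7, 7, 2, 1)), 0)
  for (y in list(channel_attention(x, ca), spatial_attention(x, sa))) {
    expect_identical(dim(y), dim(x))
    nz <- x != 0
    expect_true(all(abs(y[nz]) < abs(x[nz])))
    expect_true(all(sign(y[nz]) == sign(x[nz])))
  }
  m <- spatial_attention_map(x, sa)
  expect_true(all(m > 0 & m < 1))
})
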
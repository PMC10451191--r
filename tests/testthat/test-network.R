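# Architecture assembly, ablation toggles, determinism, block-level contracts.

test_that("the default configuration carries 16 channel gates and 4 spatial bridges", {
  m <- build_model(network_config(base_width = 8), seed = 0)
  expect_equal(sum(grepl("\\.ca\\.alpha$", names(m$params))), 16)  # 3+4+6+3 blocks
  expect_equal(sum(grepl("\\.sa\\.kernel$", names(m$params))), 4)
})

test_that("disabling both attention toggles removes all attention parameters", {
  m <- build_model(network_config(base_width = 8, use_channel_attention = FALSE,
                                  use_spatial_bridge = FALSE), seed = 0)
  expect_false(any(grepl("\\.(ca|sa)\\.", names(m$params))))
})

test_that("rebuilding from the same (config, seed) is bit-identical", {
  cfg <- tiny_net_config()
  m1 <- build_model(cfg, seed = 7)
  m2 <- build_model(cfg, seed = 7)
  expect_identical(serialize(m1$params, NULL), serialize(m2$params, NULL))
  m3 <- build_model(cfg, seed = 8)
  expect_false(identical(m1$params, m3$params))
  # parameter count is a pure function of the configuration
  expect_equal(count_parameters(m1), count_parameters(m3))
})

test_that("invalid configurations are rejected with all offenders listed", {
  err <- tryCatch(network_config(base_width = 2, stage_blocks = c(1, 1, 1),
                                 num_foreground_classes = 0),
                  condition = function(e) conditionMessage(e))
  expect_match(err, "base_width")
  expect_match(err, "stage_blocks")
  expect_match(err, "num_foreground_classes")
})

test_that("a zero-weight attention-free block with identity shortcut is a plain activation", {
  blk <- make_ca_res_block(in_channels = 8, planes = 2, stride = 1,
                           use_channel_attention = FALSE, seed = 1)
  for (nm in grep("conv", names(blk$params), value = TRUE))
    blk$params[[nm]][] <- 0
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  expect_equal(ca_res_block_forward(x, blk), pmax(x, 0), tolerance = 1e-12)
})

test_that("enabling the gate changes the output exactly by gating the branch", {
  set.seed(21)
  blk_off <- make_ca_res_block(in_channels = 8, planes = 2, stride = 1,
                               use_channel_attention = FALSE, seed = 3)
  blk_on <- make_ca_res_block(in_channels = 8, planes = 2, stride = 1,
                              use_channel_attention = TRUE, seed = 3)
  # same convolution/normalization parameters in both blocks
  for (nm in names(blk_off$params)) blk_on$params[[nm]] <- blk_off$params[[nm]]
  # keep every pre-activation positive so the final relu is the identity:
  # small branch scales, strongly positive input
  for (nm in grep("bn3\\.g", names(blk_on$params), value = TRUE)) {
    blk_on$params[[nm]][] <- 0.05
    blk_off$params[[nm]][] <- 0.05
  }
  x <- array(runif(6 * 6 * 8, 1, 2), c(6, 6, 8))
  y_off <- ca_res_block_forward(x, blk_off)
  y_on <- ca_res_block_forward(x, blk_on)
  branch <- y_off - x                      # identity shortcut, relu inactive
  st <- channel_attention_state(scale = blk_on$params[["blk.ca.alpha"]],
                                shift = blk_on$params[["blk.ca.beta"]],
                                mean = blk_on$buffers[["blk.ca.mean"]],
                                variance = blk_on$buffers[["blk.ca.var"]])
  expect_equal(y_on - x, channel_attention(branch, st), tolerance = 1e-9)
})

test_that("a stride-2 block halves spatial extents and widens channels", {
  blk <- make_ca_res_block(in_channels = 4, planes = 4, stride = 2, seed = 0)
  y <- ca_res_block_forward(array(rnorm(16 * 16 * 4), c(16, 16, 4)), blk)
  expect_identical(dim(y), c(8L, 8L, 16L))
})

test_that("the spatial bridge equals the attention module and disables to identity", {
  x <- array(rnorm(12 * 12 * 6), c(12, 12, 6))
  br <- make_sa_bridge(seed = 2)
  expect_identical(sa_bridge_forward(x, br), spatial_attention(x, br$state))
  off <- make_sa_bridge(enabled = FALSE)
  expect_identical(sa_bridge_forward(x, off), x)
  zero <- make_sa_bridge(kernel = array(0, c(7, 7, 2, 1)), bias = 0)
  expect_equal(sa_bridge_forward(x, zero), 0.5 * x, tolerance = 1e-12)
})

test_that("the forward pass obeys the shape contract and rejects bad sizes", {
  m <- build_model(tiny_net_config(), seed = 0)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  s <- model_forward(x, m)
  expect_identical(dim(s), c(64L, 64L, 5L, 2L))
  expect_true(all(is.finite(s)))
  expect_error(model_forward(array(0, c(48, 48, 1, 1)), m), "divisible by 32",
               class = "wa_data_error")
})

test_that("inference is reproducible and the ablation lattice runs", {
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  for (ca in c(FALSE, TRUE)) for (sa in c(FALSE, TRUE)) {
    m <- build_model(tiny_net_config(use_channel_attention = ca,
                                     use_spatial_bridge = sa), seed = 1)
    s1 <- model_forward(x, m)
    s2 <- model_forward(x, m)
    expect_identical(s1, s2)
    expect_identical(dim(s1), c(32L, 32L, 5L, 1L))
  }
})

test_that("saturating every gate reproduces the attention-free network", {
  m_on <- build_model(tiny_net_config(), seed = 4)
  m_off <- build_model(tiny_net_config(use_channel_attention = FALSE,
                                       use_spatial_bridge = FALSE), seed = 4)
  # share the non-attention parameters, then saturate the gates open
  for (nm in names(m_off$params)) m_on$params[[nm]] <- m_off$params[[nm]]
  for (nm in grep("\\.ca\\.beta$", names(m_on$params), value = TRUE))
    m_on$params[[nm]][] <- 60
  for (nm in grep("\\.sa\\.bias$", names(m_on$params), value = TRUE))
    m_on$params[[nm]][] <- 60
  for (nm in grep("\\.sa\\.kernel$", names(m_on$params), value = TRUE))
    m_on$params[[nm]][] <- 0
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  expect_equal(model_forward(x, m_on), model_forward(x, m_off), tolerance = 1e-5)
})

test_that("the transposed-convolution decoder variant builds and runs", {
  m <- build_model(tiny_net_config(upsample_mode = "transposed_conv"), seed = 0)
  s <- model_forward(array(runif(32 * 32), c(32, 32, 1, 1)), m)
  expect_identical(dim(s), c(32L, 32L, 5L, 1L))
})

test_that("predicted labels argmax the scores with low-label tie-breaking", {
  m <- build_model(tiny_net_config(), seed = 2)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  pred <- predict_masks(x, m)
  sc <- model_forward(x, m)
  manual <- apply(sc, c(1, 2, 4), function(v) which.max(v) - 1L)
  expect_identical(unname(pred), unname(manual))
  expect_true(all(pred %in% 0:4))
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(tiny_net_config(), seed = 11)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$buffers, m$buffers)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(model_forward(x, m), model_forward(x, m2))
})
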
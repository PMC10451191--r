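# Weighted attention residual U-Net.
#
# Encoder: a 3x3 stride-2 stem convolution, 2x2 max pooling, then four stages
# of bottleneck residual blocks (ResNet50-style widths and strides 1,2,2,2;
# block counts 3,4,6,3 by default). Each block's residual branch is gated by a
# normalized channel-attention module after the third convolution (before the
# shortcut addition, so the shortcut is never gated). Decoder: four up-steps
# (bilinear 2x + 3x3 convolution by default, transposed convolution optional)
# each concatenating the spatial-attention-bridged encoder skip, followed by
# two 3x3 conv+norm+activation layers; a final up-step restores the input
# resolution and a 1x1 projection emits C+1 score planes (background
# explicit). Total downsampling is x32, so input sides must be multiples
# of 32.

#' Network configuration
#'
#' @param in_channels input image channels (default 1, grayscale).
#' @param num_foreground_classes number of foreground classes C (output has
#'   C+1 score planes).
#' @param stage_blocks integer vector of 4 block counts (default 3,4,6,3).
#' @param base_width stem width (default 64; reduce for desk-scale runs).
#' @param use_channel_attention enable the channel-attention gate in every
#'   residual block.
#' @param use_spatial_bridge enable the spatial-attention bridge on every skip.
#' @param upsample_mode `"bilinear"` (default) or `"transposed_conv"`.
#' @param nam_style if `TRUE` the channel gate scales its shift by the
#'   normalized channel weight as well.
#' @return an object of class `wa_net_config`.
#' @export
network_config <- function(in_channels = 1L, num_foreground_classes = 4L,
                           stage_blocks = c(3L, 4L, 6L, 3L), base_width = 64L,
                           use_channel_attention = TRUE,
                           use_spatial_bridge = TRUE,
                           upsample_mode = c("bilinear", "transposed_conv"),
                           nam_style = FALSE) {
  upsample_mode <- match.arg(upsample_mode)
  cfg <- list(in_channels = as.integer(in_channels),
              num_foreground_classes = as.integer(num_foreground_classes),
              stage_blocks = as.integer(stage_blocks),
              base_width = as.integer(base_width),
              use_channel_attention = isTRUE(use_channel_attention),
              use_spatial_bridge = isTRUE(use_spatial_bridge),
              upsample_mode = upsample_mode,
              nam_style = isTRUE(nam_style))
  validate_config(cfg)
  structure(cfg, class = "wa_net_config")
}

validate_config <- function(cfg) {
  bad <- character(0)
  if (cfg$in_channels < 1) bad <- c(bad, "in_channels must be >= 1")
  if (cfg$num_foreground_classes < 1) bad <- c(bad, "num_foreground_classes must be >= 1")
  if (length(cfg$stage_blocks) != 4 || any(cfg$stage_blocks < 1))
    bad <- c(bad, "stage_blocks must be 4 integers, all >= 1")
  if (cfg$base_width < 4) bad <- c(bad, "base_width must be >= 4")
  if (!cfg$upsample_mode %in% c("bilinear", "transposed_conv"))
    bad <- c(bad, "upsample_mode must be 'bilinear' or 'transposed_conv'")
  if (length(bad))
    wa_stop_config(paste0("invalid network configuration:\n",
                          paste("  -", bad, collapse = "\n")))
  invisible(cfg)
}

net_widths <- function(cfg) {
  bw <- cfg$base_width
  planes <- bw * c(1L, 2L, 4L, 8L)
  outw <- planes * 4L
  list(planes = planes, outw = outw,
       skipw = c(bw, outw[1:3]),   # stem, stage1..3 outputs
       strides = c(1L, 2L, 2L, 2L))
}

# ---- parameter initialization ------------------------------------------------

init_conv_w <- function(kh, kw, cin, cout, gain = 2) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(gain / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

init_store <- function() new.env(parent = emptyenv())

add_bn <- function(st, pre, c) {
  st$params[[paste0(pre, ".g")]] <- rep(1, c)
  st$params[[paste0(pre, ".b")]] <- rep(0, c)
  st$buffers[[paste0(pre, ".mean")]] <- rep(0, c)
  st$buffers[[paste0(pre, ".var")]] <- rep(1, c)
}

add_conv_bn <- function(st, pre, kh, kw, cin, cout) {
  st$params[[paste0(pre, ".conv.w")]] <- init_conv_w(kh, kw, cin, cout)
  add_bn(st, paste0(pre, ".bn"), cout)
}

add_block <- function(st, pre, cin, planes, outw, has_proj, cfg) {
  st$params[[paste0(pre, ".conv1.w")]] <- init_conv_w(1, 1, cin, planes)
  add_bn(st, paste0(pre, ".bn1"), planes)
  st$params[[paste0(pre, ".conv2.w")]] <- init_conv_w(3, 3, planes, planes)
  add_bn(st, paste0(pre, ".bn2"), planes)
  st$params[[paste0(pre, ".conv3.w")]] <- init_conv_w(1, 1, planes, outw)
  add_bn(st, paste0(pre, ".bn3"), outw)
  if (cfg$use_channel_attention) {
    st$params[[paste0(pre, ".ca.alpha")]] <- rep(1, outw)
    st$params[[paste0(pre, ".ca.beta")]] <- rep(0, outw)
    st$buffers[[paste0(pre, ".ca.mean")]] <- rep(0, outw)
    st$buffers[[paste0(pre, ".ca.var")]] <- rep(1, outw)
  }
  if (has_proj) add_conv_bn(st, paste0(pre, ".down"), 1, 1, cin, outw)
}

add_up <- function(st, pre, cin, cout, cfg) {
  if (cfg$upsample_mode == "bilinear")
    add_conv_bn(st, paste0(pre, ".up"), 3, 3, cin, cout)
  else
    add_conv_bn(st, paste0(pre, ".up"), 2, 2, cin, cout)
}

#' Build a model from a configuration and a seed
#'
#' Parameter initialization (He-normal convolutions, unit normalization
#' scales) is drawn from a private Mersenne-Twister stream, so rebuilding from
#' the same `(config, seed)` is bit-identical.
#'
#' @param config a [network_config()].
#' @param seed integer seed.
#' @return an object of class `wa_model` with `config`, `seed`, `params`
#'   (named list of arrays) and `buffers` (running normalization statistics).
#' @export
build_model <- function(config, seed = 0L) {
  validate_config(config)
  w <- net_widths(config)
  C1 <- config$num_foreground_classes + 1L
  st <- init_store()
  st$params <- list()
  st$buffers <- list()
  with_seed(seed, {
    add_conv_bn(st, "stem", 3, 3, config$in_channels, config$base_width)
    cin <- config$base_width
    for (s in 1:4) {
      for (b in seq_len(config$stage_blocks[s])) {
        pre <- sprintf("stage%d.block%d", s, b)
        has_proj <- b == 1L && (cin != w$outw[s] || w$strides[s] > 1L)
        add_block(st, pre, cin, w$planes[s], w$outw[s], has_proj, config)
        cin <- w$outw[s]
      }
    }
    dec_in <- w$outw[4]
    for (i in 1:4) {
      skipw <- w$skipw[5 - i]           # s3, s2, s1, s0
      pre <- sprintf("dec%d", i)
      add_up(st, pre, dec_in, skipw, config)
      if (config$use_spatial_bridge) {
        st$params[[paste0(pre, ".sa.kernel")]] <- init_conv_w(7, 7, 2, 1)
        st$params[[paste0(pre, ".sa.bias")]] <- 0
      }
      add_conv_bn(st, paste0(pre, ".conv1"), 3, 3, 2L * skipw, skipw)
      add_conv_bn(st, paste0(pre, ".conv2"), 3, 3, skipw, skipw)
      dec_in <- skipw
    }
    add_up(st, "final", dec_in, config$base_width, config)
    st$params[["head.w"]] <- init_conv_w(1, 1, config$base_width, C1, gain = 1)
    st$params[["head.b"]] <- rep(0, C1)
  })
  structure(list(config = config, seed = as.integer(seed),
                 params = st$params, buffers = st$buffers),
            class = "wa_model")
}

#' Number of learnable parameters
#'
#' @param model a `wa_model`.
#' @return total parameter count (a pure function of the configuration).
#' @export
count_parameters <- function(model)
  sum(vapply(model$params, length, numeric(1)))

# ---- forward pass ------------------------------------------------------------

conv_bn_act <- function(ctx, x, P, buf, pre, stride, pad, training, act = TRUE) {
  h <- ag_conv2d(ctx, x, P[[paste0(pre, ".conv.w")]], NULL, stride, pad)
  h <- ag_bn(ctx, h, P[[paste0(pre, ".bn.g")]], P[[paste0(pre, ".bn.b")]],
             buf, paste0(pre, ".bn"), training)
  if (act) ag_relu(ctx, h) else h
}

block_node <- function(ctx, x, P, buf, pre, stride, has_proj, training, cfg) {
  b <- ag_conv2d(ctx, x, P[[paste0(pre, ".conv1.w")]], NULL, 1L, 0L)
  b <- ag_bn(ctx, b, P[[paste0(pre, ".bn1.g")]], P[[paste0(pre, ".bn1.b")]],
             buf, paste0(pre, ".bn1"), training)
  b <- ag_relu(ctx, b)
  b <- ag_conv2d(ctx, b, P[[paste0(pre, ".conv2.w")]], NULL, stride, 1L)
  b <- ag_bn(ctx, b, P[[paste0(pre, ".bn2.g")]], P[[paste0(pre, ".bn2.b")]],
             buf, paste0(pre, ".bn2"), training)
  b <- ag_relu(ctx, b)
  b <- ag_conv2d(ctx, b, P[[paste0(pre, ".conv3.w")]], NULL, 1L, 0L)
  b <- ag_bn(ctx, b, P[[paste0(pre, ".bn3.g")]], P[[paste0(pre, ".bn3.b")]],
             buf, paste0(pre, ".bn3"), training)
  if (cfg$use_channel_attention)
    b <- ag_ca(ctx, b, P[[paste0(pre, ".ca.alpha")]], P[[paste0(pre, ".ca.beta")]],
               buf, paste0(pre, ".ca"), training, nam_style = cfg$nam_style)
  sc <- if (has_proj)
    conv_bn_act(ctx, x, P, buf, paste0(pre, ".down"), stride, 0L, training, act = FALSE)
  else x
  ag_relu(ctx, ag_add(ctx, sc, b))
}

up_node <- function(ctx, x, P, buf, pre, training, cfg) {
  if (cfg$upsample_mode == "bilinear") {
    u <- ag_up2(ctx, x)
    conv_bn_act(ctx, u, P, buf, paste0(pre, ".up"), 1L, 1L, training)
  } else {
    u <- ag_convt2(ctx, x, P[[paste0(pre, ".up.conv.w")]])
    u <- ag_bn(ctx, u, P[[paste0(pre, ".up.bn.g")]], P[[paste0(pre, ".up.bn.b")]],
               buf, paste0(pre, ".up.bn"), training)
    ag_relu(ctx, u)
  }
}

net_forward <- function(ctx, x, P, buf, cfg, training) {
  w <- net_widths(cfg)
  s0 <- conv_bn_act(ctx, x, P, buf, "stem", 2L, 1L, training)   # H/2, bw
  h <- ag_maxpool2(ctx, s0)                                      # H/4
  skips <- vector("list", 4)
  skips[[1]] <- s0
  cin <- cfg$base_width
  for (s in 1:4) {
    for (b in seq_len(cfg$stage_blocks[s])) {
      pre <- sprintf("stage%d.block%d", s, b)
      stride <- if (b == 1L) w$strides[s] else 1L
      has_proj <- b == 1L && (cin != w$outw[s] || w$strides[s] > 1L)
      h <- block_node(ctx, h, P, buf, pre, stride, has_proj, training, cfg)
      cin <- w$outw[s]
    }
    if (s < 4) skips[[s + 1]] <- h
  }
  for (i in 1:4) {
    pre <- sprintf("dec%d", i)
    u <- up_node(ctx, h, P, buf, pre, training, cfg)
    skip <- skips[[5 - i]]
    br <- if (cfg$use_spatial_bridge)
      ag_sa(ctx, skip, P[[paste0(pre, ".sa.kernel")]], P[[paste0(pre, ".sa.bias")]])
    else skip
    h <- ag_concat_c(ctx, u, br)
    h <- conv_bn_act(ctx, h, P, buf, paste0(pre, ".conv1"), 1L, 1L, training)
    h <- conv_bn_act(ctx, h, P, buf, paste0(pre, ".conv2"), 1L, 1L, training)
  }
  h <- up_node(ctx, h, P, buf, "final", training, cfg)
  ag_conv2d(ctx, h, P[["head.w"]], P[["head.b"]], 1L, 0L)
}

# coerce user input into an (H, W, Cin, N) batch
as_image_batch <- function(images, in_channels = 1L) {
  if (is.list(images) && !is.null(images[[1]]$image)) {
    d <- dim(images[[1]]$image)
    x <- array(0, c(d[1], d[2], in_channels, length(images)))
    for (i in seq_along(images)) x[, , 1, i] <- images[[i]]$image
    return(x)
  }
  x <- images
  d <- dim(x)
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) {
    # (H, W, N) stack of single-channel images
    dim(x) <- c(d[1], d[2], 1L, d[3])
  } else if (length(d) != 4) stop("images must be a 2-4D array or a dataset list")
  x
}

# internal: build the tape once; returns nodes for training use
net_apply <- function(model, x, buf, training) {
  ctx <- ag_ctx()
  P <- lapply(model$params, function(p) ag_leaf(ctx, p, requires_grad = training))
  xn <- ag_leaf(ctx, x, requires_grad = FALSE)
  out <- net_forward(ctx, xn, P, buf, model$config, training)
  list(ctx = ctx, out = out, P = P)
}

#' Forward pass: per-pixel class scores
#'
#' Runs the network in inference mode (running normalization statistics,
#' deterministic for a fixed model). Input sides must be divisible by 32.
#'
#' @param images an `(H, W, N)` or `(H, W, 1, N)` array of intensities in
#'   \[0,1\], a single `(H, W)` matrix, or a dataset list.
#' @param model a `wa_model`.
#' @return scores array of dim `c(H, W, C + 1, N)`.
#' @export
model_forward <- function(images, model) {
  x <- as_image_batch(images, model$config$in_channels)
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    wa_stop_data(sprintf(
      "input size %dx%d is not divisible by 32; resize or zero-pad the images to a multiple of 32",
      d[1], d[2]))
  buf <- list2env(model$buffers, parent = emptyenv())
  net_apply(model, x, buf, training = FALSE)$out$value
}

#' Predict label masks
#'
#' Argmax over the C+1 score planes; ties break toward the lower label index.
#'
#' @inheritParams model_forward
#' @param batch_size images per forward pass.
#' @return integer array `(H, W, N)` of labels `0..C`.
#' @export
predict_masks <- function(images, model, batch_size = 8L) {
  x <- as_image_batch(images, model$config$in_channels)
  d <- dim(x)
  N <- d[4]
  out <- array(0L, c(d[1], d[2], N))
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    sc <- model_forward(x[, , , idx, drop = FALSE], model)
    K <- dim(sc)[3]
    m <- matrix(aperm(sc, c(1, 2, 4, 3)), ncol = K)
    lab <- max.col(m, ties.method = "first") - 1L
    out[, , idx] <- array(lab, c(d[1], d[2], length(idx)))
  }
  out
}

# ---- standalone block-level transforms --------------------------------------

#' Construct a standalone channel-attention residual block
#'
#' @param in_channels input width.
#' @param planes bottleneck width (output width is `4 * planes`).
#' @param stride stride of the 3x3 convolution (1 or 2).
#' @param use_channel_attention enable the gate.
#' @param nam_style gate shift scaling variant.
#' @param seed seed for parameter initialization.
#' @return a list with `params`, `buffers` and the block settings.
#' @export
make_ca_res_block <- function(in_channels, planes, stride = 1L,
                              use_channel_attention = TRUE, nam_style = FALSE,
                              seed = 0L) {
  outw <- 4L * planes
  has_proj <- (in_channels != outw) || stride > 1L
  st <- init_store()
  st$params <- list()
  st$buffers <- list()
  cfg <- list(use_channel_attention = use_channel_attention, nam_style = nam_style)
  with_seed(seed, add_block(st, "blk", in_channels, planes, outw, has_proj, cfg))
  list(params = st$params, buffers = st$buffers, stride = as.integer(stride),
       has_proj = has_proj, use_channel_attention = use_channel_attention,
       nam_style = nam_style)
}

#' Forward pass of a single channel-attention residual block
#'
#' `act(shortcut(x) + gate(branch(x)))` with the gate applied to the residual
#' branch after its third convolution; inference-mode normalization (running
#' statistics).
#'
#' @param f_in feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param block a block from [make_ca_res_block()].
#' @return output feature map.
#' @export
ca_res_block_forward <- function(f_in, block) {
  x <- as_feature_map(f_in)
  ctx <- ag_ctx()
  P <- lapply(block$params, function(p) ag_leaf(ctx, p, requires_grad = FALSE))
  buf <- list2env(block$buffers, parent = emptyenv())
  cfg <- list(use_channel_attention = block$use_channel_attention,
              nam_style = block$nam_style)
  out <- block_node(ctx, ag_leaf(ctx, x, FALSE), P, buf, "blk",
                    block$stride, block$has_proj, FALSE, cfg)
  restore_dims(out$value, f_in)
}

#' Construct a spatial-attention skip bridge
#'
#' @param enabled if `FALSE` the bridge passes features through unchanged.
#' @param seed seed for kernel initialization.
#' @param kernel,bias optional explicit 7x7x2x1 kernel and bias.
#' @return a list with the bridge `state` and `enabled` flag.
#' @export
make_sa_bridge <- function(enabled = TRUE, seed = 0L, kernel = NULL, bias = 0) {
  if (is.null(kernel)) kernel <- with_seed(seed, init_conv_w(7, 7, 2, 1))
  list(state = spatial_attention_state(kernel, bias), enabled = isTRUE(enabled))
}

#' Forward pass of the spatial-attention bridge
#'
#' Applies [spatial_attention()] to an encoder skip feature (the caller
#' concatenates the result with the upsampled decoder feature); a disabled
#' bridge is the identity.
#'
#' @param skip_feature feature map.
#' @param bridge a bridge from [make_sa_bridge()].
#' @return bridged feature map.
#' @export
sa_bridge_forward <- function(skip_feature, bridge) {
  if (!bridge$enabled) return(skip_feature)
  spatial_attention(skip_feature, bridge$state)
}

# ---- checkpoints -------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, seed, parameters and normalization
#' buffers; loading validates the configuration.
#'
#' @param model a `wa_model`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), seed = model$seed,
               params = model$params, buffers = model$buffers,
               version = as.character(utils::packageVersion("waresunet"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the restored `wa_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) wa_stop_data(sprintf("checkpoint '%s' not found", path))
  ck <- readRDS(path)
  cfg <- structure(ck$config, class = "wa_net_config")
  validate_config(cfg)
  structure(list(config = cfg, seed = ck$seed, params = ck$params,
                 buffers = ck$buffers), class = "wa_model")
}
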
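#' Normalized channel weights from scale factors
#'
#' Converts per-channel scale factors into normalized channel weights
#' `W_c = alpha_c / sum(alpha)`. The weights sum to one; negative scale
#' factors are permitted as long as the sum is nonzero.
#'
#' @param scale numeric vector of per-channel scale factors.
#' @return numeric vector of the same length summing to 1.
#' @export
#' @examples
#' normalized_channel_weights(c(1, 3)) # 0.25 0.75
normalized_channel_weights <- function(scale) {
  if (!is.numeric(scale) || length(scale) == 0)
    wa_stop_config("`scale` must be a non-empty numeric vector")
  S <- sum(scale)
  if (abs(S) < 1e-12)
    wa_stop_data("degenerate scale factors: sum(scale) = 0, normalized channel weights are undefined")
  scale / S
}

#' Channel attention state
#'
#' Bundles the parameters of the normalized channel-attention gate: the
#' per-channel scale `alpha`, shift `beta`, and the normalization statistics
#' (`mean`, `variance`) used to standardize the input before gating.
#'
#' @param scale per-channel scale factors (alpha).
#' @param shift per-channel shifts (beta).
#' @param mean per-channel means used for normalization.
#' @param variance per-channel variances (non-negative).
#' @param epsilon small positive stabilizer added to the variance.
#' @param nam_style if `TRUE`, the shift is scaled by the normalized channel
#'   weight as well (`sigmoid(W_c (alpha_c xhat + beta_c))`); the default
#'   applies the shift unscaled (`sigmoid(W_c alpha_c xhat + beta_c)`).
#' @return an object of class `wa_ca_state`.
#' @export
channel_attention_state <- function(scale, shift = rep(0, length(scale)),
                                    mean = rep(0, length(scale)),
                                    variance = rep(1, length(scale)),
                                    epsilon = 1e-5, nam_style = FALSE) {
  n <- length(scale)
  if (length(shift) != n || length(mean) != n || length(variance) != n)
    wa_stop_config("scale, shift, mean and variance must have one entry per channel")
  if (any(variance < 0)) wa_stop_config("variances must be non-negative")
  if (epsilon <= 0) wa_stop_config("epsilon must be positive")
  structure(list(scale = as.numeric(scale), shift = as.numeric(shift),
                 mean = as.numeric(mean), variance = as.numeric(variance),
                 epsilon = epsilon, nam_style = isTRUE(nam_style)),
            class = "wa_ca_state")
}

#' Apply the normalized channel-attention gate
#'
#' Standardizes each channel with the state's mean/variance, forms the gate
#' `sigmoid(W_c * alpha_c * xhat + beta_c)` with `W_c = alpha_c / sum(alpha)`,
#' and multiplies the input elementwise by the gate. Gate values lie strictly
#' in (0, 1), so zeros of the input map to zeros of the output.
#'
#' @param f_in feature map, `(H, W, C)` or `(H, W, C, N)` array.
#' @param state a [channel_attention_state()].
#' @return gated feature map of the same shape as `f_in`.
#' @export
channel_attention <- function(f_in, state) {
  x <- as_feature_map(f_in)
  d <- dim(x)
  if (d[3] != length(state$scale))
    wa_stop_config(sprintf("channel mismatch: feature map has %d channels, state has %d",
                           d[3], length(state$scale)))
  w <- normalized_channel_weights(state$scale)
  istd <- 1 / sqrt(state$variance + state$epsilon)
  xhat <- (x - bc_ch(state$mean, d)) * bc_ch(istd, d)
  slope <- w * state$scale
  shift <- if (state$nam_style) w * state$shift else state$shift
  gate <- 1 / (1 + exp(-(bc_ch(slope, d) * xhat + bc_ch(shift, d))))
  y <- x * gate
  dim(y) <- d
  restore_dims(y, f_in)
}

#' Spatial attention state
#'
#' Parameters of the spatial-attention gate: a 7x7 convolution mapping the
#' stacked channel-mean and channel-max planes to a single plane, plus a bias.
#'
#' @param kernel array of dim `c(7, 7, 2, 1)`.
#' @param bias scalar bias.
#' @return an object of class `wa_sa_state`.
#' @export
spatial_attention_state <- function(kernel, bias = 0) {
  kernel <- as.array(kernel)
  if (!identical(as.integer(dim(kernel)), c(7L, 7L, 2L, 1L)))
    wa_stop_config("spatial attention kernel must have dim c(7, 7, 2, 1)")
  structure(list(kernel = kernel, bias = as.numeric(bias)[1]),
            class = "wa_sa_state")
}

#' Apply the spatial-attention gate
#'
#' Computes per-pixel mean and max over channels, stacks the two planes,
#' convolves them with the state's 7x7 kernel (zero padding 3, plus bias),
#' passes the result through a sigmoid, and multiplies the input by the
#' resulting (0, 1) map, broadcast across channels.
#'
#' @param f_in feature map, `(H, W, C)` or `(H, W, C, N)` array.
#' @param state a [spatial_attention_state()].
#' @return gated feature map of the same shape as `f_in`.
#' @export
spatial_attention <- function(f_in, state) {
  x <- as_feature_map(f_in)
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- aperm(x, c(1, 2, 4, 3))
  m <- matrix(xp, ncol = C)
  A <- rowMeans(m)
  Mx <- do.call(pmax, lapply(seq_len(C), function(k) m[, k]))
  st <- array(0, c(H, W, 2L, N))
  st[, , 1L, ] <- array(A, c(H, W, N))
  st[, , 2L, ] <- array(Mx, c(H, W, N))
  u <- cpp_conv2d_fwd(st, state$kernel, state$bias, 1L, 3L)
  map3 <- array(1 / (1 + exp(-u)), c(H, W, N))
  mf <- aperm(array(map3, c(H, W, N, C)), c(1, 2, 4, 3))
  y <- x * mf
  dim(y) <- d
  restore_dims(y, f_in)
}

#' The spatial attention map alone
#'
#' Returns the (0, 1) attention map (`H x W x 1 x N`, or `H x W` for a single
#' unbatched input) rather than the gated features; useful for visualization.
#'
#' @inheritParams spatial_attention
#' @return array of attention map values in (0, 1).
#' @export
spatial_attention_map <- function(f_in, state) {
  x <- as_feature_map(f_in)
  d <- dim(x)
  C <- d[3]
  xp <- aperm(x, c(1, 2, 4, 3))
  m <- matrix(xp, ncol = C)
  A <- rowMeans(m)
  Mx <- do.call(pmax, lapply(seq_len(C), function(k) m[, k]))
  st <- array(0, c(d[1], d[2], 2L, d[4]))
  st[, , 1L, ] <- array(A, c(d[1], d[2], d[4]))
  st[, , 2L, ] <- array(Mx, c(d[1], d[2], d[4]))
  u <- cpp_conv2d_fwd(st, state$kernel, state$bias, 1L, 3L)
  map <- 1 / (1 + exp(-u))
  if (length(dim(f_in)) <= 3 && dim(map)[4] == 1) {
    map <- map[, , 1, 1]
  }
  map
}
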
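# Seeded synthetic long-tailed segmentation data.
#
# Each image is a noisy grayscale field in which each foreground class i is
# included with probability p_i; included classes paint one or more elliptical
# blobs (connected instances, not pixel noise) at class-specific sizes and
# intensities. Classes are painted in order of descending expected blob size
# and never overwrite already-labeled pixels, so the rare small class, painted
# last, is never swallowed by the large ones.

#' Configuration for the synthetic generator
#'
#' @param n_images number of images.
#' @param image_size square image side, a multiple of 32 (>= 32).
#' @param include_prob per-class inclusion probability, length C.
#' @param instances_range C x 2 matrix: min/max instance count per image.
#' @param radius_range C x 2 matrix: min/max blob radius in pixels.
#' @param class_intensity per-class mean grayscale intensity in \[0,1\].
#' @param class_contrast per-instance intensity jitter half-range.
#' @param background_intensity background mean intensity.
#' @param noise_sd standard deviation of additive pixelwise Gaussian noise.
#' @param seed integer seed.
#' @return an object of class `wa_synth_config`.
#' @export
synthetic_config <- function(n_images, image_size = 64L,
                             include_prob,
                             instances_range,
                             radius_range,
                             class_intensity,
                             class_contrast = 0.08,
                             background_intensity = 0.2,
                             noise_sd = 0.05,
                             seed = 0L) {
  C <- length(include_prob)
  instances_range <- matrix(as.numeric(instances_range), ncol = 2)
  radius_range <- matrix(as.numeric(radius_range), ncol = 2)
  if (nrow(instances_range) != C || nrow(radius_range) != C ||
      length(class_intensity) != C)
    wa_stop_config("per-class fields must all have C entries")
  if (any(include_prob < 0 | include_prob > 1))
    wa_stop_config("inclusion probabilities must lie in [0, 1]")
  if (image_size < 32 || image_size %% 32 != 0)
    wa_stop_config("image_size must be a multiple of 32 (>= 32)")
  if (any(radius_range <= 0))
    wa_stop_config("radius ranges must be positive")
  if (any(radius_range > image_size / 2))
    wa_stop_config("blob radius exceeds image_size / 2: infeasible geometry")
  structure(list(n_images = as.integer(n_images), image_size = as.integer(image_size),
                 include_prob = include_prob, instances_range = instances_range,
                 radius_range = radius_range, class_intensity = class_intensity,
                 class_contrast = class_contrast,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed), C = C),
            class = "wa_synth_config")
}

#' Long-tailed preset emulating a strongly imbalanced 4-class study
#'
#' Inclusion probabilities are proportional to per-class image frequencies of
#' 1603:869:1090:201 over 3206 images (about 8:4.3:5.4:1), i.e.
#' `p = (0.50, 0.27, 0.34, 0.063)`. Class 1 paints one large blob, classes 2-3
#' intermediate blobs, and class 4 several very small blobs, so the expected
#' class-1 : class-4 pixel ratio exceeds 100:1 - the long-tailed regime the
#' image-count weight formula targets.
#'
#' @param n_images number of images (default 200).
#' @param image_size square image side (default 64).
#' @param seed integer seed (default 0).
#' @return a `wa_synth_config`.
#' @export
longtail_preset <- function(n_images = 200L, image_size = 64L, seed = 0L) {
  sc <- image_size / 64
  synthetic_config(
    n_images = n_images, image_size = image_size,
    include_prob = c(0.50, 0.27, 0.34, 0.063),
    instances_range = rbind(c(1, 1), c(1, 2), c(1, 2), c(1, 3)),
    radius_range = sc * rbind(c(10, 16), c(4, 7), c(7, 11), c(1.2, 2.2)),
    class_intensity = c(0.55, 0.75, 0.40, 0.90),
    class_contrast = 0.08,
    background_intensity = 0.20,
    noise_sd = 0.05,
    seed = seed)
}

paint_ellipse <- function(mask, cx, cy, rx, ry, theta) {
  n <- nrow(mask)
  xs <- matrix(rep(seq_len(n), times = n), n) - cx   # row offsets
  ys <- matrix(rep(seq_len(n), each = n), n) - cy    # col offsets
  u <- (xs * cos(theta) + ys * sin(theta)) / rx
  v <- (-xs * sin(theta) + ys * cos(theta)) / ry
  (u^2 + v^2) <= 1 & mask == 0L
}

sample_range_int <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Generate a synthetic long-tailed dataset
#'
#' Deterministic for a fixed seed. Blob centres of later (smaller) classes are
#' drawn from still-unlabeled pixels, so an included class always contributes
#' at least one visible pixel unless the image is already fully labeled.
#'
#' @param config a `wa_synth_config`.
#' @return list with `dataset` (labeled images) and `record`, a data frame
#'   listing per image which classes were painted and whether it is
#'   background-only.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "wa_synth_config"))
  C <- config$C
  sz <- config$image_size
  exp_area <- pi * rowMeans(config$radius_range)^2 * rowMeans(config$instances_range)
  order_paint <- order(exp_area, decreasing = TRUE)
  with_seed(config$seed, {
    dataset <- vector("list", config$n_images)
    rec <- matrix(FALSE, config$n_images, C)
    for (img_i in seq_len(config$n_images)) {
      include <- runif(C) < config$include_prob
      mask <- matrix(0L, sz, sz)
      img <- matrix(config$background_intensity, sz, sz)
      for (cls in order_paint[include[order_paint]]) {
        k <- sample_range_int(config$instances_range[cls, 1], config$instances_range[cls, 2])
        for (inst in seq_len(k)) {
          free <- which(mask == 0L)
          if (length(free) == 0) break
          ctr <- free[sample.int(length(free), 1)]
          cx <- (ctr - 1) %% sz + 1
          cy <- (ctr - 1) %/% sz + 1
          rx <- runif(1, config$radius_range[cls, 1], config$radius_range[cls, 2])
          ry <- runif(1, config$radius_range[cls, 1], config$radius_range[cls, 2])
          theta <- runif(1, 0, pi)
          painted <- paint_ellipse(mask, cx, cy, rx, ry, theta)
          mask[painted] <- cls
          level <- config$class_intensity[cls] +
            config$class_contrast * (2 * runif(1) - 1)
          img[painted] <- level
        }
        rec[img_i, cls] <- any(mask == cls)
      }
      img <- img + rnorm(sz * sz, 0, config$noise_sd)
      # quantize to the 8-bit grayscale grid the PNG writer uses
      img <- round(pmin(pmax(img, 0), 1) * 255) / 255
      dim(img) <- c(sz, sz)
      dataset[[img_i]] <- labeled_image(img, mask,
                                        sprintf("synth%05d", img_i))
    }
    record <- data.frame(id = vapply(dataset, `[[`, character(1), "id"))
    for (cls in seq_len(C)) record[[paste0("class", cls)]] <- rec[, cls]
    record$background_only <- rowSums(rec) == 0
    list(dataset = dataset, record = record)
  })
}
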
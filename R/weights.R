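# Class rebalancing weights for long-tailed multi-class segmentation.
#
# The key quantity is the per-class *image* count N_i: the number of images in
# which class i appears at all. Inverse-frequency proportions P_i = sum(N)/N_i
# are normalized either so the weights sum to the number of classes C
# (W_i = C / (N_i * sum_j 1/N_j), the formula used in the loss) or so they sum
# to one (the form printed alongside dataset statistics tables). The same
# machinery applies to per-class pixel counts, the conventional baseline that
# image-count weighting is designed to replace.

#' Per-class image and pixel counts of a labeled dataset
#'
#' @param dataset a list of labeled images as produced by [load_dataset()] or
#'   [generate_dataset()]: each element has an integer `mask` with values in
#'   `{0..C}` (0 = background) and an `id`.
#' @param C number of foreground classes.
#' @return an object of class `wa_class_stats` with fields `class_labels`
#'   (1..C), `image_counts`, `pixel_counts` and `C`.
#' @export
compute_class_stats <- function(dataset, C) {
  C <- as.integer(C)
  if (C < 1) wa_stop_config("C must be a positive integer")
  image_counts <- integer(C)
  pixel_counts <- numeric(C)
  for (i in seq_along(dataset)) {
    m <- dataset[[i]]$mask
    if (is.null(m)) wa_stop_data(sprintf("dataset element %d has no mask", i))
    bad <- m < 0 | m > C | m != floor(m)
    if (any(bad)) {
      id <- if (!is.null(dataset[[i]]$id)) dataset[[i]]$id else as.character(i)
      wa_stop_data(sprintf(
        "mask '%s' contains label %s outside the valid range 0..%d",
        id, paste(unique(m[bad]), collapse = ", "), C))
    }
    tab <- tabulate(as.integer(m), nbins = C)  # counts labels 1..C
    pixel_counts <- pixel_counts + tab
    image_counts <- image_counts + as.integer(tab > 0)
  }
  structure(list(class_labels = seq_len(C), image_counts = image_counts,
                 pixel_counts = pixel_counts, C = C),
            class = "wa_class_stats")
}

#' Construct class statistics from known counts
#'
#' @param image_counts per-class image counts.
#' @param pixel_counts per-class pixel counts.
#' @param class_labels class identifiers, default `1..C`.
#' @return a `wa_class_stats` object.
#' @export
class_stats <- function(image_counts, pixel_counts = rep(NA_real_, length(image_counts)),
                        class_labels = seq_along(image_counts)) {
  C <- length(image_counts)
  if (length(pixel_counts) != C || length(class_labels) != C)
    wa_stop_config("image_counts, pixel_counts and class_labels must have equal length")
  if (any(image_counts < 0, na.rm = TRUE) || any(pixel_counts < 0, na.rm = TRUE))
    wa_stop_config("counts must be non-negative")
  structure(list(class_labels = class_labels,
                 image_counts = as.numeric(image_counts),
                 pixel_counts = as.numeric(pixel_counts), C = C),
            class = "wa_class_stats")
}

#' @export
print.wa_class_stats <- function(x, ...) {
  cat("Class statistics over", x$C, "foreground classes\n")
  print(data.frame(label = x$class_labels, image_count = x$image_counts,
                   pixel_count = x$pixel_counts), row.names = FALSE)
  invisible(x)
}

inverse_count_weights <- function(counts, labels, mode, background_weight, basis) {
  mode <- match.arg(mode, c("sum_to_C", "sum_to_one"))
  if (!is.numeric(background_weight) || background_weight <= 0)
    wa_stop_config("background_weight must be a positive real")
  if (any(is.na(counts)))
    wa_stop_data(sprintf("%s counts are missing; supply them or use the other weighting basis", basis))
  if (any(counts <= 0))
    wa_stop_data(sprintf(
      "class(es) %s have zero %s count: weights are undefined for absent classes; exclude the class or supply a positive floor count",
      paste(labels[counts <= 0], collapse = ", "), basis))
  C <- length(counts)
  proportions <- sum(counts) / counts          # P_i, inverse-frequency
  inv <- 1 / counts
  w <- switch(mode,
    sum_to_C = C / (counts * sum(inv)),             # sums to C
    sum_to_one = inv / sum(inv))               # sums to 1
  names(w) <- as.character(labels)
  structure(list(weights = w, proportions = proportions, mode = mode,
                 background_weight = background_weight, basis = basis, C = C),
            class = "wa_weight_vector")
}

#' Image-count based class weights
#'
#' Computes per-class rebalancing weights from the number of images containing
#' each class. Proportions are inverse to the image count
#' (`P_i = sum_j N_j / N_i`); `mode = "sum_to_C"` rescales them so the weights sum
#' to the number of classes (`W_i = C / (N_i * sum_j 1/N_j)`, the form entered
#' into the loss), while `mode = "sum_to_one"` normalizes them to sum to one.
#' Weights are invariant under rescaling all counts by a common factor and are
#' strictly decreasing in the count.
#'
#' @param stats a `wa_class_stats` object.
#' @param mode `"sum_to_C"` (weights sum to C; default, used by the loss) or
#'   `"sum_to_one"` (weights sum to 1).
#' @param background_weight positive weight applied to label 0, default 1.
#' @return an object of class `wa_weight_vector`.
#' @export
#' @examples
#' s <- class_stats(image_counts = c(1603, 869, 1090, 201))
#' round(image_based_weights(s, mode = "sum_to_one")$weights, 3)
image_based_weights <- function(stats, mode = c("sum_to_C", "sum_to_one"),
                                background_weight = 1) {
  mode <- match.arg(mode)
  inverse_count_weights(stats$image_counts, stats$class_labels, mode,
                        background_weight, basis = "image")
}

#' Pixel-count based class weights
#'
#' The conventional inverse-pixel-frequency baseline: identical normalization
#' to [image_based_weights()] with per-class pixel counts in place of image
#' counts.
#'
#' @inheritParams image_based_weights
#' @return an object of class `wa_weight_vector`.
#' @export
pixel_based_weights <- function(stats, mode = c("sum_to_C", "sum_to_one"),
                                background_weight = 1) {
  mode <- match.arg(mode)
  inverse_count_weights(stats$pixel_counts, stats$class_labels, mode,
                        background_weight, basis = "pixel")
}

#' @export
print.wa_weight_vector <- function(x, ...) {
  cat(sprintf("%s-count class weights (mode = %s, background weight = %g)\n",
              x$basis, x$mode, x$background_weight))
  print(round(x$weights, 4))
  invisible(x)
}

# full per-label weight vector for labels 0..C (background first)
full_label_weights <- function(weights, C) {
  if (inherits(weights, "wa_weight_vector")) {
    if (weights$C != C)
      wa_stop_config(sprintf("weight vector covers %d classes, expected %d", weights$C, C))
    return(c(weights$background_weight, unname(weights$weights)))
  }
  w <- as.numeric(weights)
  if (length(w) == C + 1) return(w)
  if (length(w) == C) return(c(1, w))
  wa_stop_config(sprintf("need %d (+1 background) weights, got %d", C, length(w)))
}

#' Read a class-statistics table
#'
#' Plain-text CSV with columns `label, image_count, pixel_count`, one row per
#' foreground class.
#'
#' @param path file path.
#' @return a `wa_class_stats` object.
#' @export
read_class_stats <- function(path) {
  if (!file.exists(path)) wa_stop_data(sprintf("class-statistics file '%s' not found", path))
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("label", "image_count", "pixel_count")
  if (!all(need %in% names(df)))
    wa_stop_data(sprintf("class-statistics file must have columns %s", paste(need, collapse = ", ")))
  class_stats(df$image_count, df$pixel_count, df$label)
}

#' Write a class-statistics table
#'
#' @param stats a `wa_class_stats` object.
#' @param path file path.
#' @export
write_class_stats <- function(stats, path) {
  df <- data.frame(label = stats$class_labels, image_count = stats$image_counts,
                   pixel_count = stats$pixel_counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a weight vector
#'
#' Plain-text table `label, weight` with a header recording the weighting
#' basis, normalization mode and background weight.
#'
#' @param wv a `wa_weight_vector`.
#' @param path file path.
#' @export
write_weight_vector <- function(wv, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# basis=%s mode=%s background_weight=%g",
                     wv$basis, wv$mode, wv$background_weight), con)
  writeLines("label,weight", con)
  writeLines(sprintf("%s,%.12g", names(wv$weights), wv$weights), con)
  invisible(path)
}
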
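# Dataset IO. Images are single-channel PNGs (8- or 16-bit, scaled to [0,1]
# on load); masks are 8-bit indexed PNGs whose raw values are the labels
# 0..C (0 = background). Images and masks are paired by file name. Coordinates
# are row-major with origin at the top-left; masks share the image pixel grid
# exactly.

labeled_image <- function(image, mask, id) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    wa_stop_data(sprintf("'%s': image and mask shapes differ", id))
  list(image = image, mask = mask, id = id)
}

read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]  # take the first channel of non-gray files
  x
}

#' Load an image/mask dataset from paired PNG directories
#'
#' Every image must have a same-named mask. Files are ordered
#' deterministically by name; mask labels are validated against `{0..C}`.
#' Per-file problems (missing mask, shape mismatch, out-of-range label) are
#' collected and reported together.
#'
#' @param images_dir directory of grayscale image PNGs.
#' @param masks_dir directory of same-named mask PNGs (raw values = labels).
#' @param C number of foreground classes.
#' @return list of labeled images (`image` in \[0,1\], integer `mask`, `id`).
#' @export
load_dataset <- function(images_dir, masks_dir, C) {
  if (!dir.exists(images_dir)) wa_stop_data(sprintf("images directory '%s' not found", images_dir))
  if (!dir.exists(masks_dir)) wa_stop_data(sprintf("masks directory '%s' not found", masks_dir))
  files <- sort(list.files(images_dir, pattern = "\\.png$"))
  out <- vector("list", length(files))
  errs <- character(0)
  for (i in seq_along(files)) {
    f <- files[i]
    mpath <- file.path(masks_dir, f)
    if (!file.exists(mpath)) {
      errs <- c(errs, sprintf("'%s': no mask with the same name", f))
      next
    }
    img <- read_gray_png(file.path(images_dir, f))
    msk <- round(read_gray_png(mpath) * 255)
    storage.mode(msk) <- "integer"
    if (!identical(dim(img), dim(msk))) {
      errs <- c(errs, sprintf("'%s': image is %s but mask is %s", f,
                              paste(dim(img), collapse = "x"),
                              paste(dim(msk), collapse = "x")))
      next
    }
    if (any(msk < 0L | msk > C)) {
      errs <- c(errs, sprintf("'%s': mask contains label(s) %s outside 0..%d", f,
                              paste(sort(unique(msk[msk < 0L | msk > C])), collapse = ", "), C))
      next
    }
    out[[i]] <- labeled_image(img, msk, sub("\\.png$", "", f))
  }
  if (length(errs))
    wa_stop_data(paste0("dataset validation failed:\n", paste("  -", errs, collapse = "\n")))
  out[!vapply(out, is.null, logical(1))]
}

#' Write an image/mask dataset as paired PNGs plus a manifest
#'
#' @param dataset list of labeled images.
#' @param images_dir,masks_dir output directories (created if needed).
#' @param manifest optional path for a plain-text manifest of pairs.
#' @export
write_dataset <- function(dataset, images_dir, masks_dir, manifest = NULL) {
  dir.create(images_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(masks_dir, recursive = TRUE, showWarnings = FALSE)
  for (li in dataset) {
    png::writePNG(li$image, file.path(images_dir, paste0(li$id, ".png")))
    png::writePNG(li$mask / 255, file.path(masks_dir, paste0(li$id, ".png")))
  }
  if (!is.null(manifest)) {
    ids <- vapply(dataset, `[[`, character(1), "id")
    writeLines(sprintf("%s.png\t%s.png", ids, ids), manifest)
  }
  invisible(dataset)
}

#' Drop images whose mask is background only
#'
#' Retains exactly the images with at least one foreground pixel, preserving
#' order. Background-only images carry no class signal and are removed from
#' the training split before training.
#'
#' @param dataset list of labeled images.
#' @return filtered dataset.
#' @export
remove_background_only <- function(dataset) {
  keep <- vapply(dataset, function(li) any(li$mask != 0L), logical(1))
  dataset[keep]
}

#' Split a dataset into training and validation parts
#'
#' Seeded shuffle followed by a floor-based cut: `floor(n * val_fraction)`
#' images go to validation, the rest to training. The two parts are disjoint,
#' exhaustive, and reproducible for a given seed; original ordering is kept
#' within each part.
#'
#' @param dataset list of labeled images.
#' @param val_fraction validation fraction in (0, 1); default 1/7 (about 6:1).
#' @param seed integer seed.
#' @return list with `train` and `val`.
#' @export
split_dataset <- function(dataset, val_fraction = 1 / 7, seed = 0L) {
  n <- length(dataset)
  if (n < 2) wa_stop_data("need at least 2 images to split")
  if (!(val_fraction > 0 && val_fraction < 1))
    wa_stop_config("val_fraction must lie strictly between 0 and 1")
  n_val <- floor(n * val_fraction)
  idx <- with_seed(seed, sample.int(n))
  val_idx <- sort(idx[seq_len(n_val)])
  train_idx <- sort(idx[setdiff(seq_len(n), seq_len(n_val))])
  list(train = dataset[train_idx], val = dataset[val_idx])
}

wa_palette <- function() {
  rbind(c(0, 0, 0),        # 0 background: black
        c(255, 0, 0),      # 1 red
        c(0, 255, 0),      # 2 green
        c(0, 0, 255),      # 3 blue
        c(255, 255, 0))    # 4 yellow
}

#' Colorize a label mask
#'
#' Maps labels 0..4 to black, red, green, blue and yellow respectively,
#' producing an `H x W x 3` array in \[0,1\] suitable for [png::writePNG()].
#'
#' @param mask integer mask with values in `{0..4}`.
#' @return `H x W x 3` color array.
#' @export
colorize_mask <- function(mask) {
  pal <- wa_palette()
  if (any(mask < 0 | mask > nrow(pal) - 1))
    wa_stop_data(sprintf("mask labels must lie in 0..%d for colorization", nrow(pal) - 1))
  d <- dim(mask)
  col <- pal[as.integer(mask) + 1L, , drop = FALSE] / 255
  array(col, c(d[1], d[2], 3L))
}

#' Recover labels from a colorized mask
#'
#' Inverse of [colorize_mask()]: exact palette lookup.
#'
#' @param color `H x W x 3` array in \[0,1\].
#' @return integer mask.
#' @export
mask_from_color <- function(color) {
  pal <- wa_palette() / 255
  d <- dim(color)
  flat <- matrix(color, ncol = 3)
  key <- flat[, 1] * 4 + flat[, 2] * 2 + flat[, 3]
  palkey <- pal[, 1] * 4 + pal[, 2] * 2 + pal[, 3]
  lab <- match(key, palkey) - 1L
  if (anyNA(lab)) wa_stop_data("color image contains non-palette colors")
  matrix(lab, d[1], d[2])
}
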
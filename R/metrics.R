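# Segmentation evaluation: per-class IoU, sensitivity and precision from a
# single confusion tally accumulated over all pixels of a dataset (micro
# accumulation: deterministic under image reordering, no per-image averaging).

#' Accumulate a per-class confusion tally
#'
#' Compares a predicted mask against a reference mask pixel by pixel and adds
#' the per-class true positives, false positives and false negatives into a
#' tally. Call repeatedly to fold a whole dataset into one tally.
#'
#' @param pred integer mask with labels `0..C`.
#' @param truth integer reference mask, same shape as `pred`.
#' @param C number of foreground classes.
#' @param tally an existing `wa_confusion` to accumulate into, or `NULL`.
#' @return an object of class `wa_confusion` with per-label `tp`, `fp`, `fn`.
#' @export
accumulate_confusion <- function(pred, truth, C, tally = NULL) {
  C <- as.integer(C)
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    wa_stop_data("predicted and reference masks must have identical shape")
  p <- as.integer(pred); t <- as.integer(truth)
  if (any(p < 0L | p > C) || any(t < 0L | t > C))
    wa_stop_data(sprintf("mask labels must lie in 0..%d", C))
  K <- C + 1L
  cm <- tabulate(p * K + t + 1L, nbins = K * K)  # cm[p, t] row-major in p
  dim(cm) <- c(K, K)                              # cm[t+1, p+1] column-major
  # column-major: index1 = (p*K + t) + 1 -> first dim = t, second = p
  tp <- diag(cm)
  fn <- rowSums(cm) - tp   # true label t, predicted something else
  fp <- colSums(cm) - tp   # predicted p, true label something else
  if (!is.null(tally)) {
    if (!inherits(tally, "wa_confusion") || tally$C != C)
      wa_stop_config("tally must be a wa_confusion over the same classes")
    tp <- tp + tally$tp; fp <- fp + tally$fp; fn <- fn + tally$fn
  }
  names(tp) <- names(fp) <- names(fn) <- as.character(0:C)
  structure(list(tp = tp, fp = fp, fn = fn, C = C), class = "wa_confusion")
}

#' Per-class IoU, sensitivity and precision
#'
#' `IoU = 100 TP/(TP+FP+FN)`, `sensitivity = 100 TP/(TP+FN)` and
#' `precision = 100 TP/(TP+FP)`, in percent. A zero denominator marks the cell
#' undefined (`NA`) rather than coercing it to 0 or 100.
#'
#' @param tally a `wa_confusion`.
#' @return data frame with one row per label `0..C`: `tp`, `fp`, `fn`, `iou`,
#'   `sensitivity`, `precision` (percent, `NA` when undefined).
#' @export
per_class_metrics <- function(tally) {
  stopifnot(inherits(tally, "wa_confusion"))
  ratio <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  with(tally, data.frame(
    label = 0:C,
    tp = as.numeric(tp), fp = as.numeric(fp), fn = as.numeric(fn),
    iou = ratio(tp, tp + fp + fn),
    sensitivity = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp),
    row.names = NULL))
}

#' Macro (unweighted) mean of per-class metric values
#'
#' The "Overall" column convention: an unweighted mean over the foreground
#' classes (`foreground_macro`) or over all classes including background
#' (`all_class_macro`). Undefined (`NA`) cells are excluded with a warning.
#'
#' @param values numeric vector of per-class values. For `foreground_macro`,
#'   pass foreground classes only, or name the elements with their labels
#'   (a `"0"` element is then dropped).
#' @param convention `"foreground_macro"` (default) or `"all_class_macro"`.
#' @return the macro mean.
#' @export
#' @examples
#' overall_metrics(c(63.35, 51.54, 61.48, 26.02)) # 50.5975
overall_metrics <- function(values, convention = c("foreground_macro", "all_class_macro")) {
  convention <- match.arg(convention)
  v <- values
  if (convention == "foreground_macro" && !is.null(names(v)) && "0" %in% names(v))
    v <- v[names(v) != "0"]
  if (all(is.na(v))) wa_stop_data("all per-class cells are undefined; no overall value")
  if (anyNA(v)) {
    warning("excluding ", sum(is.na(v)), " undefined per-class cell(s) from the overall mean")
    v <- v[!is.na(v)]
  }
  mean(v)
}

#' Full metrics report from a confusion tally
#'
#' @param tally a `wa_confusion`.
#' @return an object of class `wa_metrics_report`: the per-class table plus
#'   `overall_foreground` and `overall_all` rows (macro means of IoU,
#'   sensitivity, precision under both conventions).
#' @export
metrics_report <- function(tally) {
  pc <- per_class_metrics(tally)
  fg <- pc[pc$label != 0, ]
  ov <- function(x, conv) tryCatch(suppressWarnings(overall_metrics(x, conv)),
                                   error = function(e) NA_real_)
  structure(list(
    per_class = pc,
    overall_foreground = c(iou = ov(fg$iou, "foreground_macro"),
                           sensitivity = ov(fg$sensitivity, "foreground_macro"),
                           precision = ov(fg$precision, "foreground_macro")),
    overall_all = c(iou = ov(pc$iou, "all_class_macro"),
                    sensitivity = ov(pc$sensitivity, "all_class_macro"),
                    precision = ov(pc$precision, "all_class_macro")),
    undefined = pc$label[is.na(pc$iou)]),
    class = "wa_metrics_report")
}

#' @export
print.wa_metrics_report <- function(x, ...) {
  cat("Per-class segmentation metrics (percent):\n")
  tab <- x$per_class
  tab[, c("iou", "sensitivity", "precision")] <-
    round(tab[, c("iou", "sensitivity", "precision")], 2)
  print(tab[, c("label", "iou", "sensitivity", "precision")], row.names = FALSE)
  cat(sprintf("Overall (foreground macro): IoU %.2f, sensitivity %.2f, precision %.2f\n",
              x$overall_foreground["iou"], x$overall_foreground["sensitivity"],
              x$overall_foreground["precision"]))
  cat(sprintf("Overall (all-class macro):  IoU %.2f, sensitivity %.2f, precision %.2f\n",
              x$overall_all["iou"], x$overall_all["sensitivity"],
              x$overall_all["precision"]))
  if (length(x$undefined))
    cat("Undefined cells for label(s):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Write a metrics report
#'
#' Writes both a human-readable table (class columns plus Overall) and a
#' machine-readable `key,value` CSV.
#'
#' @param report a `wa_metrics_report`.
#' @param path base path; writes `<path>.txt` and `<path>.csv`.
#' @export
write_metrics_report <- function(report, path) {
  txt <- paste0(path, ".txt")
  con <- file(txt, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  pc <- report$per_class
  kv <- rbind(
    data.frame(key = sprintf("class%d.%s", rep(pc$label, 3),
                             rep(c("iou", "sensitivity", "precision"), each = nrow(pc))),
               value = c(pc$iou, pc$sensitivity, pc$precision)),
    data.frame(key = paste0("overall_foreground.", names(report$overall_foreground)),
               value = as.numeric(report$overall_foreground)),
    data.frame(key = paste0("overall_all.", names(report$overall_all)),
               value = as.numeric(report$overall_all)))
  utils::write.csv(kv, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}
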
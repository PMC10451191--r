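# Confusion accumulation and the per-class / Overall metric conventions.

test_that("identical masks give a diagonal tally", {
  m <- matrix(sample(0:4, 25, replace = TRUE), 5, 5)
  tal <- accumulate_confusion(m, m, 4)
  expect_true(all(tal$fp == 0))
  expect_true(all(tal$fn == 0))
  expect_equal(sum(tal$tp), 25)
})

test_that("fully disjoint masks land in fp/fn", {
  pred <- matrix(0L, 3, 3)
  truth <- matrix(1L, 3, 3)
  tal <- accumulate_confusion(pred, truth, 4)
  expect_equal(unname(tal$tp["1"]), 0)
  expect_equal(unname(tal$fn["1"]), 9)
  expect_equal(unname(tal$fp["0"]), 9)
})

test_that("random masks match a per-pixel counting oracle and fold correctly", {
  set.seed(11)
  total <- NULL
  otp <- ofp <- ofn <- rep(0, 5)
  for (i in 1:30) {
    pred <- matrix(sample(0:4, 64, replace = TRUE), 8, 8)
    truth <- matrix(sample(0:4, 64, replace = TRUE), 8, 8)
    o <- oracle_confusion(pred, truth, 4)
    tal <- accumulate_confusion(pred, truth, 4)
    expect_equal(unname(tal$tp), o$tp)
    expect_equal(unname(tal$fp), o$fp)
    expect_equal(unname(tal$fn), o$fn)
    total <- accumulate_confusion(pred, truth, 4, total)
    otp <- otp + o$tp; ofp <- ofp + o$fp; ofn <- ofn + o$fn
  }
  expect_equal(unname(total$tp), otp)
  expect_equal(unname(total$fp), ofp)
  expect_equal(unname(total$fn), ofn)
  # invariant: per class TP + FN = true pixels; totals sum to all pixels
  expect_equal(sum(total$tp + total$fn), 30 * 64)
})

test_that("shape mismatches are rejected", {
  expect_error(accumulate_confusion(matrix(0L, 2, 2), matrix(0L, 2, 3), 4),
               class = "wa_data_error")
})

test_that("per-class ratios follow the three standard formulas", {
  mk <- function(tp, fp, fn) {
    structure(list(tp = c("0" = 0, "1" = tp), fp = c("0" = 0, "1" = fp),
                   fn = c("0" = 0, "1" = fn), C = 1L), class = "wa_confusion")
  }
  r <- per_class_metrics(mk(5, 0, 0))[2, ]
  expect_equal(c(r$iou, r$sensitivity, r$precision), c(100, 100, 100))
  r <- per_class_metrics(mk(1, 1, 2))[2, ]
  expect_equal(r$iou, 25)
  expect_equal(r$sensitivity, 100 / 3, tolerance = 1e-10)
  expect_equal(r$precision, 50)
  r <- per_class_metrics(mk(0, 3, 2))[2, ]
  expect_equal(c(r$iou, r$sensitivity, r$precision), c(0, 0, 0))
  # 0/0 cells are flagged undefined, not coerced
  r <- per_class_metrics(mk(0, 0, 0))[2, ]
  expect_true(is.na(r$iou) && is.na(r$sensitivity) && is.na(r$precision))
})

test_that("IoU never exceeds sensitivity or precision", {
  set.seed(12)
  for (i in 1:200) {
    tal <- structure(list(tp = c("0" = sample(0:50, 1), "1" = sample(0:50, 1)),
                          fp = c("0" = sample(0:50, 1), "1" = sample(0:50, 1)),
                          fn = c("0" = sample(0:50, 1), "1" = sample(0:50, 1)),
                          C = 1L), class = "wa_confusion")
    pc <- per_class_metrics(tal)
    ok <- !is.na(pc$iou) & !is.na(pc$sensitivity) & !is.na(pc$precision)
    expect_true(all(pc$iou[ok] <= pc$sensitivity[ok] + 1e-9))
    expect_true(all(pc$iou[ok] <= pc$precision[ok] + 1e-9))
    # IoU = 100 exactly when the class is perfectly segmented with support
    perfect <- ok & pc$iou > 100 - 1e-9
    expect_true(all(pc$fp[perfect] == 0 & pc$fn[perfect] == 0 & pc$tp[perfect] > 0))
  }
})

test_that("the Overall column is the unweighted foreground mean", {
  expect_equal(overall_metrics(c(63.35, 51.54, 61.48, 26.02)), 50.5975)
  expect_equal(round(overall_metrics(c(62.22, 52.82, 61.66, 29.96)), 2), 51.67,
               tolerance = 0.005)
  expect_equal(overall_metrics(rep(7.5, 4)), 7.5)
  # a named background entry is dropped under the foreground convention
  v <- c("0" = 99, "1" = 10, "2" = 20, "3" = 30, "4" = 40)
  expect_equal(overall_metrics(v, "foreground_macro"), 25)
  expect_equal(overall_metrics(v, "all_class_macro"), mean(v))
  expect_warning(got <- overall_metrics(c(10, NA, 30)), "undefined")
  expect_equal(got, 20)
  expect_error(overall_metrics(c(NA_real_, NA_real_)), class = "wa_data_error")
})

test_that("published per-class IoU rows reproduce their printed Overall cells", {
  # benchmark rows (4 foreground classes + printed Overall), checked to half a
  # unit in the last printed decimal place
  rows <- list(
    list(v = c(61.71, 47.02, 60.32, 12.98), overall = 45.51),
    list(v = c(65.68, 48.42, 64.12, 22.74), overall = 50.24),
    list(v = c(63.2, 48.59, 61.47, 14.94), overall = 47.05),
    list(v = c(64.95, 60.69, 63.56, 0.21), overall = 47.35),
    list(v = c(63.35, 51.54, 61.48, 26.02), overall = 50.60),
    list(v = c(58.28, 51.22, 55.05, 16.63), overall = 45.30),
    list(v = c(65.13, 52.47, 66.84, 21.14), overall = 51.40),
    list(v = c(62.22, 52.82, 61.66, 29.96), overall = 51.67),
    list(v = c(62.24, 39.69, 60.06, 4.18), overall = 41.54),
    list(v = c(66.81, 53.12, 64.52, 0.0), overall = 46.11),
    list(v = c(60.66, 41.91, 60.83, 10.57), overall = 43.49),
    list(v = c(62.78, 48.76, 61.13, 8.09), overall = 45.19),
    list(v = c(79.54, 45.51, 76.34, 18.89), overall = 55.07),
    list(v = c(81.05, 53.58, 81.45, 17.04), overall = 58.28),
    list(v = c(83.23, 57.59, 79.27, 33.70), overall = 63.45),
    list(v = c(71.88, 84.12, 72.96, 19.35), overall = 62.08),
    list(v = c(73.59, 84.40, 71.03, 13.02), overall = 60.51),
    list(v = c(71.14, 86.44, 73.53, 74.05), overall = 76.29))
  for (r in rows)
    expect_lt(abs(overall_metrics(r$v, "foreground_macro") - r$overall), 0.005 + 1e-9)
})

test_that("metrics reports round-trip to disk in both formats", {
  pred <- matrix(c(0L, 1L, 2L, 2L), 2, 2)
  truth <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  rep_ <- metrics_report(accumulate_confusion(pred, truth, 4))
  base <- tempfile()
  suppressWarnings(write_metrics_report(rep_, base))
  expect_true(file.exists(paste0(base, ".txt")))
  kv <- utils::read.csv(paste0(base, ".csv"))
  expect_equal(kv$value[kv$key == "class1.sensitivity"], 50)
})
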
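# Weighted per-pixel cross-entropy and a seeded CPU training loop.
#
# The loss is the class-weighted categorical cross-entropy normalized by the
# summed weight of the evaluated pixels:
#   loss = sum_p w_{y_p} (-log softmax(scores_p)[y_p]) / sum_p w_{y_p}
# which is invariant under rescaling all weights by a positive constant and
# reduces exactly to the plain mean cross-entropy under uniform weights. Class
# weights are computed once from the training-split statistics before training
# starts, not per batch.

# internal: loss value and gradient wrt scores
wce_core <- function(scores, targets, wfull, want_grad = FALSE) {
  d <- dim(scores)
  K <- d[3]
  y <- as.integer(targets)
  if (any(y < 0L | y > K - 1L))
    wa_stop_data(sprintf("target labels must lie in 0..%d", K - 1L))
  m <- matrix(aperm(scores, c(1, 2, 4, 3)), ncol = K)   # rows in (h, w, n) order
  n <- nrow(m)
  rmax <- m[, 1]
  for (k in 2:K) rmax <- pmax(rmax, m[, k])
  lse <- rmax + log(rowSums(exp(m - rmax)))
  iy <- cbind(seq_len(n), y + 1L)
  wp <- wfull[y + 1L]
  sw <- sum(wp)
  loss <- sum(wp * (lse - m[iy])) / sw
  if (!want_grad) return(list(loss = loss))
  g <- exp(m - lse) * (wp / sw)
  g[iy] <- g[iy] - wp / sw
  g <- aperm(array(g, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
  list(loss = loss, grad = g)
}

#' Weighted per-pixel cross-entropy
#'
#' @param scores `(H, W, C + 1, N)` score array (or `(H, W, C + 1)`).
#' @param targets integer label array `(H, W, N)` (or `(H, W)`) in `0..C`.
#' @param weights a `wa_weight_vector` (its `background_weight` covers label
#'   0), or a numeric vector of length C+1 (labels 0..C) or C (foreground
#'   only; background weight 1).
#' @return the scalar loss (non-negative).
#' @export
weighted_cross_entropy <- function(scores, targets, weights) {
  scores <- as_feature_map(scores)
  C <- dim(scores)[3] - 1L
  wfull <- full_label_weights(weights, C)
  if (any(wfull <= 0)) wa_stop_config("all class weights must be positive")
  wce_core(scores, targets, wfull)$loss
}

#' Training configuration
#'
#' @param epochs number of passes over the training data (>= 0).
#' @param batch_size images per step.
#' @param learning_rate Adam step size.
#' @param optimizer_name currently `"adam"`.
#' @param weight_mode `"uniform"`, `"image_based"` or `"pixel_based"`; used by
#'   [train_model()] to derive class weights from the training split when no
#'   explicit weight vector is passed.
#' @param seed integer seed for shuffling (and any weight-derived randomness).
#' @param max_steps optional hard cap on optimizer steps (overrides epochs).
#' @param metrics_every evaluate metrics every this many epochs (0 = only
#'   after the final epoch).
#' @param device device hint (only `"cpu"` is available).
#' @return an object of class `wa_train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 8L, learning_rate = 1e-3,
                         optimizer_name = "adam",
                         weight_mode = c("uniform", "image_based", "pixel_based"),
                         seed = 0L, max_steps = NULL, metrics_every = 1L,
                         device = "cpu") {
  weight_mode <- match.arg(weight_mode)
  if (epochs < 0) wa_stop_config("epochs must be >= 0")
  if (batch_size < 1) wa_stop_config("batch_size must be >= 1")
  if (learning_rate <= 0) wa_stop_config("learning_rate must be positive")
  if (!identical(optimizer_name, "adam"))
    wa_stop_config("only the 'adam' optimizer is implemented")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer_name = optimizer_name,
                 weight_mode = weight_mode, seed = as.integer(seed),
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
                 metrics_every = as.integer(metrics_every), device = device),
            class = "wa_train_config")
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    # in-place update; the tape referencing these arrays is discarded after
    # the step, and fresh leaves are built from `params` next step
    cpp_adam_step(params[[nm]], g, state$m[[nm]], state$v[[nm]],
                  lr, beta1, beta2, eps, c1, c2)
  }
  list(params = params, state = state)
}

dataset_to_arrays <- function(dataset) {
  d <- dim(dataset[[1]]$image)
  n <- length(dataset)
  xs <- array(0, c(d[1], d[2], 1L, n))
  ys <- array(0L, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    xs[, , 1, i] <- dataset[[i]]$image
    ys[, , i] <- dataset[[i]]$mask
  }
  list(x = xs, y = ys)
}

resolve_weights <- function(weights, dataset, cfg, C) {
  if (!is.null(weights)) return(full_label_weights(weights, C))
  switch(cfg$weight_mode,
    uniform = rep(1, C + 1L),
    image_based = full_label_weights(image_based_weights(compute_class_stats(dataset, C)), C),
    pixel_based = full_label_weights(pixel_based_weights(compute_class_stats(dataset, C)), C))
}

#' Train a model
#'
#' Seeded, single-device training with Adam on the weighted cross-entropy.
#' With `epochs = 0` (and no `max_steps`) the model is returned unchanged.
#' A non-finite loss aborts with a diagnostic.
#'
#' @param model a `wa_model`.
#' @param dataset training data: list of labeled images (equal sizes,
#'   divisible by 32).
#' @param config a [train_config()].
#' @param weights optional explicit class weights (`wa_weight_vector` or
#'   numeric); when `NULL` they are derived from the training data according
#'   to `config$weight_mode`.
#' @param eval_dataset data used for the per-epoch metrics history (default:
#'   the training data).
#' @return list with the trained `model`, a `history` data frame (per-epoch
#'   mean loss and, where evaluated, per-class IoU/sensitivity/precision), and
#'   `best_model`/`best_epoch` — the checkpoint with the highest overall
#'   foreground IoU among evaluated epochs (`NULL` when metrics were never
#'   evaluated).
#' @export
train_model <- function(model, dataset, config, weights = NULL,
                        eval_dataset = dataset) {
  stopifnot(inherits(model, "wa_model"), inherits(config, "wa_train_config"))
  if (length(dataset) == 0) wa_stop_data("training dataset is empty")
  C <- model$config$num_foreground_classes
  wfull <- resolve_weights(weights, dataset, config, C)
  arr <- dataset_to_arrays(dataset)
  d <- dim(arr$x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    wa_stop_data("training images must have sides divisible by 32")
  n <- d[4]
  total_steps <- if (!is.null(config$max_steps)) config$max_steps
                 else config$epochs * ceiling(n / config$batch_size)
  if (total_steps == 0) {
    hist <- data.frame(epoch = integer(0), loss = numeric(0))
    return(list(model = model, history = hist))
  }
  # deep copy: the optimizer updates parameters in place
  params <- lapply(model$params, function(p) p + 0)
  buf <- list2env(model$buffers, parent = emptyenv())
  opt <- adam_new(params)
  hist_rows <- list()
  step <- 0L
  epoch <- 0L
  best <- list(iou = -Inf, epoch = NA_integer_, model = NULL)
  with_seed(config$seed, {
    while (step < total_steps) {
      epoch <- epoch + 1L
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        if (step >= total_steps) break
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- arr$x[, , , idx, drop = FALSE]
        yb <- arr$y[, , idx, drop = FALSE]
        run <- net_apply(list(config = model$config, params = params), xb, buf,
                         training = TRUE)
        lr_ <- wce_core(run$out$value, yb, wfull, want_grad = TRUE)
        if (!is.finite(lr_$loss))
          stop(sprintf("training diverged: non-finite loss at step %d (epoch %d); lower the learning rate or check the inputs",
                       step + 1L, epoch))
        ag_backward(run$ctx, run$out, lr_$grad)
        grads <- lapply(run$P, function(nd) nd$grad)
        upd <- adam_step(params, grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
        losses <- c(losses, lr_$loss)
        step <- step + 1L
      }
      cur <- structure(list(config = model$config, seed = model$seed,
                            params = params, buffers = as.list(buf)),
                       class = "wa_model")
      do_metrics <- !is.null(eval_dataset) &&
        ((config$metrics_every > 0 && epoch %% config$metrics_every == 0) ||
           step >= total_steps)
      row <- data.frame(epoch = epoch, loss = mean(losses))
      if (do_metrics) {
        rep_ <- evaluate_model(cur, eval_dataset)
        pc <- rep_$per_class
        for (cl in pc$label) {
          row[[sprintf("iou_%d", cl)]] <- pc$iou[pc$label == cl]
          row[[sprintf("sens_%d", cl)]] <- pc$sensitivity[pc$label == cl]
          row[[sprintf("prec_%d", cl)]] <- pc$precision[pc$label == cl]
        }
        row$overall_iou <- rep_$overall_foreground["iou"]
        # keep the checkpoint with the best overall foreground IoU
        if (is.finite(row$overall_iou) && row$overall_iou > best$iou) {
          best$iou <- row$overall_iou
          best$epoch <- epoch
          best$model <- structure(list(config = model$config, seed = model$seed,
                                       params = lapply(params, function(p) p + 0),
                                       buffers = as.list(buf)),
                                  class = "wa_model")
        }
      }
      hist_rows[[epoch]] <- row
    }
  })
  model$params <- params
  model$buffers <- as.list(buf)
  hist <- do.call(rbind, lapply(hist_rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(hist_rows, names))), names(r))
    for (m in miss) r[[m]] <- NA_real_
    r
  }))
  list(model = model, history = hist,
       best_model = best$model, best_epoch = best$epoch)
}

#' Evaluate a model on a dataset
#'
#' Accumulates a single confusion tally over all pixels (micro accumulation)
#' and returns the full metrics report.
#'
#' @param model a `wa_model`.
#' @param dataset list of labeled images.
#' @param batch_size images per forward pass.
#' @return a `wa_metrics_report` (with the tally attached as `$tally`).
#' @export
evaluate_model <- function(model, dataset, batch_size = 8L) {
  C <- model$config$num_foreground_classes
  arr <- dataset_to_arrays(dataset)
  preds <- predict_masks(arr$x, model, batch_size = batch_size)
  tally <- accumulate_confusion(preds, arr$y, C)
  rep_ <- metrics_report(tally)
  rep_$tally <- tally
  rep_
}
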
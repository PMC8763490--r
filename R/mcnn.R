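# Multilayer CNN stage classifier.
#
# Architecture: n_blocks of [3x3 convolution (same padding) -> ReLU ->
# 2x2 max-pool] -> flatten -> dropout -> fully-connected -> ReLU ->
# fully-connected -> softmax, trained by momentum SGD on the cross-entropy
# loss with a stepped learning-rate schedule and early stopping. The depth
# axis of the (height x width x depth) input is treated as the channel axis
# of 2D convolutions. The numeric core is compiled; every stochastic choice
# (weight init, shuffling, dropout) is drawn from R's RNG so a fixed seed
# reproduces training bit for bit.

#' Rectified linear activation
#' @param y numeric scalar, vector or array.
#' @export
relu <- function(y) {
  pmax(y, 0)
}

#' Softmax over classes
#' @param z numeric vector, or matrix with one column per sample.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    e <- exp(sweep(z, 2, apply(z, 2, max)))
    sweep(e, 2, colSums(e), "/")
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Cross-entropy loss
#'
#' Mean over the batch of `-sum_c z_c log p_c` with `z` the one-hot class
#' indicator and `p` the predicted class probabilities. Probabilities are
#' clamped below at `eps`; each probability vector must sum to 1.
#'
#' @param indicator one-hot matrix (samples x classes) or vector of 0/1.
#' @param predicted probability matrix/vector of the same shape.
#' @param eps clamp floor.
#' @export
cross_entropy <- function(indicator, predicted, eps = 1e-12) {
  indicator <- rbind(indicator)
  predicted <- rbind(predicted)
  stopifnot(identical(dim(indicator), dim(predicted)))
  sums <- rowSums(predicted)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("predicted rows must be probability vectors summing to 1")
  }
  p <- pmin(pmax(predicted, eps), 1)
  mean(-rowSums(indicator * log(p)))
}

#' Stepped learning-rate schedule
#'
#' `lr0 * factor^(-floor(epoch / every))`: the learning rate drops by
#' `factor` every `every` epochs (epochs count from 0).
#'
#' @param epoch integer epoch index (0-based).
#' @param lr0 initial learning rate.
#' @param factor decay factor (default 10).
#' @param every epochs per step (default 10).
#' @export
lr_schedule <- function(epoch, lr0, factor = 10, every = 10) {
  stopifnot(all(epoch >= 0))
  lr0 * factor^(-floor(epoch / every))
}

#' M-CNN configuration
#'
#' @param input_shape (height, width, depth); spatial dims must be
#'   divisible by `2^n_blocks`.
#' @param n_blocks number of conv+pool blocks (1..6 supported; default 6).
#' @param channel_progression output channels per block.
#' @param dropout_rate dropout on the flattened features.
#' @param fc_units hidden fully-connected width.
#' @param n_classes output classes.
#' @param lr0 initial learning rate.
#' @param lr_decay_factor,lr_decay_every stepped schedule (see
#'   [lr_schedule()]).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param momentum SGD momentum.
#' @param clip_norm global L2 clip on the mean-over-batch gradient (one
#'   oversized momentum-amplified step can kill every ReLU); 0 disables.
#' @param early_stopping_patience epochs without validation-loss improvement
#'   before stopping (`Inf` disables).
#' @param seed RNG seed for init/shuffling/dropout.
#' @export
mcnn_config <- function(input_shape = c(256L, 256L, 8L), n_blocks = 6L,
                        channel_progression = c(8L, 16L, 32L, 64L, 128L, 256L),
                        dropout_rate = 0.2, fc_units = 4096L, n_classes = 9L,
                        lr0 = 0.01, lr_decay_factor = 10, lr_decay_every = 10,
                        epochs = 30L, batch_size = 10L, momentum = 0.9,
                        clip_norm = 5, early_stopping_patience = 10L,
                        seed = 1L) {
  input_shape <- as.integer(rep_len(input_shape, 3))
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 1, dropout_rate >= 0, dropout_rate < 1,
            fc_units >= 1, n_classes >= 2, batch_size >= 1, epochs >= 1)
  channel_progression <- as.integer(rep_len(channel_progression, n_blocks))
  red <- 2^n_blocks
  if (input_shape[1] %% red != 0 || input_shape[2] %% red != 0 ||
      input_shape[1] < red || input_shape[2] < red) {
    stop("input ", input_shape[1], "x", input_shape[2], " cannot pass ",
         n_blocks, " 2x2 poolings (needs divisibility by ", red,
         "); pad the input or reduce n_blocks")
  }
  structure(list(input_shape = input_shape, n_blocks = n_blocks,
                 kernel_size = 3L,
                 channel_progression = channel_progression,
                 dropout_rate = dropout_rate, fc_units = as.integer(fc_units),
                 n_classes = as.integer(n_classes), lr0 = lr0,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = lr_decay_every, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 clip_norm = clip_norm,
                 early_stopping_patience = early_stopping_patience,
                 seed = seed), class = "mcnn_config")
}

#' Desk-scale benchmark configuration
#'
#' The configuration used for the synthetic 9-class size-binned benchmark:
#' 64 x 64 x 8 slabs, six conv blocks, dropout 0.2, 4096 fully connected
#' units, batch size 10, stepped learning rate. The channel progression is
#' halved relative to [mcnn_config()]'s full-size default so a complete
#' 10-fold cross-validation fits a single-CPU time budget; the task's
#' capacity needs are far below either progression.
#'
#' @param ... overrides passed to [mcnn_config()].
#' @export
mcnn_benchmark_config <- function(...) {
  args <- list(input_shape = c(64L, 64L, 8L),
               channel_progression = c(4L, 8L, 16L, 32L, 64L, 128L),
               n_classes = 9L, lr0 = 0.01, epochs = 15L)
  override <- list(...)
  args[names(override)] <- override
  do.call(mcnn_config, args)
}

zeros_like_weights <- function(w) {
  lapply(w, function(x) {
    if (is.list(x)) zeros_like_weights(x) else x * 0
  })
}

deep_copy_weights <- function(w) {
  lapply(w, function(x) {
    if (is.list(x)) deep_copy_weights(x) else x + 0
  })
}

#' Build an M-CNN model
#'
#' He-initialized weights drawn from R's RNG under the config seed. The
#' reported parameter count is a deterministic function of the
#' configuration.
#'
#' @param config an [mcnn_config()].
#' @param class_labels optional class-name vector of length `n_classes`.
#' @return object of class `mcnn_model`.
#' @export
build_mcnn <- function(config = mcnn_config(), class_labels = NULL) {
  stopifnot(inherits(config, "mcnn_config"))
  if (!is.null(class_labels) &&
      length(class_labels) != config$n_classes) {
    stop("class_labels length must equal n_classes")
  }
  ch <- c(config$input_shape[3], config$channel_progression)
  hw <- config$input_shape[1:2]
  with_seed(config$seed, {
    conv_w <- conv_b <- vector("list", config$n_blocks)
    for (k in seq_len(config$n_blocks)) {
      fan_in <- 9 * ch[k]
      conv_w[[k]] <- matrix(stats::rnorm(ch[k + 1] * fan_in,
                                         sd = sqrt(2 / fan_in)),
                            nrow = ch[k + 1])
      conv_b[[k]] <- numeric(ch[k + 1])
      hw <- hw %/% 2L
    }
    flat <- prod(hw) * ch[length(ch)]
    # hidden layers He-initialized; the classifier head starts at zero so an
    # untrained model scores exactly uniform (loss log(n_classes))
    fc_w <- list(
      matrix(stats::rnorm(config$fc_units * flat, sd = sqrt(2 / flat)),
             nrow = config$fc_units),
      matrix(0, nrow = config$n_classes, ncol = config$fc_units))
    fc_b <- list(numeric(config$fc_units), numeric(config$n_classes))
  })
  n_params <- sum(vapply(conv_w, length, 0L)) +
    sum(vapply(conv_b, length, 0L)) +
    sum(vapply(fc_w, length, 0L)) + sum(vapply(fc_b, length, 0L))
  structure(list(config = config, conv_w = conv_w, conv_b = conv_b,
                 fc_w = fc_w, fc_b = fc_b, n_params = n_params,
                 flat_features = flat, class_labels = class_labels,
                 trained_epochs = 0L),
            class = "mcnn_model")
}

#' @export
print.mcnn_model <- function(x, ...) {
  cfg <- x$config
  hw <- cfg$input_shape[1:2] %/% 2L^cfg$n_blocks
  cat(sprintf(paste0(
    "<mcnn_model> %d blocks [3x3 conv -> ReLU -> 2x2 pool], input %s,\n",
    "  channels %s, final grid %dx%d, fc %d -> %d classes, %s parameters\n"),
    cfg$n_blocks, paste(cfg$input_shape, collapse = "x"),
    paste(cfg$channel_progression, collapse = "-"), hw[1], hw[2],
    cfg$fc_units, cfg$n_classes, format(x$n_params, big.mark = ",")))
  invisible(x)
}

check_input_array <- function(x, config) {
  d <- dim(x)
  if (length(d) == 3L) {
    x <- array(x, c(d, 1L))
    d <- dim(x)
  }
  if (length(d) != 4L || !all(d[1:3] == config$input_shape)) {
    stop("input shape ", paste(d, collapse = "x"),
         " does not match the configured ",
         paste(config$input_shape, collapse = "x"), " (H x W x depth [x N])")
  }
  x
}

#' Class probabilities for images
#'
#' @param object a trained (or untrained) `mcnn_model`.
#' @param x array (H, W, depth) or (H, W, depth, N).
#' @param ... unused.
#' @return list: `probabilities` (N x n_classes), `class` (argmax labels).
#' @export
predict.mcnn_model <- function(object, x, ...) {
  x <- check_input_array(x, object$config)
  probs <- mcnn_predict_cpp(as.numeric(x), dim(x), object$conv_w,
                            object$conv_b, object$fc_w, object$fc_b)
  probs <- t(probs)
  labels <- object$class_labels %||% as.character(seq_len(ncol(probs)))
  colnames(probs) <- labels
  list(probabilities = probs, class = labels[max.col(probs, "first")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train an M-CNN
#'
#' Momentum-SGD minimization of the softmax cross-entropy, with the stepped
#' learning-rate schedule, per-epoch reshuffling, inverted dropout on the
#' flattened features, and early stopping on validation loss (the weights
#' from the best validation epoch are restored). Fully reproducible for a
#' fixed `config$seed`.
#'
#' @param model an `mcnn_model` from [build_mcnn()].
#' @param x training array (H, W, depth, N).
#' @param y training labels (character/factor, must match `class_labels`
#'   when the model has them).
#' @param x_val,y_val optional validation set (enables early stopping).
#' @param epochs override of `config$epochs`.
#' @param verbose print one line per epoch.
#' @return the trained model, with a `history` data.frame (epoch, lr,
#'   train_loss, train_acc, val_loss, val_acc).
#' @export
train_mcnn <- function(model, x, y, x_val = NULL, y_val = NULL,
                       epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "mcnn_model"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  x <- check_input_array(x, cfg)
  n <- dim(x)[4]
  if (is.null(model$class_labels)) {
    model$class_labels <- sort(unique(as.character(y)))
    if (length(model$class_labels) > cfg$n_classes) {
      stop("more distinct labels (", length(model$class_labels),
           ") than configured classes (", cfg$n_classes, ")")
    }
    model$class_labels <- c(model$class_labels,
                            rep("", cfg$n_classes -
                                  length(model$class_labels)))[1:cfg$n_classes]
  }
  yi <- match(as.character(y), model$class_labels) - 1L
  if (anyNA(yi)) stop("labels outside the model's class vocabulary")
  has_val <- !is.null(x_val)
  if (has_val) {
    x_val <- check_input_array(x_val, cfg)
    yvi <- match(as.character(y_val), model$class_labels) - 1L
    if (anyNA(yvi)) stop("validation labels outside the class vocabulary")
  }

  # training mutates weights in place in compiled code: deep-copy first
  w <- deep_copy_weights(list(conv_w = model$conv_w, conv_b = model$conv_b,
                              fc_w = model$fc_w, fc_b = model$fc_b))
  v <- zeros_like_weights(w)
  flat <- model$flat_features
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), train_acc = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  best <- list(loss = Inf, weights = NULL, epoch = 0L)
  wait <- 0L
  xnum <- as.numeric(x)
  dimx <- dim(x)
  xv_num <- if (has_val) as.numeric(x_val) else NULL

  eval_split <- function(w, xs, ys) {
    probs <- t(mcnn_predict_cpp(xs, c(cfg$input_shape, length(ys)),
                                w$conv_w, w$conv_b, w$fc_w, w$fc_b))
    pred <- max.col(probs, "first") - 1L
    loss <- mean(-log(pmax(probs[cbind(seq_along(ys), ys + 1L)], 1e-12)))
    c(loss = loss, acc = mean(pred == ys))
  }

  with_seed(cfg$seed, {
    for (ep in seq_len(epochs)) {
      lr <- lr_schedule(ep - 1L, cfg$lr0, cfg$lr_decay_factor,
                        cfg$lr_decay_every)
      ord <- sample.int(n)
      dropmask <- if (cfg$dropout_rate > 0) {
        matrix((stats::runif(flat * n) >= cfg$dropout_rate) + 0, flat, n)
      } else {
        matrix(1, 1, 1)
      }
      ep_stats <- mcnn_epoch_cpp(xnum, dimx, yi, w$conv_w, w$conv_b,
                                 w$fc_w, w$fc_b, v$conv_w, v$conv_b,
                                 v$fc_w, v$fc_b, ord, dropmask,
                                 cfg$batch_size, lr, cfg$momentum,
                                 cfg$dropout_rate, cfg$clip_norm)
      # running loss/accuracy over the epoch's minibatches (pre-update
      # forward passes), the usual cheap training metrics
      row <- data.frame(epoch = ep, lr = lr, train_loss = ep_stats[1],
                        train_acc = ep_stats[2],
                        val_loss = NA_real_, val_acc = NA_real_)
      if (has_val) {
        vl <- eval_split(w, xv_num, yvi)
        row$val_loss <- unname(vl["loss"])
        row$val_acc <- unname(vl["acc"])
        if (row$val_loss < best$loss - 1e-12) {
          best <- list(loss = row$val_loss, weights = deep_copy_weights(w),
                       epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      hist <- rbind(hist, row)
      if (verbose) {
        message(sprintf(
          "epoch %3d lr %.2e train loss %.4f acc %.3f%s", ep, lr,
          row$train_loss, row$train_acc,
          if (has_val) sprintf(" val loss %.4f acc %.3f", row$val_loss,
                               row$val_acc) else ""))
      }
      if (has_val && is.finite(cfg$early_stopping_patience) &&
          wait >= cfg$early_stopping_patience) {
        break
      }
    }
  })
  if (has_val && !is.null(best$weights)) w <- best$weights
  model$conv_w <- w$conv_w
  model$conv_b <- w$conv_b
  model$fc_w <- w$fc_w
  model$fc_b <- w$fc_b
  model$history <- hist
  model$trained_epochs <- nrow(hist)
  model
}

#' Save / load a model (single portable file with embedded config)
#' @param model an `mcnn_model`.
#' @param path file path.
#' @export
save_mcnn <- function(model, path) {
  stopifnot(inherits(model, "mcnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_mcnn
#' @export
load_mcnn <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mcnn_model"))
  model
}
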
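#' Training configuration
#'
#' Adam with an initial learning rate of 1e-4 dropped by a factor of 0.1
#' every 30 epochs, 60 epochs, minibatch 8, shuffling every epoch,
#' categorical cross-entropy, and a validation check every 100 iterations.
#' The desk-scale profile trains for 30 epochs.
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param lr_drop multiplicative drop factor.
#' @param lr_step epochs between drops.
#' @param val_every validation check period, in iterations.
#' @param augment an [augment_policy()], or `NULL` to disable augmentation.
#' @param shuffle reshuffle the training set every epoch.
#' @param seed seed controlling initialisation, shuffling, augmentation and
#'   dropout.
#' @param verbose print progress at each validation check.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 60, batch_size = 8, lr = 1e-4,
                         lr_drop = 0.1, lr_step = 30, val_every = 100,
                         augment = augment_policy(), shuffle = TRUE,
                         seed = 1, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, lr_drop > 0, lr_step >= 1,
            val_every >= 1)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 lr_drop = lr_drop, lr_step = lr_step, val_every = val_every,
                 augment = augment, shuffle = shuffle, seed = seed,
                 verbose = verbose), class = "train_config")
}

#' Learning rate at a given (0-based) epoch
#'
#' Piecewise-constant schedule `lr * lr_drop^floor(epoch / lr_step)`.
#'
#' @param config a `train_config`.
#' @param epoch 0-based epoch index (or vector).
#' @export
learning_rate_at <- function(config, epoch) {
  config$lr * config$lr_drop^floor(epoch / config$lr_step)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

evaluate_loss_acc <- function(net, x, y_idx, batch = 16) {
  N <- dim(x)[4]
  loss <- 0; correct <- 0
  for (b0 in seq(1, N, by = batch)) {
    b1 <- min(N, b0 + batch - 1)
    fw <- forward_cnn(net, x[, , , b0:b1, drop = FALSE], training = FALSE,
                      keep = FALSE)
    sx <- softmax_xent(fw$probs, y_idx[b0:b1])
    loss <- loss + sx$loss * (b1 - b0 + 1)
    correct <- correct + sum(max.col(fw$probs) == y_idx[b0:b1])
  }
  list(loss = loss / N, acc = correct / N)
}

#' Fit the filament-event CNN
#'
#' Trains the convolutional classifier on labelled emission-event images
#' with the stated optimiser schedule and augmentation policy, checkpointing
#' on best validation accuracy.  Images can be supplied either as a
#' `dataset_manifest` (the train and val splits are loaded and resized to
#' the architecture's input side) or directly as arrays.
#'
#' @param manifest a `dataset_manifest`, or `NULL` when arrays are given.
#' @param x,y training images (side x side x 3 x N array) and labels
#'   (factor over `particle_classes()`), used when `manifest` is `NULL`.
#' @param x_val,y_val optional validation arrays.
#' @param architecture a `cnn_architecture`.
#' @param config a `train_config`.
#' @return an object of class `filament_cnn`: the best-validation network,
#'   the per-check training `history`, the class levels and the
#'   configuration.
#' @export
filament_cnn <- function(manifest = NULL, x = NULL, y = NULL,
                         x_val = NULL, y_val = NULL,
                         architecture = cnn_profile("small"),
                         config = train_config()) {
  t0 <- Sys.time()
  classes <- particle_classes()
  if (!is.null(manifest)) {
    tr <- load_manifest_images(manifest, "train", architecture$input_side)
    va <- load_manifest_images(manifest, "val", architecture$input_side)
    x <- tr$x; y <- tr$labels; x_val <- va$x; y_val <- va$labels
  }
  stopifnot(!is.null(x), !is.null(y), dim(x)[4] == length(y))
  y <- factor(y, levels = classes)
  if (any(table(y) == 0))
    warning("training split has empty class(es): ",
            paste(classes[table(y) == 0], collapse = ", "))
  y_idx <- as.integer(y)
  has_val <- !is.null(x_val)
  yv_idx <- if (has_val) as.integer(factor(y_val, levels = classes))
  net <- build_network(architecture, seed = derive_seed(config$seed, "init"))
  adam <- adam_init(net$params)
  N <- dim(x)[4]
  side <- architecture$input_side
  best <- list(acc = -1, params = net$params, running = net$running)
  hist <- list()
  iter <- 0
  run_loss <- c()
  with_seed(derive_seed(config$seed, "trainloop"), {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- learning_rate_at(config, epoch)
      ord <- if (config$shuffle) sample.int(N) else seq_len(N)
      for (b0 in seq(1, N, by = config$batch_size)) {
        idx <- ord[b0:min(N, b0 + config$batch_size - 1)]
        xb <- x[, , , idx, drop = FALSE]
        if (!is.null(config$augment))
          for (k in seq_along(idx))
            xb[, , , k] <- augment_image(xb[, , , k], config$augment)
        fw <- forward_cnn(net, xb, training = TRUE)
        net$running <- fw$running
        sx <- softmax_xent(fw$probs, y_idx[idx])
        run_loss <- c(run_loss, sx$loss)
        bw <- backward_cnn(net, fw$cache, sx$dlogits)
        upd <- adam_step(net$params, bw$grads, adam, lr)
        net$params <- upd$params
        adam <- upd$state
        iter <- iter + 1
        if (iter %% config$val_every == 0 && has_val) {
          ev <- evaluate_loss_acc(net, x_val, yv_idx)
          hist[[length(hist) + 1]] <- data.frame(
            iteration = iter, epoch = epoch, lr = lr,
            train_loss = mean(run_loss), val_loss = ev$loss, val_acc = ev$acc)
          run_loss <- c()
          if (ev$acc >= best$acc)
            best <- list(acc = ev$acc, params = net$params,
                         running = net$running)
          if (config$verbose)
            message(sprintf("iter %d (epoch %d): train loss %.4f, val acc %.3f",
                            iter, epoch, utils::tail(hist, 1)[[1]]$train_loss,
                            ev$acc))
        }
      }
    }
  })
  if (has_val) {
    ev <- evaluate_loss_acc(net, x_val, yv_idx)
    hist[[length(hist) + 1]] <- data.frame(
      iteration = iter, epoch = config$epochs - 1L,
      lr = learning_rate_at(config, config$epochs - 1L),
      train_loss = if (length(run_loss)) mean(run_loss) else NA_real_,
      val_loss = ev$loss, val_acc = ev$acc)
    if (ev$acc >= best$acc)
      best <- list(acc = ev$acc, params = net$params, running = net$running)
    net$params <- best$params
    net$running <- best$running
  }
  structure(list(
    network = net, architecture = architecture, config = config,
    classes = classes,
    history = if (length(hist)) do.call(rbind, hist) else NULL,
    best_val_acc = if (has_val) best$acc else NA_real_,
    train_seconds = as.numeric(Sys.time() - t0, units = "secs")),
    class = "filament_cnn")
}

#' Class probabilities for new images
#'
#' Inference pass (batch-norm running moments, dropout off); deterministic.
#'
#' @param object a fitted `filament_cnn`.
#' @param newdata image array (side x side x 3 x N, or a single 3-d image).
#' @param type `"prob"` for a probability data frame with predicted class
#'   and confidence, or `"class"` for the predicted factor alone.
#' @param batch internal batch size.
#' @param ... unused.
#' @export
predict.filament_cnn <- function(object, newdata, type = c("prob", "class"),
                                 batch = 16, ...) {
  type <- match.arg(type)
  x <- newdata
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  side <- object$architecture$input_side
  if (dim(x)[1] != side || dim(x)[2] != side)
    stop("images must be ", side, " x ", side, " to match the network input")
  N <- dim(x)[4]
  probs <- matrix(0, N, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (b0 in seq(1, N, by = batch)) {
    b1 <- min(N, b0 + batch - 1)
    fw <- forward_cnn(object$network, x[, , , b0:b1, drop = FALSE],
                      training = FALSE, keep = FALSE)
    probs[b0:b1, ] <- fw$probs
  }
  cls <- factor(object$classes[max.col(probs)], levels = object$classes)
  if (type == "class") return(cls)
  out <- as.data.frame(probs)
  out$predicted <- cls
  out$confidence <- apply(probs, 1, max)
  out
}

#' @export
print.filament_cnn <- function(x, ...) {
  spec <- x$architecture
  cat(sprintf("Filament emission-event CNN (%d x %d input, %s filters, %d-unit head)\n",
              spec$input_side, spec$input_side,
              paste(vapply(spec$block_filters, paste, "", collapse = "-"),
                    collapse = "/"), spec$fc_units))
  cat(sprintf("  %s parameters; trained %d epochs in %.1f s\n",
              format(count_params(spec), big.mark = ","),
              x$config$epochs, x$train_seconds))
  if (!is.na(x$best_val_acc))
    cat(sprintf("  best validation accuracy: %.1f%%\n", 100 * x$best_val_acc))
  invisible(x)
}

#' @export
summary.filament_cnn <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nValidation checks:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.filament_cnn <- function(object, ...) object$network$params

#' Simulate class labels from the predictive distribution
#'
#' Draws class labels for `newdata` from the fitted softmax probabilities
#' (one multinomial draw per image and replicate).
#'
#' @param object a fitted `filament_cnn`.
#' @param nsim number of replicate draws.
#' @param seed optional seed.
#' @param newdata image array as in [predict.filament_cnn()].
#' @param ... unused.
#' @return data frame with one factor column per replicate.
#' @export
simulate.filament_cnn <- function(object, nsim = 1, seed = NULL,
                                  newdata, ...) {
  probs <- as.matrix(predict(object, newdata)[, object$classes])
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, {
      idx <- apply(probs, 1, function(p) sample.int(length(p), 1, prob = p))
      factor(object$classes[idx], levels = object$classes)
    }, simplify = FALSE), col.names = paste0("sim_", seq_len(nsim)))
    out
  })
}

#' Plot the training history
#' @param x a `filament_cnn`.
#' @param ... passed to `plot`.
#' @export
plot.filament_cnn <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("no training history recorded")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$iteration, h$train_loss, type = "b", xlab = "iteration",
       ylab = "loss", main = "loss", ...)
  graphics::lines(h$iteration, h$val_loss, type = "b", col = 2)
  graphics::legend("topright", c("train", "val"), col = 1:2, lty = 1, bty = "n")
  plot(h$iteration, 100 * h$val_acc, type = "b", xlab = "iteration",
       ylab = "validation accuracy (%)", main = "accuracy", ...)
  invisible(x)
}
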
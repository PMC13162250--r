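#' CNN architecture specification
#'
#' Four convolutional blocks of 3 x 3, stride-1, same-padding convolutions,
#' each convolution followed by batch normalisation and ReLU; 2 x 2 max
#' pooling (stride 2) after every block except the last; dropout before the
#' head; a fully connected ReLU layer and a fully connected softmax output
#' over the four particle classes.  The full profile takes 512 x 512 x 3
#' input through filter counts 32-32 / 64-64 / 128-128 / 256 (spatial sizes
#' 512 -> 256 -> 128 -> 64) into a 128-unit head; the small profile halves
#' the filters and head width and takes 128 x 128 input.
#'
#' @param input_side input image side; must be divisible by 8 (three pools).
#' @param block_filters list of integer vectors, one per block.
#' @param fc_units width of the fully connected hidden layer.
#' @param n_classes number of output classes.
#' @param dropout dropout rate applied after flattening, before the head.
#' @param batchnorm use batch normalisation after each convolution.
#' @return an object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(input_side = 512,
                             block_filters = list(c(32, 32), c(64, 64),
                                                  c(128, 128), 256),
                             fc_units = 128, n_classes = 4, dropout = 0.5,
                             batchnorm = TRUE) {
  n_pool <- length(block_filters) - 1
  if (input_side %% (2^n_pool) != 0)
    stop("input side must be divisible by ", 2^n_pool)
  stopifnot(fc_units >= 1, n_classes >= 2, dropout >= 0, dropout < 1)
  structure(list(input_side = as.integer(input_side),
                 in_channels = 3L,
                 block_filters = lapply(block_filters, as.integer),
                 fc_units = as.integer(fc_units),
                 n_classes = as.integer(n_classes),
                 dropout = dropout, batchnorm = batchnorm),
            class = "cnn_architecture")
}

#' Named architecture profiles
#'
#' @param profile `"full"` (512-input, 32/64/128/256 filters, 128-unit head)
#'   or `"small"` (128-input, filters and head width halved) for desk-scale
#'   runs.
#' @export
cnn_profile <- function(profile = c("small", "full")) {
  profile <- match.arg(profile)
  switch(profile,
    full = cnn_architecture(),
    small = cnn_architecture(input_side = 128,
                             block_filters = list(c(16, 16), c(32, 32),
                                                  c(64, 64), 128),
                             fc_units = 64))
}

# Flat description of the conv stack: one row per conv layer.
conv_layout <- function(spec) {
  blocks <- spec$block_filters
  rows <- list()
  in_ch <- spec$in_channels
  side <- spec$input_side
  for (b in seq_along(blocks)) {
    for (j in seq_along(blocks[[b]])) {
      rows[[length(rows) + 1]] <- data.frame(
        layer = length(rows) + 1L, block = b, pos = j,
        in_ch = in_ch, out_ch = blocks[[b]][j], side = side,
        pool_after = j == length(blocks[[b]]) && b < length(blocks))
      in_ch <- blocks[[b]][j]
    }
    if (b < length(blocks)) side <- side / 2
  }
  do.call(rbind, rows)
}

#' Feature-map side lengths at which each block operates
#'
#' The pools after blocks 1 to 3 halve the spatial size, so the default
#' full-profile blocks see 512, 256, 128 and 64 pixel sides.
#'
#' @param spec a `cnn_architecture`.
#' @return integer vector, one side per block.
#' @export
feature_map_sides <- function(spec) {
  n <- length(spec$block_filters)
  as.integer(spec$input_side / 2^(seq_len(n) - 1))
}

#' Parameter count of the architecture
#'
#' Closed-form arithmetic: each 3 x 3 convolution holds
#' `3 * 3 * in_ch * out_ch + out_ch` weights (plus `2 * out_ch` batch-norm
#' scale/shift), the head `D * fc_units + fc_units` and
#' `fc_units * n_classes + n_classes`.
#'
#' @param spec a `cnn_architecture`.
#' @param by_layer return the per-layer breakdown instead of the total.
#' @export
count_params <- function(spec, by_layer = FALSE) {
  lay <- conv_layout(spec)
  conv <- 9 * lay$in_ch * lay$out_ch + lay$out_ch
  bn <- if (spec$batchnorm) 2 * lay$out_ch else rep(0, nrow(lay))
  final_side <- spec$input_side / 2^(length(spec$block_filters) - 1)
  D <- final_side^2 * utils::tail(lay$out_ch, 1)
  fc <- c(D * spec$fc_units + spec$fc_units,
          spec$fc_units * spec$n_classes + spec$n_classes)
  if (by_layer) return(list(conv = conv, bn = bn, fc = fc))
  sum(conv) + sum(bn) + sum(fc)
}

#' Build (initialise) the network
#'
#' He-uniform fan-in initialisation for all weights, zero biases, unit
#' batch-norm scale; fully deterministic under the seed.
#'
#' @param spec a `cnn_architecture`.
#' @param seed integer seed for the weight draw.
#' @return an object of class `cnn_network`: list with `spec`, `params`
#'   (named list of arrays) and `running` (batch-norm running moments).
#' @export
build_network <- function(spec = cnn_profile("small"), seed = 1) {
  stopifnot(inherits(spec, "cnn_architecture"))
  lay <- conv_layout(spec)
  with_seed(seed, {
    params <- list()
    running <- list()
    for (i in seq_len(nrow(lay))) {
      fan_in <- 9 * lay$in_ch[i]
      lim <- sqrt(6 / fan_in)
      params[[paste0("conv", i, "_w")]] <-
        array(stats::runif(9 * lay$in_ch[i] * lay$out_ch[i], -lim, lim),
              dim = c(3, 3, lay$in_ch[i], lay$out_ch[i]))
      params[[paste0("conv", i, "_b")]] <- numeric(lay$out_ch[i])
      if (spec$batchnorm) {
        params[[paste0("bn", i, "_gamma")]] <- rep(1, lay$out_ch[i])
        params[[paste0("bn", i, "_beta")]] <- numeric(lay$out_ch[i])
        running[[paste0("bn", i, "_mean")]] <- numeric(lay$out_ch[i])
        running[[paste0("bn", i, "_var")]] <- rep(1, lay$out_ch[i])
      }
    }
    final_side <- spec$input_side / 2^(length(spec$block_filters) - 1)
    D <- final_side^2 * utils::tail(lay$out_ch, 1)
    lim <- sqrt(6 / D)
    params$fc1_w <- matrix(stats::runif(D * spec$fc_units, -lim, lim),
                           D, spec$fc_units)
    params$fc1_b <- numeric(spec$fc_units)
    lim <- sqrt(6 / spec$fc_units)
    params$fc2_w <- matrix(stats::runif(spec$fc_units * spec$n_classes, -lim, lim),
                           spec$fc_units, spec$n_classes)
    params$fc2_b <- numeric(spec$n_classes)
    structure(list(spec = spec, params = params, running = running,
                   layout = lay), class = "cnn_network")
  })
}

# Per-layer parameter list handed to the native stack kernels.
stack_layers <- function(net) {
  lay <- net$layout
  P <- net$params
  lapply(seq_len(nrow(lay)), function(i) {
    list(w = P[[paste0("conv", i, "_w")]], b = P[[paste0("conv", i, "_b")]],
         gamma = if (net$spec$batchnorm) P[[paste0("bn", i, "_gamma")]],
         beta = if (net$spec$batchnorm) P[[paste0("bn", i, "_beta")]],
         bn = net$spec$batchnorm, pool = lay$pool_after[i])
  })
}

# Forward pass.  x: (side, side, 3, N).  training = TRUE uses batch
# statistics (and returns updated running moments) and applies the given
# dropout mask; inference uses running moments, no dropout.
# keep = TRUE retains the native-layer cache for the backward pass.
forward_cnn <- function(net, x, training = FALSE, dropout_mask = NULL,
                        keep = training) {
  spec <- net$spec
  P <- net$params
  eps <- 1e-5
  st <- fs_stack_fwd(x, stack_layers(net), training, eps, 0.9, net$running)
  a <- st$out
  cache <- if (keep) list(handle = st$cache) else NULL
  d <- dim(a)
  N <- d[4]
  flat <- matrix(a, nrow = prod(d[1:3]), ncol = N)   # D x N
  if (training && spec$dropout > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix((stats::runif(length(flat)) >= spec$dropout) /
                               (1 - spec$dropout), nrow(flat), N)
    flat_d <- flat * dropout_mask
  } else {
    dropout_mask <- NULL
    flat_d <- flat
  }
  h_pre <- crossprod(flat_d, P$fc1_w) + matrix(P$fc1_b, N, spec$fc_units, byrow = TRUE)
  h <- h_pre * (h_pre > 0)
  logits <- h %*% P$fc2_w + matrix(P$fc2_b, N, spec$n_classes, byrow = TRUE)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  if (keep) {
    cache$flat <- flat; cache$flat_d <- flat_d; cache$dropout_mask <- dropout_mask
    cache$h_pre <- h_pre; cache$h <- h
    cache$top_dim <- d
  }
  list(logits = logits, probs = probs, cache = cache,
       running = if (training) st$running else net$running)
}

# Backward pass from d(loss)/d(logits).  Returns parameter gradients; if
# capture_relu is a conv-layer index, also returns the gradient at that
# layer's ReLU output (as used by Grad-CAM).
backward_cnn <- function(net, cache, dlogits, capture_relu = NULL) {
  spec <- net$spec
  P <- net$params
  eps <- 1e-5
  grads <- list()
  grads$fc2_w <- crossprod(cache$h, dlogits)
  grads$fc2_b <- colSums(dlogits)
  dh <- dlogits %*% t(P$fc2_w)
  dh <- dh * (cache$h_pre > 0)
  grads$fc1_w <- cache$flat_d %*% dh
  grads$fc1_b <- colSums(dh)
  dflat <- P$fc1_w %*% t(dh)                     # D x N
  if (!is.null(cache$dropout_mask)) dflat <- dflat * cache$dropout_mask
  da <- array(dflat, dim = cache$top_dim)
  bw <- fs_stack_bwd(cache$handle, stack_layers(net), da, eps,
                     if (is.null(capture_relu)) 0L else as.integer(capture_relu))
  for (i in seq_len(nrow(net$layout))) {
    grads[[paste0("conv", i, "_w")]] <- bw$grads[[i]]$dw
    grads[[paste0("conv", i, "_b")]] <- bw$grads[[i]]$db
    if (spec$batchnorm) {
      grads[[paste0("bn", i, "_gamma")]] <- bw$grads[[i]]$dgamma
      grads[[paste0("bn", i, "_beta")]] <- bw$grads[[i]]$dbeta
    }
  }
  list(grads = grads, captured = bw$captured)
}

# Cross-entropy loss and its logit gradient from one-hot labels.
softmax_xent <- function(probs, y_idx) {
  N <- nrow(probs)
  p_true <- probs[cbind(seq_len(N), y_idx)]
  loss <- -mean(log(pmax(p_true, 1e-12)))
  dlogits <- probs
  dlogits[cbind(seq_len(N), y_idx)] <- dlogits[cbind(seq_len(N), y_idx)] - 1
  list(loss = loss, dlogits = dlogits / N)
}
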
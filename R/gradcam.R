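#' Grad-CAM saliency heatmap
#'
#' Channel weights are the spatial averages of the gradient of the target
#' class's pre-softmax score with respect to a chosen ReLU activation; the
#' heatmap is the ReLU of the weighted channel sum, bilinearly upsampled to
#' the input size and max-normalised to \[0, 1\].  The default layer is the
#' second ReLU of the third convolutional block, a mid-level layer that
#' keeps fine spatial detail while carrying class-discriminative features.
#'
#' @param model a fitted `filament_cnn` (or a raw `cnn_network`).
#' @param image one input image (side x side x 3 array in \[0, 1\]).
#' @param target_class class whose score is explained; defaults to the
#'   predicted class.
#' @param layer conv-layer index whose ReLU output is used; default the
#'   second layer of block 3.
#' @return a `side x side` heatmap matrix in \[0, 1\].
#' @export
gradcam <- function(model, image, target_class = NULL, layer = NULL) {
  net <- if (inherits(model, "filament_cnn")) model$network else model
  stopifnot(inherits(net, "cnn_network"))
  lay <- net$layout
  if (is.null(layer)) {
    cand <- which(lay$block == 3 & lay$pos == 2)
    if (!length(cand))
      stop("architecture has no second layer in block 3; pass `layer`")
    layer <- cand
  }
  if (!layer %in% lay$layer) stop("invalid conv layer index: ", layer)
  d <- dim(image)
  stopifnot(length(d) == 3, d[3] == 3)
  x <- array(image, c(d, 1))
  fw <- forward_cnn(net, x, training = FALSE, keep = TRUE)
  classes <- particle_classes()
  if (is.null(target_class)) {
    tc <- which.max(fw$probs[1, ])
  } else {
    tc <- match(target_class, classes)
    if (is.na(tc)) stop("unknown target class: ", target_class)
  }
  dlogits <- matrix(0, 1, net$spec$n_classes)
  dlogits[1, tc] <- 1
  bw <- backward_cnn(net, fw$cache, dlogits, capture_relu = layer)
  A <- fs_stack_relu(fw$cache$handle, layer)   # (h, w, K, 1)
  G <- bw$captured
  K <- dim(A)[3]
  wts <- vapply(seq_len(K), function(k) mean(G[, , k, 1]), numeric(1))
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(K)) cam <- cam + wts[k] * A[, , k, 1]
  cam[cam < 0] <- 0
  up <- fs_resize_bilinear(array(cam, c(dim(cam), 1L)), d[1], d[2])[, , 1]
  mx <- max(up)
  if (mx > 0) up <- up / mx
  up
}

#' Extract the most salient square patches from a heatmap
#'
#' Greedy selection of up to `k` local maxima with non-overlap suppression:
#' the window around the current global maximum is accepted only if it does
#' not overlap an already selected window (ties in the heatmap are broken
#' row-major: topmost row first, then leftmost column).  Windows that would
#' cross the border are re-centred to fit inside the frame.
#'
#' @param image the source image (side x side x 3).
#' @param heatmap matching heatmap matrix from [gradcam()].
#' @param k number of patches requested.
#' @param patch_side window side in pixels (64 at full resolution; scale
#'   with the input side for reduced profiles).
#' @return list of patches, each a list with `img` (patch array), `row`,
#'   `col` (0-based top-left corner) and `side`; fewer than `k` if no more
#'   disjoint windows fit.
#' @export
extract_patches <- function(image, heatmap, k = 3, patch_side = 64) {
  d <- dim(image)
  stopifnot(nrow(heatmap) == d[1], ncol(heatmap) == d[2],
            patch_side <= min(d[1:2]))
  h <- heatmap
  sel <- list()
  win <- matrix(numeric(0), 0, 2)  # selected 0-based top-left corners
  while (length(sel) < k && any(is.finite(h)) && max(h, na.rm = TRUE) > -Inf) {
    mx <- max(h)
    if (!is.finite(mx)) break
    cand <- which(h == mx, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]  # row-major
    r <- cand[1, 1]; c <- cand[1, 2]
    r0 <- min(max(r - 1 - floor(patch_side / 2), 0), d[1] - patch_side)
    c0 <- min(max(c - 1 - floor(patch_side / 2), 0), d[2] - patch_side)
    overlaps <- nrow(win) > 0 &&
      any(abs(win[, 1] - r0) < patch_side & abs(win[, 2] - c0) < patch_side)
    if (!overlaps) {
      sel[[length(sel) + 1]] <- list(
        img = image[(r0 + 1):(r0 + patch_side),
                    (c0 + 1):(c0 + patch_side), , drop = FALSE],
        row = r0, col = c0, side = patch_side)
      win <- rbind(win, c(r0, c0))
      h[(r0 + 1):(r0 + patch_side), (c0 + 1):(c0 + patch_side)] <- -Inf
    } else {
      h[r, c] <- -Inf
    }
  }
  sel
}

#' Chromaticity of the brightest pixels of a patch
#'
#' Brightness is `R + G + B`; the `n_pixels` brightest non-black pixels map
#' to red-green chromaticity `(r, g) = (R, G) / (R + G + B)` (ties broken by
#' column-major pixel order; fewer points are returned when fewer non-black
#' pixels exist).
#'
#' @param patch an image patch (h x w x 3 array), or a patch list from
#'   [extract_patches()].
#' @param n_pixels number of brightest pixels to keep (default 30).
#' @return data frame with columns `r`, `g`, `brightness`; zero rows for an
#'   all-black patch (with a warning).
#' @export
patch_chromaticity <- function(patch, n_pixels = 30) {
  if (is.list(patch)) patch <- patch$img
  d <- dim(patch)
  stopifnot(length(d) == 3, d[3] == 3)
  s <- patch[, , 1] + patch[, , 2] + patch[, , 3]
  pos <- which(s > 0)
  if (!length(pos)) {
    warning("all-black patch: no chromaticity points")
    return(data.frame(r = numeric(0), g = numeric(0), brightness = numeric(0)))
  }
  top <- pos[order(s[pos], decreasing = TRUE)][seq_len(min(n_pixels, length(pos)))]
  data.frame(r = patch[, , 1][top] / s[top],
             g = patch[, , 2][top] / s[top],
             brightness = s[top])
}

#' Fraction of Grad-CAM mass inside the filament band
#'
#' Localisation summary: for each correctly classified non-blank image, the
#' share of total heatmap mass lying in the horizontal band around the
#' filament stripe, averaged over images.
#'
#' @param model a fitted `filament_cnn`.
#' @param x image array (side x side x 3 x N).
#' @param labels true labels.
#' @param predicted optional predicted classes.
#' @param band_rows integer rows of the filament band (1-based); defaults to
#'   the central quarter of the image.
#' @return mean band mass fraction in \[0, 1\].
#' @export
gradcam_band_mass <- function(model, x, labels, predicted = NULL,
                              band_rows = NULL) {
  side <- model$architecture$input_side
  band_rows <- band_rows %||% seq(round(side * 3 / 8), round(side * 5 / 8))
  if (is.null(predicted)) predicted <- predict(model, x, type = "class")
  labels <- factor(labels, levels = model$classes)
  masses <- c()
  for (i in seq_len(dim(x)[4])) {
    if (labels[i] == "blank" || predicted[i] != labels[i]) next
    hm <- gradcam(model, x[, , , i], target_class = as.character(labels[i]))
    if (sum(hm) > 0)
      masses <- c(masses, sum(hm[band_rows, ]) / sum(hm))
  }
  mean(masses)
}

#' Grad-CAM chromaticity points for a set of classified images
#'
#' For each correctly classified image: compute the Grad-CAM heatmap for its
#' true class, extract the `k` most intense patches, and collect the
#' chromaticity of the top `n_pixels` brightest pixels of each patch.
#'
#' @param model a fitted `filament_cnn`.
#' @param x image array (side x side x 3 x N).
#' @param labels true labels (factor over the particle classes).
#' @param predicted optional predicted classes (computed if missing).
#' @param k,patch_side,n_pixels patch selection parameters; `patch_side`
#'   defaults to 64 scaled by `input_side / 512`.
#' @param layer Grad-CAM layer (default as in [gradcam()]).
#' @return data frame with columns `r`, `g`, `class`, `image`, `patch`.
#' @export
chroma_points <- function(model, x, labels, predicted = NULL, k = 3,
                          patch_side = NULL, n_pixels = 30, layer = NULL) {
  side <- model$architecture$input_side
  patch_side <- patch_side %||% max(8, round(64 * side / 512))
  if (is.null(predicted)) predicted <- predict(model, x, type = "class")
  labels <- factor(labels, levels = model$classes)
  out <- list()
  for (i in seq_len(dim(x)[4])) {
    if (predicted[i] != labels[i]) next
    img <- x[, , , i]
    hm <- gradcam(model, img, target_class = as.character(labels[i]),
                  layer = layer)
    patches <- extract_patches(img, hm, k = k, patch_side = patch_side)
    for (j in seq_along(patches)) {
      pts <- suppressWarnings(patch_chromaticity(patches[[j]], n_pixels))
      if (nrow(pts))
        out[[length(out) + 1]] <- data.frame(
          r = pts$r, g = pts$g, class = as.character(labels[i]),
          image = i, patch = j)
    }
  }
  if (!length(out))
    return(data.frame(r = numeric(0), g = numeric(0), class = character(0),
                      image = integer(0), patch = integer(0)))
  do.call(rbind, out)
}
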
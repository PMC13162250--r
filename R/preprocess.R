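#' Crop a frame into two square segments
#'
#' A `width x height` frame is cut into left and right square segments of
#' side `width / 2`, vertically centred so the filament band is retained in
#' both: for the full-resolution 1920 x 1200 frame this is columns
#' \[0, 960) / \[960, 1920) and rows \[120, 1080) in 0-based, half-open
#' pixel coordinates.
#'
#' @param frame a `labeled_image` or a height x width x 3 array.
#' @return list with elements `left` and `right` (side x side x 3 arrays).
#' @export
crop_segments <- function(frame) {
  px <- if (inherits(frame, "labeled_image")) frame$pixels else frame
  d <- dim(px)
  if (length(d) != 3 || d[3] != 3)
    stop("frame must be a height x width x 3 array")
  H <- d[1]; W <- d[2]
  side <- W / 2
  if (side != floor(side) || side > H)
    stop("frame width must be even and at most twice the height")
  r0 <- (H - side) / 2  # 0-based first row of the retained band
  if (r0 != floor(r0))
    stop("frame height minus width/2 must be even")
  rows <- (r0 + 1):(r0 + side)
  list(left = px[rows, 1:side, , drop = FALSE],
       right = px[rows, (side + 1):W, , drop = FALSE])
}

#' Bilinear image resize
#'
#' Pixel-centre bilinear interpolation to a square `side x side` output.
#' Interpolation cannot leave the input value range.
#'
#' @param image height x width x channels array (or a matrix).
#' @param side output side length, at least 8.
#' @return resized array.
#' @export
resize_image <- function(image, side) {
  stopifnot(side >= 8)
  m <- FALSE
  if (is.matrix(image)) { image <- array(image, c(dim(image), 1L)); m <- TRUE }
  out <- fs_resize_bilinear(image, as.integer(side), as.integer(side))
  if (m) out <- out[, , 1]
  out
}

#' Training augmentation policy
#'
#' Random horizontal/vertical reflection, rotation within +/- `rotate_deg`
#' degrees, independent per-axis scaling within `scale_range`, and vertical
#' translation within +/- (input height / 8) pixels.  Horizontal translation
#' is always disabled: shifting along the filament axis could move emission
#' events out of the frame.
#'
#' @param reflect_x,reflect_y enable random reflections.
#' @param rotate_deg rotation half-range in degrees.
#' @param scale_range per-axis scale factor range.
#' @param translate_frac vertical translation bound as a fraction of the
#'   input height; the study policy uses exactly 1/8.  Set to 0 to disable.
#' @return an object of class `augment_policy`.
#' @export
augment_policy <- function(reflect_x = TRUE, reflect_y = TRUE,
                           rotate_deg = 5, scale_range = c(0.95, 1.05),
                           translate_frac = 1 / 8) {
  stopifnot(rotate_deg >= 0, diff(scale_range) >= 0, translate_frac >= 0)
  structure(list(reflect_x = reflect_x, reflect_y = reflect_y,
                 rotate_deg = rotate_deg, scale_range = scale_range,
                 translate_frac = translate_frac), class = "augment_policy")
}

#' Draw one set of augmentation parameters
#'
#' @param policy an `augment_policy`.
#' @param height input image height in pixels (sets the vertical translation
#'   bound `height / 8`).
#' @param seed optional seed.
#' @return list with `flip_x`, `flip_y`, `angle_deg`, `scale_x`, `scale_y`,
#'   `shift_y`, `shift_x` (always 0).
#' @export
sample_augment_params <- function(policy, height, seed = NULL) {
  stopifnot(inherits(policy, "augment_policy"))
  with_seed(seed, {
    list(flip_x = policy$reflect_x && stats::runif(1) < 0.5,
         flip_y = policy$reflect_y && stats::runif(1) < 0.5,
         angle_deg = stats::runif(1, -policy$rotate_deg, policy$rotate_deg),
         scale_x = stats::runif(1, policy$scale_range[1], policy$scale_range[2]),
         scale_y = stats::runif(1, policy$scale_range[1], policy$scale_range[2]),
         shift_y = stats::runif(1, -height * policy$translate_frac,
                                height * policy$translate_frac),
         shift_x = 0)
  })
}

# Build the output->input affine map for a parameter draw and apply it in a
# single bilinear resample with symmetric (mirror) padding.  Transform order
# (as forward operations about the image centre): reflect, rotate, scale,
# then vertical translate.
apply_augment_params <- function(image, par) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  th <- par$angle_deg * pi / 180
  Fl <- diag(c(if (par$flip_y) -1 else 1, if (par$flip_x) -1 else 1))
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sc <- diag(c(par$scale_y, par$scale_x))
  A <- Sc %*% Rot %*% Fl              # forward: v' = A (v - ctr) + ctr + t
  Ainv <- solve(A)
  t_vec <- c(par$shift_y, par$shift_x)
  offset <- as.numeric(ctr - Ainv %*% (ctr + t_vec))
  M <- cbind(Ainv, offset)            # source = Ainv %*% dest + offset
  fs_affine_warp(image, M)
}

#' Apply one random augmentation draw to a square image
#'
#' @param image square height x width x channels array.
#' @param policy an `augment_policy`.
#' @param seed optional seed.
#' @return augmented image, same dimensions and value range.
#' @export
augment_image <- function(image, policy = augment_policy(), seed = NULL) {
  d <- dim(image)
  stopifnot(length(d) == 3, d[1] == d[2])
  par <- sample_augment_params(policy, d[1], seed)
  apply_augment_params(image, par)
}
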
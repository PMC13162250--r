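#' Dataset configuration
#'
#' Curated per-class image counts default to blank 71, chalk 59, pollen 63,
#' salt 33 (226 total), split 180 train / 46 val (stratified by class), with
#' an additional 26-image held-out test set and a 107-image reduced-power
#' robustness set (25/28/27/27) rendered at power fraction 0.85.
#'
#' @param out_dir directory the image files are written to.
#' @param counts named per-class curated counts.
#' @param n_val total validation count (stratified largest-remainder split).
#' @param test_counts per-class held-out test counts (sum 26).
#' @param robustness_counts per-class robustness counts (sum 107).
#' @param robustness_power power fraction of the robustness set.
#' @param scene a `scene_config`; the desk-scale default renders 256 x 160
#'   frames whose crop segments are 128 x 128 (use [scene_config()] for
#'   full-resolution frames).
#' @param camera a `camera_model`.
#' @param seed master seed for rendering and splitting.
#' @return an object of class `dataset_config`.
#' @export
dataset_config <- function(out_dir = tempfile("filasense_data_"),
                           counts = c(blank = 71, chalk = 59, pollen = 63, salt = 33),
                           n_val = 46,
                           test_counts = c(blank = 7, chalk = 7, pollen = 6, salt = 6),
                           robustness_counts = c(blank = 25, chalk = 28, pollen = 27, salt = 27),
                           robustness_power = 0.85,
                           scene = scene_config_small(),
                           camera = camera_model(),
                           seed = 1) {
  stopifnot(all(counts >= 1), n_val < sum(counts), all(test_counts >= 0),
            all(robustness_counts >= 0), robustness_power > 0,
            robustness_power <= 1)
  for (nm in list(counts, test_counts, robustness_counts))
    stopifnot(identical(sort(names(nm)), sort(particle_classes())))
  structure(list(out_dir = out_dir, counts = counts, n_val = n_val,
                 test_counts = test_counts,
                 robustness_counts = robustness_counts,
                 robustness_power = robustness_power, scene = scene,
                 camera = camera, seed = seed), class = "dataset_config")
}

# Largest-remainder stratified allocation of n_val validation images.
val_allocation <- function(counts, n_val) {
  exact <- counts * n_val / sum(counts)
  base <- floor(exact)
  rem <- n_val - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

# A segment passes curation when the class is blank or at least one emission
# event centre falls inside the segment (mirrors manual curation of frames
# that actually contain events).
segment_has_event <- function(frame, side, r0, c_range) {
  ev <- frame$events
  if (!nrow(ev)) return(FALSE)
  any(ev$x >= c_range[1] & ev$x <= c_range[2] &
        ev$y >= r0 + 1 & ev$y <= r0 + side)
}

# Render frames for one class until `n` curated segments are collected.
collect_segments <- function(class_label, n, scene, camera, power, seed) {
  out <- vector("list", n)
  seeds <- integer(n)
  got <- 0
  frame_idx <- 0
  sc <- scene
  sc$power_fraction <- power
  W <- sc$width; H <- sc$height; side <- W / 2
  r0 <- (H - side) / 2
  while (got < n) {
    frame_idx <- frame_idx + 1
    fseed <- derive_seed(seed, paste0(class_label, "_frame_", frame_idx))
    fr <- render_frame(class_label, sc, camera, seed = fseed)
    segs <- crop_segments(fr)
    ranges <- list(left = c(1, side), right = c(side + 1, W))
    for (s in c("left", "right")) {
      if (got >= n) break
      ok <- class_label == "blank" ||
        segment_has_event(fr, side, r0, ranges[[s]])
      if (ok) {
        got <- got + 1
        out[[got]] <- segs[[s]]
        seeds[got] <- fseed
      }
    }
    if (frame_idx > 50 * n + 100)
      stop("curation failed to fill the quota; check event means")
  }
  list(segments = out, seeds = seeds)
}

#' Build a curated, split image dataset
#'
#' Renders frames per class, crops each into two square segments, curates
#' segments (non-blank segments must contain at least one emission event),
#' writes the curated/test/robustness segments as 8-bit PNG files in class
#' folders, and returns the manifest with train/val/test/robustness splits.
#' Byte-identical output under a fixed seed.
#'
#' @param config a `dataset_config`.
#' @param seed master seed (defaults to `config$seed`).
#' @return a `dataset_manifest`: data frame with columns `path`, `label`,
#'   `split`, `power_fraction`, `frame_seed`, plus attributes recording the
#'   configuration; also written as `manifest.csv` in `out_dir`.
#' @export
build_image_dataset <- function(config = dataset_config(), seed = config$seed) {
  stopifnot(inherits(config, "dataset_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  classes <- particle_classes()
  val_n <- val_allocation(config$counts[classes], config$n_val)
  rows <- list()
  for (cl in classes) {
    n_cur <- config$counts[[cl]]
    n_test <- config$test_counts[[cl]]
    n_rob <- config$robustness_counts[[cl]]
    cur <- collect_segments(cl, n_cur + n_test, config$scene, config$camera,
                            power = 1, seed = derive_seed(seed, paste0(cl, "_main")))
    rob <- if (n_rob > 0) {
      collect_segments(cl, n_rob, config$scene, config$camera,
                       power = config$robustness_power,
                       seed = derive_seed(seed, paste0(cl, "_robust")))
    } else list(segments = list(), seeds = integer(0))
    # stratified val draw within the curated block
    idx_val <- with_seed(derive_seed(seed, paste0(cl, "_split")),
                         sort(sample.int(n_cur, val_n[[cl]])))
    split <- rep("train", n_cur)
    split[idx_val] <- "val"
    split <- c(split, rep("test", n_test), rep("robustness", n_rob))
    segs <- c(cur$segments, rob$segments)
    fseeds <- c(cur$seeds, rob$seeds)
    power <- c(rep(1, n_cur + n_test), rep(config$robustness_power, n_rob))
    cls_dir <- file.path(config$out_dir, cl)
    dir.create(cls_dir, showWarnings = FALSE)
    for (i in seq_along(segs)) {
      path <- file.path(cls_dir, sprintf("%s_%s_%03d.png", cl, split[i], i))
      png::writePNG(segs[[i]], path)
      rows[[length(rows) + 1]] <- data.frame(
        path = path, label = cl, split = split[i], power_fraction = power[i],
        frame_seed = fseeds[i], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "counts") <- config$counts
  attr(manifest, "seed") <- seed
  attr(manifest, "segment_side") <- config$scene$width / 2
  class(manifest) <- c("dataset_manifest", "data.frame")
  utils::write.csv(as.data.frame(manifest), file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a manifest CSV written by [build_image_dataset()]
#' @param path path to `manifest.csv`.
#' @export
read_manifest <- function(path) {
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(manifest) <- c("dataset_manifest", "data.frame")
  manifest
}

#' Load manifest images into a batch array
#'
#' Reads the PNG segments of the requested splits and resizes them to the
#' network input side.
#'
#' @param manifest a `dataset_manifest`.
#' @param splits character vector of splits to load.
#' @param input_side target side length.
#' @return list with `x` (side x side x 3 x N array) and `labels` (factor
#'   over the four classes).
#' @export
load_manifest_images <- function(manifest, splits, input_side) {
  sel <- manifest[manifest$split %in% splits, , drop = FALSE]
  if (!nrow(sel)) stop("no images in split(s): ", paste(splits, collapse = ", "))
  x <- array(0, dim = c(input_side, input_side, 3, nrow(sel)))
  for (i in seq_len(nrow(sel))) {
    img <- png::readPNG(sel$path[i])
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3]
    if (dim(img)[1] != input_side)
      img <- resize_image(img, input_side)
    x[, , , i] <- img
  }
  list(x = x, labels = factor(sel$label, levels = particle_classes()),
       paths = sel$path)
}
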
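#' Experiment configuration
#'
#' One master seed drives every stage (dataset rendering, weight
#' initialisation, shuffling, augmentation, dropout, analysis subsampling)
#' through [derive_seed()].  The configuration round-trips losslessly
#' through YAML via [write_experiment_config()] / [read_experiment_config()].
#'
#' @param seed master seed.
#' @param out_dir output directory for images, tables and the report.
#' @param profile architecture profile, `"small"` or `"full"`.
#' @param epochs training epochs (default 30 for small, 60 for full).
#' @param analyses named logical toggles: `gradcam`, `morphology`, `onset`.
#' @param morphology_n particles per class in the morphology stage.
#' @param morphology_pixel_scale micrometres per pixel for the morphology
#'   stage (coarser than the microscope default to keep the slide small).
#' @param dataset optional `dataset_config` overriding the default dataset
#'   (its `seed` and `out_dir` are still derived from this configuration).
#' @param architecture optional `cnn_architecture` overriding the profile.
#' @param train optional `train_config` overriding the study schedule (its
#'   seed is still derived from this configuration's master seed).
#' @param verbose print stage progress.
#' @return an object of class `experiment_config` (a named list).
#' @export
experiment_config <- function(seed = 1, out_dir = tempfile("filasense_run_"),
                              profile = c("small", "full"), epochs = NULL,
                              analyses = c(gradcam = TRUE, morphology = TRUE,
                                           onset = TRUE),
                              morphology_n = 80,
                              morphology_pixel_scale = 0.5,
                              dataset = NULL, architecture = NULL,
                              train = NULL, verbose = FALSE) {
  profile <- match.arg(profile)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 profile = profile,
                 epochs = epochs %||% if (profile == "small") 30L else 60L,
                 analyses = as.list(analyses), morphology_n = morphology_n,
                 morphology_pixel_scale = morphology_pixel_scale,
                 dataset = dataset, architecture = architecture,
                 train = train, verbose = verbose),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config an `experiment_config`.
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- experiment_config(seed = raw$seed, out_dir = raw$out_dir,
                           profile = raw$profile, epochs = raw$epochs,
                           morphology_n = raw$morphology_n,
                           morphology_pixel_scale = raw$morphology_pixel_scale,
                           verbose = isTRUE(raw$verbose))
  cfg$analyses <- raw$analyses
  cfg
}

#' Run the full study on synthetic data
#'
#' Executes simulate -> preprocess -> train -> evaluate (full-power test set
#' and reduced-power robustness set) -> Grad-CAM chromaticity cluster
#' analysis -> dark-field morphology -> broadening-onset detection, and
#' writes a single JSON report with every computed metric plus a snapshot
#' of the configuration.  Deterministic: two runs with the same
#' configuration produce identical reports.
#'
#' @param config an [experiment_config()].
#' @return the report, invisibly also written to `out_dir/report.json`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  seed <- config$seed
  arch <- config$architecture %||% cnn_profile(config$profile)
  scene <- if (config$profile == "small") scene_config_small() else scene_config()

  say("stage 1/6: rendering dataset")
  ds_cfg <- config$dataset %||%
    dataset_config(scene = scene)
  ds_cfg$out_dir <- file.path(config$out_dir, "images")
  ds_cfg$seed <- derive_seed(seed, "dataset")
  manifest <- build_image_dataset(ds_cfg)

  say("stage 2/6: training CNN (%d epochs)", config$epochs)
  tc <- config$train %||%
    train_config(epochs = config$epochs, verbose = config$verbose)
  tc$seed <- derive_seed(seed, "train")
  model <- filament_cnn(manifest, architecture = arch, config = tc)

  say("stage 3/6: evaluating held-out test set")
  test <- load_manifest_images(manifest, "test", arch$input_side)
  test_pred <- predict(model, test$x)
  cm_test <- confusion_matrix(test_pred$predicted, test$labels)
  m_test <- classification_metrics(cm_test, test_pred)

  say("stage 4/6: evaluating reduced-power robustness set")
  rob <- load_manifest_images(manifest, "robustness", arch$input_side)
  rob_pred <- predict(model, rob$x)
  cm_rob <- confusion_matrix(rob_pred$predicted, rob$labels)
  m_rob <- classification_metrics(cm_rob, rob_pred)

  chroma <- NULL
  if (isTRUE(config$analyses$gradcam)) {
    say("stage 5a/6: Grad-CAM chromaticity analysis")
    pts <- chroma_points(model, test$x, test$labels,
                         predicted = test_pred$predicted)
    utils::write.csv(pts, file.path(config$out_dir, "chromaticity.csv"),
                     row.names = FALSE)
    if (nrow(pts) < 2 || length(unique(pts$class)) < 2)
      stop("chromaticity analysis needs correctly classified test images ",
           "of at least two classes; the model is too weak (", nrow(pts),
           " points)")
    sil <- silhouette_stats(pts[, c("r", "g")], pts$class)
    mah <- mahalanobis_distances(pts[, c("r", "g")], pts$class)
    cents <- t(vapply(split(pts[, c("r", "g")], pts$class), colMeans,
                      numeric(2)))
    band <- round(arch$input_side / 2 +
                    c(-3, 3) * ds_cfg$scene$stripe_thickness *
                      arch$input_side / (ds_cfg$scene$width / 2))
    chroma <- list(silhouette = list(
                     weighted_mean = sil$weighted_mean, ci95 = sil$ci95,
                     per_class = sil$per_class),
                   mahalanobis = mah,
                   centroids = cents,
                   stripe_band_mass = gradcam_band_mass(
                     model, test$x, test$labels,
                     predicted = test_pred$predicted,
                     band_rows = band[1]:band[2]))
  }

  morph <- NULL
  if (isTRUE(config$analyses$morphology)) {
    say("stage 5b/6: dark-field morphology")
    sl <- slide_config(pixel_scale = config$morphology_pixel_scale)
    morph <- lapply(c("chalk", "pollen", "salt"), function(cl) {
      slide <- render_darkfield_slide(cl, config$morphology_n, sl,
                                      seed = derive_seed(seed, paste0("slide_", cl)))
      tab <- segment_particles(slide$image, sl$pixel_scale)
      list(class = cl, n_truth = nrow(slide$particles), n_segmented = nrow(tab),
           mean_d_eq_um = mean(tab$d_eq_um),
           mean_circularity = mean(tab$circularity),
           mean_eccentricity = mean(tab$eccentricity),
           truth_mean_d_eq_um = mean(slide$particles$d_eq_um))
    })
    names(morph) <- c("chalk", "pollen", "salt")
    morph$sampler <- unclass(sampler_stats(342, 10, 9))
  }

  onset <- NULL
  if (isTRUE(config$analyses$onset)) {
    say("stage 5c/6: broadening-onset detection")
    series <- generate_power_series()
    onset <- list(detected_power_pct = 100 * detect_onset(series),
                  n_powers = length(series))
  }

  say("stage 6/6: writing report")
  strip_s3 <- function(x) {
    if (is.object(x) && !is.data.frame(x)) x <- unclass(x)
    if (is.list(x) && !is.data.frame(x)) x[] <- lapply(x, strip_s3)
    x
  }
  report <- list(
    config = strip_s3(config),
    dataset = list(curated = sum(attr(manifest, "counts")),
                   train = sum(manifest$split == "train"),
                   val = sum(manifest$split == "val"),
                   test = sum(manifest$split == "test"),
                   robustness = sum(manifest$split == "robustness")),
    training = list(best_val_acc_pct = 100 * model$best_val_acc,
                    final_train_loss = utils::tail(model$history$train_loss, 1)),
    test = list(confusion_percent = cm_test$percent,
                per_class = m_test$per_class,
                mean_accuracy_pct = m_test$mean_accuracy_pct,
                mean_f1 = m_test$mean_f1),
    robustness = list(confusion_percent = cm_rob$percent,
                      per_class = m_rob$per_class,
                      mean_accuracy_pct = m_rob$mean_accuracy_pct,
                      mean_f1 = m_rob$mean_f1),
    chroma = chroma,
    morphology = morph,
    onset = onset,
    # quantities that follow from printed inputs by direct arithmetic but
    # differ from rounded published figures; reported, not reconciled
    arithmetic_notes = list(
      concentration_direct_m3 = 342 / 0.09,
      reduced_power_recall_mean_pct = mean(c(93.5, 96.4, 70.4, 97.2)),
      peak_intensity_1mJ_Wcm2 = peak_intensity(laser_params(1.0))))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
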
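# Shared fixtures, built once per test run and memoised.

.fs_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fs_cache)) assign(key, force(expr), envir = .fs_cache)
  get(key, envir = .fs_cache)
}

# Miniature scene for fast rendering where only statistics matter.
mini_scene <- function(...) {
  defaults <- list(width = 64, height = 40, stripe_thickness = 2,
                   event_sigma_range = c(1, 1.8))
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}

# Reduced architecture (32 px input) for fast end-to-end property tests.
tiny_architecture <- function() {
  cnn_architecture(input_side = 32,
                   block_filters = list(c(8, 8), c(16, 16), c(24, 24), 32),
                   fc_units = 24)
}

tiny_dataset <- function() {
  memo("tiny_dataset", {
    cfg <- dataset_config(
      out_dir = file.path(tempdir(), "fs_tiny_data"),
      counts = c(blank = 25, chalk = 25, pollen = 25, salt = 25), n_val = 40,
      test_counts = c(blank = 5, chalk = 5, pollen = 5, salt = 5),
      robustness_counts = c(blank = 5, chalk = 5, pollen = 5, salt = 5),
      scene = mini_scene(), seed = 401)
    build_image_dataset(cfg)
  })
}

# Quick model fitted on the tiny dataset (higher learning rate than the
# study protocol purely to converge fast at this scale).
tiny_model <- function() {
  memo("tiny_model", {
    filament_cnn(tiny_dataset(), architecture = tiny_architecture(),
                 config = train_config(epochs = 25, lr = 1e-3, val_every = 50,
                                       seed = 402))
  })
}

# Slide fixtures for morphology statistics (coarser pixel scale keeps the
# slide small; the size/shape distributions are scale-free in micrometres).
slide_fixture <- function(class_label, n = 500, pixel_scale = 0.5) {
  memo(paste0("slide_", class_label, "_", n, "_", pixel_scale), {
    sl <- slide_config(pixel_scale = pixel_scale)
    render_darkfield_slide(class_label, n, sl, seed = 77)
  })
}
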
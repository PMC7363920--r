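# Shared fixtures: a small imagelet geometry and one quickly trained network,
# built once per test run.

deg2rad <- function(x) x * pi / 180

# 32 px imagelets keep unit-test trainings fast; the field of view matches
# the 64 px default (coarser pitch).
quick_params <- function(...) imagelet_params(size = 32L, ...)

# noise-free, centered circular head: the silhouette is a pure oriented
# ellipse plus an isotropic disc, so moment analysis is exact up to pixels
clean_params <- function(size = 64L) imagelet_params(
  size = size, head_offset_m = 0, noise_sd_mm = 0, dropout = 0,
  head_ax_m = 0.09, body_a_m = 0.24, body_b_m = 0.13)

quick_net_config <- function() net_config(input_size = 32L,
                                          conv_channels = c(8L, 16L, 32L),
                                          dense_widths = 64L, bins = 45L)

# one small trained estimator shared across test files (lazy, cached)
.fixture_env <- new.env(parent = emptyenv())

quick_trained_net <- function() {
  if (is.null(.fixture_env$net)) {
    train <- generate_imagelets(3000, noise_sd_deg = 20,
                                params = quick_params(), seed = 421)
    cfg <- train_config(epochs = 6, seed = 421)
    .fixture_env$net <- train_orientation_net(train, quick_net_config(), cfg)
  }
  .fixture_env$net
}

quick_test_set <- function(n = 400, seed = 720) {
  key <- paste0("test_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_imagelets(n, noise_sd_deg = 20,
                                              params = quick_params(),
                                              seed = seed)
  .fixture_env[[key]]
}
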
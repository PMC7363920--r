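test_that("bias is the plain mean of signed projective residuals, in degrees", {
  refs <- deg2rad(c(10, -30, 55, 80))
  expect_equal(orientation_bias(refs, refs), 0)
  expect_equal(orientation_bias(wrap_p1(refs + deg2rad(3)), refs), 3,
               tolerance = 1e-9)
  expect_equal(orientation_bias(deg2rad(c(20, 0)), deg2rad(c(10, 10))), 0,
               tolerance = 1e-9)
  expect_error(orientation_bias(1, c(1, 2)))
  expect_warning(orientation_bias(deg2rad(88), 0), "wrap")
})

test_that("aggregate bias is the root mean square of per-network biases", {
  expect_equal(aggregate_bias(c(0, 0, 0)), 0)
  expect_equal(aggregate_bias(c(3, -4)), sqrt((9 + 16) / 2))
  expect_equal(aggregate_bias(-2.5), 2.5)
})

test_that("armse distinguishes bias from variance and matches its algebraic identity", {
  expect_equal(armse(list(rep(0, 5))), 0)
  expect_equal(armse(list(deg2rad(rep(5, 8)))), 5, tolerance = 1e-9)
  expect_equal(armse(list(deg2rad(c(5, -5, 5, -5)))), 5, tolerance = 1e-9)

  set.seed(17)
  res <- lapply(1:6, function(i) deg2rad(stats::rnorm(40, mean = i - 3, sd = 6)))
  via_moments <- mean(vapply(res, function(r) {
    b <- mean(r)
    v <- mean(r^2) - b^2
    sqrt(b^2 + v)
  }, numeric(1))) * 180 / pi
  expect_equal(armse(res), via_moments, tolerance = 1e-12)
  # total error dominates the systematic part (Jensen)
  biases <- vapply(res, function(r) mean(r) * 180 / pi, numeric(1))
  expect_gte(armse(res), aggregate_bias(biases))
})

test_that("evaluate_replicates summarizes per-network errors coherently", {
  refs <- deg2rad(seq(-80, 80, by = 20))
  preds <- list(refs, wrap_p1(refs + deg2rad(2)))
  ev <- evaluate_replicates(preds, refs)
  expect_equal(ev$per_replicate$bias_deg, c(0, 2), tolerance = 1e-9)
  expect_equal(ev$aggregate_bias_deg, sqrt(mean(c(0, 4))), tolerance = 1e-9)
  expect_equal(ev$armse_deg, 1, tolerance = 1e-9)
})

test_that("reference labels come from smoothed per-trajectory predictions", {
  # constant-orientation stream + exact oracle -> constant reference
  p <- clean_params(size = 32)
  img <- generate_imagelet(deg2rad(25), p, 0, seed = 2)
  n <- 90
  frames <- tibble::tibble(id = "a", t_s = seq(0, by = 1 / 30, length.out = n),
                           imagelet = replicate(n, img$imagelet,
                                                simplify = FALSE),
                           background_mm = img$background_mm)
  oracle <- function(imagelet, background_mm)
    orientation_from_moments(imagelet, background_mm)
  refs <- make_reference_labels(oracle, frames, seed = 1)
  expect_equal(nrow(refs), 1L)
  expect_lt(abs(p1_signed_diff(refs$theta_r, deg2rad(25))) * 180 / pi, 1.5)

  # jittered predictions around a constant are smoothed to within 1 degree
  jitter_env <- new.env(); jitter_env$i <- 0
  set.seed(44)
  noise <- stats::rnorm(n, 0, deg2rad(5))
  noisy_est <- function(imagelet, background_mm) {
    jitter_env$i <- jitter_env$i + 1
    wrap_p1(deg2rad(25) + noise[jitter_env$i])
  }
  refs2 <- make_reference_labels(noisy_est, frames, seed = 1)
  expect_lt(abs(p1_signed_diff(refs2$theta_r, deg2rad(25))) * 180 / pi, 1)

  # trajectories shorter than the filter window are excluded with a message
  short <- frames[1:40, ]
  short$id <- "b"
  expect_message(out <- make_reference_labels(oracle, rbind(frames, short),
                                              seed = 1),
                 "shorter than filter window")
  expect_equal(out$id, "a")
})

test_that("a 0.8 Hz gait oscillation survives the 2 Hz reference filter", {
  t <- seq(0, 30, by = 1 / 30)
  x <- sin(2 * pi * 0.8 * t)
  y <- lowpass_signal(x, rate_hz = 30)
  mid <- 200:700
  gain <- stats::sd(y[mid]) / stats::sd(x[mid])
  # zero-phase (forward-backward) first-order Butterworth: |H|^2 at 0.8 Hz
  expected <- 1 / (1 + (tan(pi * 0.8 / 30) / tan(pi * 2 / 30))^2)
  expect_equal(gain, expected, tolerance = 0.02)
  expect_gt(gain, 0.85)
})
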
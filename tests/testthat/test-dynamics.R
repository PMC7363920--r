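test_that("velocity direction is the pi-periodic angle to the +y axis", {
  t <- seq(0, 2, by = 1 / 30)
  up <- tibble::tibble(t_s = t, x_m = 0 * t, y_m = 1.2 * t)
  expect_equal(unique(wrap_p1(velocity_direction(up)$theta)), 0)
  right <- tibble::tibble(t_s = t, x_m = 1.2 * t, y_m = 0 * t)
  expect_equal(abs(unique(wrap_p1(velocity_direction(right)$theta))), pi / 2)
  down <- tibble::tibble(t_s = t, x_m = 0 * t, y_m = -1.2 * t)
  expect_equal(unique(wrap_p1(velocity_direction(down)$theta)), 0)
  still <- tibble::tibble(t_s = t, x_m = 0 * t, y_m = 0 * t)
  expect_error(velocity_direction(still),
               class = "pedorient_undefined_direction")
})

test_that("the zero-phase low-pass filter has unit DC gain and the Butterworth rolloff", {
  const <- rep(0.7, 300)
  expect_equal(lowpass_signal(const, rate_hz = 30), const, tolerance = 1e-9)

  # 10 Hz tone at 30 Hz sampling, 2 Hz cutoff: forward-backward first-order
  # Butterworth gives |H|^2 = 1/(1 + (tan(pi f/fs)/tan(pi fc/fs))^2)
  t <- seq(0, 60, by = 1 / 30)
  x <- sin(2 * pi * 10 * t)
  y <- lowpass_signal(x, rate_hz = 30)
  mid <- 400:1400
  gain <- stats::sd(y[mid]) / stats::sd(x[mid])
  expected <- 1 / (1 + (tan(pi * 10 / 30) / tan(pi * 2 / 30))^2)
  expect_equal(gain, expected, tolerance = 0.2)

  set.seed(3)
  wn <- stats::rnorm(2000)
  expect_lt(stats::var(lowpass_signal(wn, rate_hz = 30)), stats::var(wn))
  expect_error(lowpass_signal(stats::rnorm(30), rate_hz = 30), "window")
})

test_that("the OU delay simulator relaxes exponentially and matches its stationary law", {
  p <- ou_params(xi = 0)
  sim <- simulate_ou_delay(p, 10, seed = 1, d0 = p$d_hat + 0.5)
  expect_equal(sim$d_s, p$d_hat + 0.5 * exp(-sim$t_s / p$tau),
               tolerance = 0.02)
  # stationary moments and relaxation time at the reference parameters
  p2 <- ou_params()
  sims <- lapply(1:5, function(s) simulate_ou_delay(p2, 300, seed = s)$d_s)
  d <- unlist(sims)
  n_eff <- length(d) / (2 * p2$tau * 30)   # decorrelation-adjusted
  se_mean <- stats::sd(d) / sqrt(n_eff)
  expect_lt(abs(mean(d) - p2$d_hat), 3 * se_mean)
  v_true <- p2$xi_eff^2 * p2$tau / 2
  expect_lt(abs(stats::var(d) - v_true), 3 * v_true * sqrt(2 / n_eff))
  acfs <- rowMeans(sapply(sims, function(x)
    stats::acf(x, lag.max = 60, plot = FALSE)$acf))
  df <- data.frame(lag = (0:60) / 30, m = acfs)
  tau_hat <- coef(stats::nls(m ~ exp(-lag / tau), start = list(tau = 1),
                             data = df))[["tau"]]
  expect_lt(abs(tau_hat - p2$tau) / p2$tau, 0.15)
  expect_error(simulate_ou_delay(p2, 10, dt_s = 2))
  expect_warning(simulate_ou_delay(p2, 10, dt_s = 0.3, seed = 1), "tau")
})

test_that("the delay estimator resolves constructed shifts to the millisecond", {
  sig <- generate_orientation_signal(60, seed = 3)
  shifted <- orientation_signal(sig$t_s,
                                c(rep(sig$theta[1], 3),
                                  sig$theta[1:(nrow(sig) - 3)]), 30)
  de <- estimate_delay(sig, shifted)
  expect_lt(abs(de$mean_s - 0.100), 0.001)
  de0 <- estimate_delay(sig, sig)
  expect_lt(abs(de0$mean_s), 0.001)
})

test_that("estimated delay spread grows with the OU noise intensity", {
  sig <- generate_orientation_signal(120, seed = 7)
  sds <- vapply(c(0, 0.5, 1.85), function(xi) {
    p <- ou_params(xi = xi)
    tv <- suppressMessages(synthesize_velocity_direction(sig, p, seed = 11))
    estimate_delay(sig, tv)$sd_s
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("delayed-coupling synthesis has the exact degenerate limits", {
  sig <- generate_orientation_signal(30, seed = 5)
  p_id <- ou_params(A = 1, d_hat = 0, xi = 0)
  tv <- synthesize_velocity_direction(sig, p_id, seed = 1)
  expect_equal(tv$theta, sig$theta[seq_len(nrow(tv))], tolerance = 1e-9)

  p_shift <- ou_params(A = 1, d_hat = 0.1, xi = 0)
  tv2 <- suppressMessages(synthesize_velocity_direction(sig, p_shift, seed = 1))
  de <- estimate_delay(sig, tv2)
  expect_lt(abs(de$mean_s - 0.100), 0.002)
})

test_that("constant-delay synthesis scales the spectrum by A^2 (shift theorem)", {
  sig <- generate_orientation_signal(120, sway_amp_deg = 8, drift = NULL,
                                     seed = 6)
  p <- ou_params(A = 1.85, d_hat = 0.1, xi = 0)
  tv <- suppressMessages(synthesize_velocity_direction(sig, p, seed = 1))
  ps_in <- welch_psd(sig)
  ps_out <- welch_psd(tv)
  i <- which.max(ps_in$psd)
  expect_equal(ps_out$psd[i] / ps_in$psd[i], p$A^2, tolerance = 0.1)
})

test_that("round-trip parameter recovery from synthesized pairs", {
  p <- ou_params()  # A = 1.85, d_hat = 0.08 s, tau = 1.2 s, xi = 1.85
  pairs <- lapply(1:12, function(s) {
    th <- generate_orientation_signal(60, seed = 300 + s)
    list(theta = th,
         theta_v = suppressMessages(
           synthesize_velocity_direction(th, p, seed = 400 + s)))
  })
  A_hat <- recover_amplitude(pairs, d_hat = p$d_hat)
  expect_lt(abs(A_hat - p$A) / p$A, 0.10)
  delays <- unlist(lapply(pairs, function(pr)
    estimate_delay(pr$theta, pr$theta_v)$windows$delay_s))
  expect_lt(abs(mean(delays) - p$d_hat) / p$d_hat, 0.15)
})

test_that("welch psd satisfies parseval and grand averaging checks rates", {
  set.seed(9)
  x <- stats::rnorm(6000)
  ps <- welch_psd(x, rate_hz = 30)
  expect_lt(abs(sum(ps$psd) * ps$freq_hz[2] / stats::var(x) - 1), 0.05)

  s1 <- generate_orientation_signal(30, seed = 1)
  s2 <- generate_orientation_signal(30, rate_hz = 15, seed = 2)
  expect_error(grand_average_psd(list(s1, s2)), "mixed")
  ga <- grand_average_psd(list(s1, s1))
  expect_equal(ga$psd, welch_psd(s1)$psd)
})

test_that("delay statistics by speed recover an imposed speed-delay trend", {
  speeds <- c(0.7, 1.0, 1.3)
  imposed <- c(0.160, 0.130, 0.100)
  rows <- purrr::map2(speeds, imposed, function(v, d) {
    th <- generate_orientation_signal(60, seed = round(v * 100))
    tv <- suppressMessages(synthesize_velocity_direction(
      th, ou_params(A = 1, d_hat = d, xi = 0), seed = 1))
    tibble::tibble(v_hat_mps = v,
                   delay_s = estimate_delay(th, tv)$windows$delay_s)
  })
  tab <- delay_statistics_by_speed(dplyr::bind_rows(rows),
                                   speed_breaks = c(0.6, 0.85, 1.15, 1.45))
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$mean_delay_s) < 0))
  expect_equal(tab$cv, tab$sd_delay_s / tab$mean_delay_s)

  single <- delay_statistics_by_speed(rows[[1]],
                                      speed_breaks = c(0.6, 0.85))
  expect_equal(nrow(single), 1L)
})
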
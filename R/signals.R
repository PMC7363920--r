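# Synthetic orientation signals emulating the yawing of a walking pedestrian:
# a stepping-frequency sway plus a slow stochastic heading drift.

#' Drift specification for synthetic orientation signals
#'
#' The slow heading drift is band-limited Gaussian noise (white noise
#' band-pass filtered, then rescaled to a target rms), emulating large-scale
#' path curvature. The default band is centered near 0.2 Hz, the typical
#' low-frequency energy of walking-direction signals.
#'
#' @param amp_deg Target rms amplitude of the drift (degrees); 0 disables it.
#' @param band_hz Pass band (Hz), length 2.
#' @return List of class `"drift_spec"`.
#' @export
drift_spec <- function(amp_deg = 10, band_hz = c(0.1, 0.3)) {
  structure(list(amp_deg = amp_deg, band_hz = band_hz), class = "drift_spec")
}

#' Generate a synthetic orientation signal
#'
#' `theta(t) = mean_heading + sway + drift`, with a sinusoidal sway at the
#' stepping frequency (typically ~0.8 Hz, random initial phase) and a slow
#' band-limited Gaussian drift. The signal is kept unwrapped (continuous);
#' apply [wrap_p1()] for projective-line representatives.
#'
#' @param duration_s Signal length (s).
#' @param rate_hz Sampling rate (default 30 Hz).
#' @param mean_heading Mean orientation (radians).
#' @param sway_freq_hz Sway frequency (default 0.8 Hz).
#' @param sway_amp_deg Sway amplitude (degrees, must be < 90 for projective
#'   identifiability).
#' @param drift A [drift_spec] (or `NULL` to disable drift).
#' @param seed Optional integer seed (RNG state restored).
#' @return An [orientation_signal].
#' @export
generate_orientation_signal <- function(duration_s, rate_hz = 30,
                                        mean_heading = 0,
                                        sway_freq_hz = 0.8,
                                        sway_amp_deg = 8,
                                        drift = drift_spec(),
                                        seed = NULL) {
  if (sway_amp_deg >= 90)
    rlang::abort("`sway_amp_deg` must be below 90 (projective identifiability).")
  local_seed(seed)
  t <- seq(0, duration_s, by = 1 / rate_hz)
  n <- length(t)
  phi0 <- stats::runif(1, 0, 2 * pi)
  theta <- mean_heading +
    (sway_amp_deg * pi / 180) * sin(2 * pi * sway_freq_hz * t + phi0)
  if (!is.null(drift) && drift$amp_deg > 0) {
    wn <- stats::rnorm(n + 600)
    bw <- signal::butter(2, drift$band_hz / (rate_hz / 2), type = "pass")
    dr <- filtfilt_pad(wn, bw$b, bw$a, 120)[301:(300 + n)]
    dr <- dr / stats::sd(dr) * drift$amp_deg * pi / 180
    theta <- theta + dr
  }
  orientation_signal(t, theta, rate_hz = rate_hz)
}
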
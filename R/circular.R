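#' Wrap an angle onto the real projective line
#'
#' Orientations of a shoulder line are defined modulo a half turn: a body
#' rotation of 180 degrees leaves the orientation unchanged, so angles live on
#' the real projective line P1(R) rather than the circle. `wrap_p1()` maps any
#' finite angle to its canonical representative in `(-pi/2, pi/2]`; the wrap
#' point `-pi/2 == pi/2` is stored as `+pi/2`.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector of the same length, each value in `(-pi/2, pi/2]`
#'   and congruent to the input modulo `pi`.
#' @examples
#' wrap_p1(100 * pi / 180) * 180 / pi  # -80
#' wrap_p1(c(0, pi, -pi / 2))
#' @export
wrap_p1 <- function(theta) {
  if (!is.numeric(theta)) rlang::abort("`theta` must be numeric.")
  if (any(!is.finite(theta))) rlang::abort("`theta` must be finite.")
  w <- theta %% pi              # in [0, pi)
  ifelse(w > pi / 2, w - pi, w) # (-pi/2, pi/2]
}

#' Signed difference between two projective-line angles
#'
#' Shortest signed arc from `b` to `a` on P1(R): the unique value
#' `d` in `(-pi/2, pi/2]` with `wrap_p1(b + d) == a`. Used for prediction
#' residuals `theta_o - theta_r`.
#'
#' @param a,b Numeric vectors of angles in radians (recycled to a common
#'   length; canonicalized internally).
#' @return Numeric vector of signed differences in `(-pi/2, pi/2]` radians.
#' @examples
#' p1_signed_diff(-85 * pi / 180, 85 * pi / 180) * 180 / pi  # +10
#' @export
p1_signed_diff <- function(a, b) {
  wrap_p1(a - b)
}

#' Unwrap a projective-line angle sequence into a continuous signal
#'
#' Lifts a sequence of wrapped orientations to a continuous real-valued signal
#' by accumulating the shortest projective step between consecutive samples.
#' Well-posed only when true inter-sample changes stay below a quarter turn.
#'
#' @param theta Numeric vector of angles in radians (any representatives).
#' @return Numeric vector, same length, with `out[1] == wrap_p1(theta[1])` and
#'   successive increments in `(-pi/2, pi/2]`.
#' @export
unwrap_p1 <- function(theta) {
  if (length(theta) == 0) return(numeric(0))
  steps <- p1_signed_diff(theta[-1], theta[-length(theta)])
  cumsum(c(wrap_p1(theta[1]), steps))
}

#' Bin centers of the uniform P1(R) quantization
#'
#' @param bins Number of uniform bins `B` covering `(-pi/2, pi/2]`
#'   (default 45, i.e. 4-degree bins). Bin `i` covers
#'   `[-pi/2 + (i-1) pi/B, -pi/2 + i pi/B)` with its center at the midpoint.
#' @return Numeric vector of `B` bin centers in radians.
#' @export
p1_bin_centers <- function(bins = 45L) {
  check_bins(bins)
  -pi / 2 + (seq_len(bins) - 0.5) * pi / bins
}

check_bins <- function(bins) {
  if (length(bins) != 1 || !is.finite(bins) || bins < 2 || bins != round(bins))
    rlang::abort("`bins` must be a single integer >= 2.")
  invisible(as.integer(bins))
}

#' Discrete angular distribution over P1(R) bins
#'
#' Container for a probability distribution over `B` uniform projective-line
#' bins: the network's softmax output and the two-hot training targets both
#' take this form.
#'
#' @param weights Non-negative numeric vector of length `B` summing to 1
#'   (within 1e-9).
#' @return An object of class `"angular_dist"`: the weights with attributes
#'   `bins` and `bin_centers`.
#' @export
angular_dist <- function(weights) {
  if (!is.numeric(weights) || length(weights) < 2)
    rlang::abort("`weights` must be a numeric vector of length >= 2.")
  if (any(!is.finite(weights)) || any(weights < 0))
    rlang::abort("`weights` must be finite and non-negative.")
  if (abs(sum(weights) - 1) > 1e-9)
    rlang::abort("`weights` must sum to 1 (within 1e-9).")
  structure(as.numeric(weights),
            bins = length(weights),
            bin_centers = p1_bin_centers(length(weights)),
            class = "angular_dist")
}

#' @export
print.angular_dist <- function(x, ...) {
  cat(sprintf("<angular_dist: %d bins, width %.3g deg>\n",
              attr(x, "bins"), 180 / attr(x, "bins")))
  mu <- tryCatch(circular_mean_p1(x), error = function(e) NA_real_)
  if (is.finite(mu)) cat(sprintf("  circular mean: %.3f deg\n", mu * 180 / pi))
  invisible(x)
}

#' Two-hot encoding of an orientation
#'
#' Represents an orientation as a probability distribution supported on (at
#' most) the two bins whose centers bracket it, with weights chosen so that
#' the projective circular average of the encoding returns the angle exactly
#' (no quantization error). The weights are the exact inverse of the
#' double-angle circular mean, `w ∝ sin` of the doubled angular distances to
#' the two neighbouring centers; to first order in the bin width they are the
#' usual linear-interpolation coefficients. Adjacency is cyclic across the
#' wrap point.
#'
#' @param theta Single angle in radians (any representative).
#' @param bins Number of bins `B` (default 45). Values below 10 are accepted
#'   but atypical; `B < 2` is an error.
#' @return An [angular_dist] with at most two nonzero adjacent weights.
#' @examples
#' d <- two_hot_encode(0.3)
#' circular_mean_p1(d)  # 0.3
#' @export
two_hot_encode <- function(theta, bins = 45L) {
  bins <- check_bins(bins)
  if (length(theta) != 1 || !is.finite(theta))
    rlang::abort("`theta` must be a single finite angle.")
  theta <- wrap_p1(theta)
  binw <- pi / bins
  # index (0-based) of the lower neighbouring center, cyclic
  u <- (theta + pi / 2) / binw - 0.5
  i0 <- floor(u)
  frac <- u - i0
  lo <- (as.integer(i0) %% bins) + 1L
  hi <- (as.integer(i0 + 1) %% bins) + 1L
  w <- numeric(bins)
  if (frac < 1e-12) {
    w[lo] <- 1
  } else if (frac > 1 - 1e-12) {
    w[hi] <- 1
  } else {
    # exact inversion of the double-angle mean:
    # delta_lo = doubled distance to lower center, delta_hi to upper center
    d_lo <- 2 * frac * binw
    d_hi <- 2 * (1 - frac) * binw
    w_lo <- sin(d_hi)
    w_hi <- sin(d_lo)
    s <- w_lo + w_hi
    w[lo] <- w[lo] + w_lo / s
    w[hi] <- w[hi] + w_hi / s
  }
  angular_dist(w)
}

#' Projective-line circular mean of an angular distribution
#'
#' Axial-statistics ("double angle") construction: each bin center `c` is
#' mapped to the unit vector at `2c` on the circle, the weighted vector mean
#' is formed, and half the angle of the resultant is wrapped back to P1(R).
#'
#' @param dist An [angular_dist], or a bare numeric weight vector (bins
#'   inferred from its length).
#' @param tol Degeneracy threshold on the resultant length (default 1e-8):
#'   below it (e.g. a uniform distribution) the mean is undefined and an
#'   error of class `"pedorient_degenerate"` is signalled rather than an
#'   arbitrary angle returned.
#' @return Single angle in radians, in `(-pi/2, pi/2]`.
#' @export
circular_mean_p1 <- function(dist, tol = 1e-8) {
  if (!inherits(dist, "angular_dist")) dist <- angular_dist(dist)
  ctr <- attr(dist, "bin_centers")
  w <- as.numeric(dist)
  cx <- sum(w * cos(2 * ctr))
  sx <- sum(w * sin(2 * ctr))
  r <- sqrt(cx^2 + sx^2)
  if (r < tol)
    rlang::abort("Degenerate angular distribution: resultant length below tolerance.",
                 class = "pedorient_degenerate")
  wrap_p1(atan2(sx, cx) / 2)
}

#' Cross-entropy between two angular distributions
#'
#' `H(pred, target) = -sum(target * log(pred))`, the training loss of the
#' orientation network. Predictions are clamped at `1e-12` before the log so
#' the loss stays finite.
#'
#' @param pred,target [angular_dist] objects (or bare weight vectors) of equal
#'   length; `pred` is the softmax output, `target` the two-hot label.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(pred, target) {
  p <- as.numeric(pred)
  t <- as.numeric(target)
  if (length(p) != length(t))
    rlang::abort("`pred` and `target` must have the same number of bins.")
  -sum(t * log(pmax(p, 1e-12)))
}
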
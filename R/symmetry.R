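# O(2) transforms of imagelets and the strictly equivariant group-averaged
# estimator: orientations must rotate with the image and change sign under
# reflection about the y axis, so an estimator can be symmetrized post hoc by
# averaging over the group orbit.

#' A planar orthogonal transform (rotation, optional reflection)
#'
#' Represents `phi = Phi R_alpha` in O(2): a rotation by `alpha` about the
#' imagelet center followed (optionally) by the reflection `J` about the +y
#' direction (a left-right mirror). The determinant is +1 without the flip,
#' -1 with it; an orientation transforms as
#' `theta -> wrap_p1((theta + alpha) * det)`.
#'
#' @param alpha Rotation angle in radians (full circle).
#' @param flip Apply the reflection after the rotation?
#' @return List of class `"plane_transform"` with `alpha`, `flip`, `det`.
#' @export
plane_transform <- function(alpha = 0, flip = FALSE) {
  structure(list(alpha = alpha, flip = isTRUE(flip),
                 det = if (isTRUE(flip)) -1 else 1),
            class = "plane_transform")
}

#' Compose two planar transforms
#'
#' `compose_transforms(a, b)` is "`b` first, then `a`". The composition stays
#' in O(2) and determinants multiply.
#'
#' @param a,b [plane_transform]s.
#' @return A [plane_transform].
#' @export
compose_transforms <- function(a, b) {
  # Phi^fa R_aa Phi^fb R_ab = Phi^(fa xor fb) R_(ab + det(b)*aa)
  plane_transform(alpha = b$alpha + b$det * a$alpha,
                  flip = xor(a$flip, b$flip))
}

#' Apply a planar transform to an orientation
#' @param theta Angle(s) in radians.
#' @param transform A [plane_transform].
#' @return Canonical transformed angle(s).
#' @export
transform_angle <- function(theta, transform) {
  wrap_p1((theta + transform$alpha) * transform$det)
}

#' Apply a planar transform to an imagelet
#'
#' Rotates the depth image about its center by `alpha` (bilinear
#' interpolation, background fill), then applies the left-right mirror if the
#' transform carries a reflection (the mirror is an exact pixel permutation).
#'
#' @param imagelet Square depth matrix.
#' @param transform A [plane_transform].
#' @param fill Fill value for pixels rotated in from outside (typically the
#'   background depth).
#' @return Transformed depth matrix.
#' @export
transform_imagelet <- function(imagelet, transform, fill) {
  if (nrow(imagelet) != ncol(imagelet))
    rlang::abort("imagelet must be square.")
  cube <- array(imagelet, dim = c(nrow(imagelet), ncol(imagelet), 1))
  rotate_flip_batch(cube, transform$alpha, as.integer(transform$flip),
                    fill = fill)[, , 1]
}

#' O(2) group-averaged orientation estimate
#'
#' Builds the strictly equivariant estimator from a point estimator `f` by
#' averaging over the group orbit: for each sampled rotation `alpha_j` the
#' imagelet is evaluated both plainly and mirrored, giving the paired terms
#' `wrap_p1(f(R_a I) - a)` and `wrap_p1(-f(J R_a I) - a)` (the reflection
#' enters with negated sign, so any constant bias of `f` cancels); the `2k`
#' terms are combined with the projective circular mean, which reduces to the
#' arithmetic mean when the terms cluster away from the wrap point and stays
#' well-defined otherwise. An incoherent estimator (e.g. a constant) yields a
#' degenerate term set and raises an error. Intended for bias-free
#' estimators; a warning is emitted if the network's recorded training bias
#' exceeds 1 degree.
#'
#' @param f An `orientation_net`, or a function `f(imagelet, background_mm)`
#'   returning a canonical angle.
#' @param newdata Tibble with `imagelet` and `background_mm`.
#' @param k Number of sampled rotations (>= 1); each is evaluated with and
#'   without the reflection (2k evaluations).
#' @param sampling `"uniform"` (grid `alpha_j = 2 pi j / k`, deterministic) or
#'   `"random"` (i.i.d. uniform rotations).
#' @param seed Seed for random sampling.
#' @return Numeric vector of canonical orientation estimates.
#' @export
group_average_orientation <- function(f, newdata, k = 8,
                                      sampling = c("uniform", "random"),
                                      seed = NULL) {
  sampling <- match.arg(sampling)
  if (k < 1) rlang::abort("`k` must be at least 1.")
  local_seed(seed)
  alphas <- if (sampling == "uniform") 2 * pi * (seq_len(k) - 1) / k
            else stats::runif(k, 0, 2 * pi)
  n <- nrow(newdata)
  bg <- rep_len(newdata$background_mm, n)

  is_net <- inherits(f, "orientation_net")
  if (is_net && is.finite(f$train_bias_deg) && abs(f$train_bias_deg) > 1)
    rlang::warn(sprintf(
      "estimator training bias %.2f deg exceeds 1 deg; group average assumes a bias-free estimator",
      f$train_bias_deg))

  eval_f <- function(cube_mm) {
    if (is_net) {
      imgs <- purrr::map(seq_len(dim(cube_mm)[3]), function(i) cube_mm[, , i])
      nd <- tibble::tibble(imagelet = imgs, background_mm = bg)
      predict(f, nd)$theta_o
    } else {
      vapply(seq_len(dim(cube_mm)[3]),
             function(i) f(cube_mm[, , i], bg[i]), numeric(1))
    }
  }

  cube <- simplify2array(newdata$imagelet)
  if (length(dim(cube)) == 2) dim(cube) <- c(dim(cube), 1)
  cx <- numeric(n); sx <- numeric(n)
  for (a in alphas) {
    plain <- rotate_flip_batch(cube, rep(a, n), rep(0L, n), fill = bg[1])
    mirr <- rotate_flip_batch(cube, rep(a, n), rep(1L, n), fill = bg[1])
    t1 <- wrap_p1(eval_f(plain) - a)
    t2 <- wrap_p1(-eval_f(mirr) - a)
    cx <- cx + cos(2 * t1) + cos(2 * t2)
    sx <- sx + sin(2 * t1) + sin(2 * t2)
  }
  r <- sqrt(cx^2 + sx^2) / (2 * k)
  if (any(r < 1e-8))
    rlang::abort("group-average terms are degenerate (incoherent estimator).",
                 class = "pedorient_degenerate")
  wrap_p1(atan2(sx, cx) / 2)
}
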
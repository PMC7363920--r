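# Synthetic overhead-depth imagelet generator: a pedestrian is emulated as a
# body/shoulder ellipse plus a head ellipse at lower depth (closer to the
# sensor), on a flat floor background, with sensor-like pixel noise.

#' Parameter ranges for the two-ellipse synthetic pedestrian
#'
#' Ranges (min, max in metres / millimetres) from which each imagelet draws its
#' shape. A scalar fixes the value. Defaults are plausible adult
#' anthropometrics seen from overhead; exact values are immaterial for
#' validation because the ground-truth orientation is known by construction.
#'
#' @param size Imagelet side length in pixels (square).
#' @param pixel_pitch_m Metres per pixel. The default `NULL` scales the field
#'   of view to 1.28 m regardless of `size` (0.02 m/px at 64 px).
#' @param body_a_m,body_b_m Body-ellipse semi-major / semi-minor axis (m). The
#'   major axis lies along the shoulder line; `a/b >= 1.1` is enforced so the
#'   orientation is identifiable.
#' @param head_ax_m Head-ellipse semi-axes (m), both drawn from this range.
#' @param head_offset_m Maximum head-center offset (m) along the body minor
#'   axis (the walking direction); the offset is drawn uniformly in
#'   `[-max, max]` and jitters the silhouette centroid.
#' @param background_mm Floor depth (mm from sensor).
#' @param body_drop_mm Body depth below background (mm).
#' @param head_drop_mm Head depth below the body (mm).
#' @param noise_sd_mm Additive Gaussian depth-noise sd (mm).
#' @param dropout Fraction of pixels reset to background depth, imitating
#'   depth-sensor holes.
#' @return A list of class `"imagelet_params"`.
#' @export
imagelet_params <- function(size = 64L,
                            pixel_pitch_m = NULL,
                            body_a_m = c(0.20, 0.28),
                            body_b_m = c(0.10, 0.16),
                            head_ax_m = c(0.07, 0.11),
                            head_offset_m = 0.06,
                            background_mm = 2600,
                            body_drop_mm = c(1000, 1400),
                            head_drop_mm = c(200, 300),
                            noise_sd_mm = 10,
                            dropout = 0.01) {
  size <- as.integer(size)
  if (size < 8) rlang::abort("`size` must be at least 8 pixels.")
  if (is.null(pixel_pitch_m)) pixel_pitch_m <- 1.28 / size
  rng <- function(x) if (length(x) == 1) c(x, x) else sort(x[1:2])
  p <- list(size = size, pixel_pitch_m = pixel_pitch_m,
            body_a_m = rng(body_a_m), body_b_m = rng(body_b_m),
            head_ax_m = rng(head_ax_m),
            head_offset_m = abs(head_offset_m[1]),
            background_mm = background_mm,
            body_drop_mm = rng(body_drop_mm),
            head_drop_mm = rng(head_drop_mm),
            noise_sd_mm = noise_sd_mm, dropout = dropout)
  if (max(p$body_b_m) * 1.1 > min(p$body_a_m))
    rlang::abort("body axis ranges must keep a/b >= 1.1 (orientation identifiability).")
  structure(p, class = "imagelet_params")
}

# direction of an angle measured from +y, counterclockwise positive
# (x rightward, y upward)
dir_from_y <- function(phi) cbind(-sin(phi), cos(phi))

runif1 <- function(r) stats::runif(1, r[1], r[2])

# render one noise-free two-ellipse depth image; draw = list of fixed shapes
render_imagelet <- function(theta_gt, draw, p, body_only = FALSE) {
  S <- p$size
  c0 <- (S + 1) / 2
  xs <- ((1:S) - c0) * p$pixel_pitch_m
  x <- matrix(xs, S, S, byrow = TRUE)   # column coordinate
  y <- matrix(rev(xs), S, S)            # row 1 = top = largest y
  u <- dir_from_y(theta_gt + pi / 2)    # shoulder line (body major axis)
  w <- dir_from_y(theta_gt)             # walking direction (body minor axis)
  px_u <- x * u[1] + y * u[2]
  px_w <- x * w[1] + y * w[2]
  img <- matrix(p$background_mm, S, S)
  body <- (px_u / draw$a_b)^2 + (px_w / draw$b_b)^2 <= 1
  img[body] <- p$background_mm - draw$body_drop
  if (!body_only) {
    hc <- draw$head_off * w               # head center, on the minor axis
    uh <- dir_from_y(draw$head_rot + pi / 2)
    wh <- dir_from_y(draw$head_rot)
    hx <- x - hc[1]; hy <- y - hc[2]
    head <- ((hx * uh[1] + hy * uh[2]) / draw$a_h)^2 +
            ((hx * wh[1] + hy * wh[2]) / draw$b_h)^2 <= 1
    img[head] <- p$background_mm - draw$body_drop - draw$head_drop
  }
  img
}

draw_shapes <- function(theta_gt, p) {
  draw <- list(
    a_b = runif1(p$body_a_m),
    b_b = runif1(p$body_b_m),
    a_h = runif1(p$head_ax_m),
    b_h = runif1(p$head_ax_m),
    head_off = stats::runif(1, -p$head_offset_m, p$head_offset_m),
    head_rot = stats::runif(1, -pi / 2, pi / 2),
    body_drop = runif1(p$body_drop_mm),
    head_drop = runif1(p$head_drop_mm)
  )
  # the silhouette must fit the field of view; shrink axes if not
  half_fov <- (p$size / 2 - 1) * p$pixel_pitch_m
  reach <- max(draw$a_b, abs(draw$head_off) + max(draw$a_h, draw$b_h))
  if (reach > half_fov) {
    fac <- half_fov / reach
    rlang::inform(sprintf(
      "silhouette exceeds imagelet bounds; shrinking axes by factor %.3f", fac))
    draw$a_b <- draw$a_b * fac; draw$b_b <- draw$b_b * fac
    draw$a_h <- draw$a_h * fac; draw$b_h <- draw$b_h * fac
    draw$head_off <- draw$head_off * fac
  }
  draw
}

#' Generate one synthetic pedestrian imagelet
#'
#' Renders a body ellipse whose major axis lies along the shoulder line (i.e.
#' perpendicular to the orientation `theta_gt`, the angle between the
#' shoulder-line normal and the +y axis), superposes a head ellipse at lower
#' depth, then adds Gaussian depth noise and pixel dropout. A noisy training
#' label `theta_label = wrap_p1(theta_gt + eps)`, `eps ~ N(0, noise_sd_deg)`,
#' imitates velocity-direction supervision.
#'
#' @param theta_gt Ground-truth orientation (radians; any representative).
#' @param params An [imagelet_params] object.
#' @param label_noise_sd_deg Sd of the centered Gaussian label noise, degrees
#'   (default 20).
#' @param seed Optional integer; when given, the draw is fully reproducible
#'   and the caller's RNG state is untouched.
#' @return A list with `imagelet` (matrix, depth in mm), `theta_gt`,
#'   `theta_label` (canonical radians), `background_mm`, `pixel_pitch_m`,
#'   and the drawn `shapes`.
#' @export
generate_imagelet <- function(theta_gt, params = imagelet_params(),
                              label_noise_sd_deg = 20, seed = NULL) {
  local_seed(seed)
  theta_gt <- wrap_p1(theta_gt)
  p <- params
  draw <- draw_shapes(theta_gt, p)
  img <- render_imagelet(theta_gt, draw, p)
  if (p$noise_sd_mm > 0)
    img <- img + matrix(stats::rnorm(p$size^2, 0, p$noise_sd_mm), p$size)
  if (p$dropout > 0) {
    k <- stats::rbinom(1, p$size^2, p$dropout)
    if (k > 0) img[sample.int(p$size^2, k)] <- p$background_mm
  }
  img <- pmin(img, p$background_mm)
  eps <- stats::rnorm(1, 0, label_noise_sd_deg * pi / 180)
  list(imagelet = img,
       theta_gt = theta_gt,
       theta_label = wrap_p1(theta_gt + eps),
       background_mm = p$background_mm,
       pixel_pitch_m = p$pixel_pitch_m,
       shapes = draw)
}

#' Generate a dataset of synthetic imagelets
#'
#' Ground-truth orientations are i.i.d. uniform on the projective line; labels
#' carry independent centered Gaussian noise (wrapped).
#'
#' @param n Number of imagelets (>= 1).
#' @param noise_sd_deg Label-noise sd in degrees.
#' @param params An [imagelet_params].
#' @param seed Optional integer seed (reproducible, RNG state restored).
#' @return A tibble with columns `id`, `theta_gt`, `theta_label` (radians),
#'   `imagelet` (list of matrices), `background_mm`, `pixel_pitch_m`.
#' @export
generate_imagelets <- function(n, noise_sd_deg = 20,
                               params = imagelet_params(), seed = NULL) {
  if (length(n) != 1 || !is.finite(n) || n < 1)
    rlang::abort("`n` must be a single integer >= 1.")
  n <- as.integer(n)
  local_seed(seed)
  theta <- stats::runif(n, -pi / 2, pi / 2)
  out <- purrr::map(theta, function(th)
    generate_imagelet(th, params, label_noise_sd_deg = noise_sd_deg))
  tibble::tibble(
    id = seq_len(n),
    theta_gt = vapply(out, `[[`, numeric(1), "theta_gt"),
    theta_label = vapply(out, `[[`, numeric(1), "theta_label"),
    imagelet = purrr::map(out, "imagelet"),
    background_mm = params$background_mm,
    pixel_pitch_m = params$pixel_pitch_m
  )
}

#' Orientation of a depth blob from image second moments
#'
#' Classical principal-axis baseline: threshold the depth image against the
#' background, compute the second moments of the mask, and return the
#' orientation of the shoulder-line normal (major axis minus a quarter turn).
#' On noise-free single-ellipse imagelets this estimator is exact up to pixel
#' discretization, and it is O(2)-equivariant by construction, which makes it
#' a useful oracle for the group-averaging machinery.
#'
#' @param imagelet Depth matrix (mm).
#' @param background_mm Background depth (mm).
#' @param min_drop_mm Pixels at least this far below background count as body
#'   (default 500).
#' @return Orientation in canonical radians.
#' @export
orientation_from_moments <- function(imagelet, background_mm,
                                     min_drop_mm = 500) {
  S <- nrow(imagelet)
  mask <- imagelet < background_mm - min_drop_mm
  if (sum(mask) < 3) rlang::abort("too few body pixels for a moment estimate.")
  c0 <- (S + 1) / 2
  xs <- ((1:S) - c0)
  x <- matrix(xs, S, S, byrow = TRUE)[mask]
  y <- matrix(rev(xs), S, S)[mask]
  cx <- x - mean(x); cy <- y - mean(y)
  C <- matrix(c(mean(cx^2), mean(cx * cy), mean(cx * cy), mean(cy^2)), 2)
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]  # major axis
  phi_axis <- atan2(-v[1], v[2])                # angle from +y, ccw
  wrap_p1(phi_axis - pi / 2)
}

# run code under a temporary seed, restoring the caller's RNG state
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
  do.call(on.exit, list(bquote((.(restore))()), add = TRUE), envir = env)
  invisible()
}
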
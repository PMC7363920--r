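test_that("planar transforms compose within O(2) with multiplicative determinant", {
  set.seed(21)
  for (i in 1:20) {
    a <- plane_transform(runif(1, 0, 2 * pi), runif(1) < 0.5)
    b <- plane_transform(runif(1, 0, 2 * pi), runif(1) < 0.5)
    ab <- compose_transforms(a, b)
    expect_equal(ab$det, a$det * b$det)
    th <- runif(1, -pi / 2, pi / 2)
    expect_equal(transform_angle(th, ab),
                 transform_angle(transform_angle(th, b), a),
                 tolerance = 1e-12)
  }
})

test_that("identity and double flip act trivially on imagelets", {
  img <- generate_imagelet(0.4, quick_params(), seed = 6)
  ident <- transform_imagelet(img$imagelet, plane_transform(0),
                              fill = img$background_mm)
  expect_identical(ident, img$imagelet)
  fl <- plane_transform(0, flip = TRUE)
  twice <- transform_imagelet(transform_imagelet(img$imagelet, fl,
                                                 img$background_mm),
                              fl, img$background_mm)
  expect_identical(twice, img$imagelet)
})

test_that("rotating an imagelet rotates its measured orientation", {
  p <- clean_params(size = 128)
  img <- generate_imagelet(deg2rad(20), p, 0, seed = 4)
  rot <- transform_imagelet(img$imagelet, plane_transform(deg2rad(50)),
                            fill = img$background_mm)
  est <- orientation_from_moments(rot, img$background_mm)
  # bilinear resampling adds interpolation error on top of discretization
  expect_lt(abs(p1_signed_diff(est, deg2rad(70))) * 180 / pi, 1.5)
  # flip negates
  fl <- transform_imagelet(img$imagelet, plane_transform(0, TRUE),
                           fill = img$background_mm)
  expect_lt(abs(p1_signed_diff(orientation_from_moments(fl, img$background_mm),
                               deg2rad(-20))) * 180 / pi, 1)
})

test_that("group averaging an already equivariant estimator reproduces it", {
  p <- clean_params()
  oracle <- function(imagelet, background_mm)
    orientation_from_moments(imagelet, background_mm)
  nd <- generate_imagelets(6, noise_sd_deg = 0, params = p, seed = 9)
  plain <- vapply(seq_len(6), function(i)
    oracle(nd$imagelet[[i]], nd$background_mm[i]), numeric(1))
  for (k in c(1, 4, 8)) {
    ga <- group_average_orientation(oracle, nd, k = k)
    expect_lt(max(abs(p1_signed_diff(ga, plain))) * 180 / pi, 2)
  }
})

test_that("a constant estimator is annihilated by the flip antisymmetrization", {
  nd <- generate_imagelets(1, params = quick_params(), seed = 3)
  const_f <- function(imagelet, background_mm) 0.3
  expect_error(group_average_orientation(const_f, nd, k = 4),
               class = "pedorient_degenerate")
})

test_that("group averaging does not worsen a trained estimator", {
  est <- quick_trained_net()
  test <- quick_test_set(200)
  plain <- predict(est, test)$theta_o
  # the small fixture net legitimately carries ~1 deg of recorded bias
  ga <- suppressWarnings(predict(est, test, group_k = 16)$theta_o)
  rmse <- function(x) sqrt(mean(p1_signed_diff(x, test$theta_gt)^2)) * 180 / pi
  expect_lte(rmse(ga), rmse(plain) * 1.02)
})

test_that("random-mode group averaging is seeded and reproducible", {
  est <- quick_trained_net()
  test <- quick_test_set(10)
  a <- suppressWarnings(
    predict(est, test, group_k = 4, sampling = "random", seed = 5)$theta_o)
  b <- suppressWarnings(
    predict(est, test, group_k = 4, sampling = "random", seed = 5)$theta_o)
  expect_identical(a, b)
})
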
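deg <- function(x) x * pi / 180

test_that("wrap_p1 canonicalizes to (-pi/2, pi/2] and is pi-periodic and idempotent", {
  expect_equal(wrap_p1(0), 0)
  expect_equal(wrap_p1(deg(100)), deg(-80))
  expect_equal(wrap_p1(pi / 2), pi / 2)    # wrap point stored as +pi/2
  expect_equal(wrap_p1(-pi / 2), pi / 2)

  set.seed(11)
  theta <- runif(200, -10, 10)
  k <- sample(-5:5, 200, replace = TRUE)
  expect_equal(wrap_p1(theta + k * pi), wrap_p1(theta), tolerance = 1e-12)
  expect_equal(wrap_p1(wrap_p1(theta)), wrap_p1(theta))
  w <- wrap_p1(theta)
  expect_true(all(w > -pi / 2 & w <= pi / 2))
  # congruent to input mod pi
  expect_equal((theta - w) %% pi, rep(0, 200), tolerance = 1e-9)
  expect_error(wrap_p1(NaN))
  expect_error(wrap_p1(Inf))
})

test_that("p1_signed_diff is the shortest projective arc", {
  expect_equal(p1_signed_diff(deg(10), deg(10)), 0)
  expect_equal(p1_signed_diff(deg(-85), deg(85)), deg(10), tolerance = 1e-12)

  set.seed(12)
  a <- wrap_p1(runif(300, -5, 5))
  b <- wrap_p1(runif(300, -5, 5))
  d <- p1_signed_diff(a, b)
  expect_true(all(d > -pi / 2 & d <= pi / 2))
  expect_equal(wrap_p1(b + d), a, tolerance = 1e-12)
  # |diff| equals brute-force min over integer pi shifts
  brute <- vapply(seq_along(a), function(i)
    min(abs(a[i] - b[i] + (-2:2) * pi)), numeric(1))
  expect_equal(abs(d), brute, tolerance = 1e-9)
  # antisymmetry away from the boundary representative
  keep <- abs(abs(d) - pi / 2) > 1e-6
  expect_equal(d[keep], -p1_signed_diff(b, a)[keep], tolerance = 1e-12)
})

test_that("two_hot_encode puts mass on at most two adjacent bins and hits centers exactly", {
  B <- 45L
  ctr <- p1_bin_centers(B)
  d <- two_hot_encode(ctr[7], B)
  expect_equal(as.numeric(d)[7], 1)
  expect_equal(sum(as.numeric(d) > 0), 1L)

  mid <- (ctr[7] + ctr[8]) / 2
  d2 <- as.numeric(two_hot_encode(mid, B))
  expect_equal(d2[7], 0.5, tolerance = 1e-12)
  expect_equal(d2[8], 0.5, tolerance = 1e-12)

  set.seed(13)
  for (theta in wrap_p1(runif(50, -5, 5))) {
    w <- as.numeric(two_hot_encode(theta, B))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    nz <- which(w > 0)
    expect_lte(length(nz), 2L)
    if (length(nz) == 2L) {
      gap <- diff(nz)
      expect_true(gap == 1L || gap == B - 1L)  # cyclic adjacency across wrap
    }
  }
  expect_error(two_hot_encode(0.1, bins = 1L))
})

test_that("encode/decode round trip is exact on P1 for several bin counts", {
  set.seed(14)
  theta <- wrap_p1(runif(1000, -5, 5))
  for (B in c(10L, 45L, 90L)) {
    back <- vapply(theta, function(th) circular_mean_p1(two_hot_encode(th, B)),
                   numeric(1))
    expect_equal(back, theta, tolerance = 1e-9)
  }
})

test_that("circular mean follows the double-angle construction, incl. the wrap point", {
  B <- 45L
  ctr <- p1_bin_centers(B)
  one <- numeric(B); one[which.min(abs(ctr))] <- 1
  expect_equal(circular_mean_p1(one), ctr[which.min(abs(ctr))])

  # 0.5 at +88 deg, 0.5 at -88 deg -> +/-90 (wrap point), NOT 0
  w <- 0.5 * as.numeric(two_hot_encode(deg(88), B)) +
       0.5 * as.numeric(two_hot_encode(deg(-88), B))
  m <- circular_mean_p1(w)
  expect_equal(abs(m), pi / 2, tolerance = 1e-9)

  expect_error(circular_mean_p1(rep(1 / B, B)), class = "pedorient_degenerate")
})

test_that("circular mean is equivariant under rigid rotation of the support", {
  B <- 45L
  set.seed(15)
  for (i in 1:20) {
    theta <- runif(1, -1.3, 1.3)
    alpha <- runif(1, -1.2, 1.2)
    m0 <- circular_mean_p1(two_hot_encode(theta, B))
    m1 <- circular_mean_p1(two_hot_encode(theta + alpha, B))
    expect_equal(m1, wrap_p1(m0 + alpha), tolerance = 1e-9)
  }
})

test_that("cross-entropy has the closed-form values and is minimized at the target", {
  B <- 45L
  ctr <- p1_bin_centers(B)
  onehot <- as.numeric(two_hot_encode(ctr[3], B))
  expect_equal(cross_entropy(onehot, onehot), 0, tolerance = 1e-10)
  expect_equal(cross_entropy(rep(1 / B, B), onehot), log(B), tolerance = 1e-12)

  # numeric minimization over the simplex at B = 10 recovers the target
  B2 <- 10L
  target <- as.numeric(two_hot_encode(0.4, B2))
  obj <- function(z) {
    p <- exp(z) / sum(exp(z))
    cross_entropy(p, target)
  }
  opt <- optim(rep(0, B2), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  p_hat <- exp(opt$par) / sum(exp(opt$par))
  expect_equal(p_hat, target, tolerance = 1e-4)
  expect_equal(opt$value, cross_entropy(target, target), tolerance = 1e-6)
})

test_that("unwrap_p1 lifts wrapped sequences continuously", {
  t <- seq(0, 3, by = 1 / 30)
  truth <- 0.3 + 1.8 * t          # passes through several wraps
  lifted <- unwrap_p1(wrap_p1(truth))
  expect_equal(diff(lifted), diff(truth), tolerance = 1e-12)
  expect_equal(wrap_p1(lifted), wrap_p1(truth), tolerance = 1e-12)
})
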
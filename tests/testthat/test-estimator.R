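make_traj <- function(id, v, duration_s = 6, rate = 30, dir = c(0, 1)) {
  t <- seq(0, by = 1 / rate, length.out = duration_s * rate)
  tibble::tibble(id = id, t_s = t, x_m = v * t * dir[1], y_m = v * t * dir[2])
}

make_frames <- function(traj, size = 8) {
  tibble::tibble(id = traj$id, t_s = traj$t_s,
                 imagelet = replicate(nrow(traj),
                                      matrix(2600, size, size), simplify = FALSE),
                 background_mm = 2600)
}

test_that("velocity-label training sets respect the speed filter and subsampling", {
  cfg <- train_config(label_source = "velocity_direction")
  slow <- make_traj("a", v = 0.3)
  expect_error(build_training_set(make_frames(slow), slow, cfg),
               class = "pedorient_empty_dataset")

  fast <- make_traj("b", v = 1.2)   # 6 s at 30 Hz, 0.5 s subsampling -> 12
  ts <- build_training_set(make_frames(fast), fast, cfg)
  expect_equal(nrow(ts), 12L)
  expect_equal(ts$theta_label, rep(0, 12))  # motion along +y
})

test_that("the augmentation orbit makes labels uniform on the projective line", {
  n <- 10000
  samples <- tibble::tibble(
    imagelet = replicate(n, matrix(2600, 4, 4), simplify = FALSE),
    theta_label = rep(0.7, n),  # all identical before augmentation
    background_mm = 2600)
  aug <- augment_samples(samples, seed = 5)
  h <- table(cut(aug$theta_label, breaks = seq(-pi / 2, pi / 2, length.out = 16)))
  expect_gt(stats::chisq.test(h)$p.value, 0.01)
})

test_that("training memorizes a single repeated imagelet to within one bin", {
  img <- generate_imagelet(deg2rad(30), quick_params(), 0, seed = 8)
  samples <- tibble::tibble(
    imagelet = replicate(200, img$imagelet, simplify = FALSE),
    theta_label = deg2rad(30), background_mm = img$background_mm)
  cfg <- train_config(epochs = 30, augment = FALSE, seed = 3)
  est <- train_orientation_net(samples, quick_net_config(), cfg)
  pr <- predict(est, samples[1, ])
  expect_lt(abs(p1_signed_diff(pr$theta_o, deg2rad(30))) * 180 / pi, 4)
})

test_that("training is deterministic under a fixed seed and the loss decreases", {
  train <- quick_test_set(300, seed = 31)
  cfg <- train_config(epochs = 3, seed = 11)
  e1 <- train_orientation_net(train, quick_net_config(), cfg)
  e2 <- train_orientation_net(train, quick_net_config(), cfg)
  expect_identical(e1$loss_history, e2$loss_history)
  expect_identical(e1$weights, e2$weights)
  expect_lt(utils::tail(e1$loss_history, 1), e1$loss_history[1])
})

test_that("the network's training loss equals the circular module's cross-entropy", {
  train <- quick_test_set(256, seed = 32)
  cfg <- train_config(epochs = 1, learning_rate = 0, augment = FALSE, seed = 2)
  est <- train_orientation_net(train, quick_net_config(), cfg)  # weights = init
  pr <- predict(est, train, return_dist = TRUE)
  ce <- vapply(seq_len(nrow(train)), function(i)
    cross_entropy(pr$h_pred[[i]], two_hot_encode(train$theta_label[i], 45)),
    numeric(1))
  expect_equal(est$loss_history[1], mean(ce), tolerance = 1e-6)
})

test_that("prediction decodes the softmax with the projective circular mean", {
  est <- quick_trained_net()
  test <- quick_test_set(50)
  pr <- predict(est, test, return_dist = TRUE)
  manual <- vapply(pr$h_pred, circular_mean_p1, numeric(1))
  expect_equal(pr$theta_o, manual, tolerance = 1e-12)
  expect_true(all(abs(vapply(pr$h_pred, sum, numeric(1)) - 1) < 1e-9))

  wrong <- generate_imagelets(2, params = imagelet_params(size = 16), seed = 1)
  expect_error(predict(est, wrong), "size")
})

test_that("an estimator trained on noisy labels localizes held-out orientations", {
  est <- quick_trained_net()
  test <- quick_test_set(400)
  pr <- predict(est, test)
  res <- abs(p1_signed_diff(pr$theta_o, test$theta_gt)) * 180 / pi
  expect_lt(stats::median(res), 10)
})

test_that("tidy and glance summarize a fitted estimator", {
  est <- quick_trained_net()
  td <- tidy(est)
  expect_equal(names(td), c("epoch", "loss"))
  gl <- glance(est)
  expect_equal(gl$n_train, 3000L)
  expect_gt(gl$n_params, 1000L)
})
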
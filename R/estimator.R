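# The CNN point-estimator: configuration, training-set assembly from
# velocity-direction weak labels, training with O(2) augmentation, and
# prediction through the circular-average decoding of the softmax output.

#' Network architecture configuration
#'
#' A compact convolutional network: 3x3 stride-2 convolution blocks with ReLU,
#' global average pooling, dense layers, and a final `bins`-way softmax whose
#' output is decoded by the projective circular mean. The architecture is a
#' configuration, not a constant; the defaults (~0.1 M parameters at 64 px)
#' are sized for CPU training.
#'
#' @param input_size Imagelet side length in pixels.
#' @param conv_channels Output channels of each conv block.
#' @param dense_widths Hidden dense-layer widths (may be empty).
#' @param bins Output bins `B` over the projective line (default 45,
#'   4-degree bins).
#' @return List of class `"net_config"`.
#' @export
net_config <- function(input_size = 64L, conv_channels = c(16L, 32L, 64L),
                       dense_widths = 128L, bins = 45L) {
  check_bins(bins)
  h <- as.integer(input_size)
  for (i in seq_along(conv_channels)) h <- (h + 2L - 3L) %/% 2L + 1L
  if (h < 1) rlang::abort("too many conv blocks for this input size.")
  structure(list(input_size = as.integer(input_size),
                 conv_channels = as.integer(conv_channels),
                 dense_widths = as.integer(dense_widths),
                 bins = as.integer(bins)),
            class = "net_config")
}

#' @export
print.net_config <- function(x, ...) {
  cat(sprintf("<net_config: %dpx, conv [%s], dense [%s], %d bins, %s params>\n",
              x$input_size, paste(x$conv_channels, collapse = ","),
              paste(x$dense_widths, collapse = ","), x$bins,
              format(cnn_param_count(unclass(x)), big.mark = ",")))
  invisible(x)
}

#' Training configuration
#'
#' @param label_source `"ground_truth_plus_noise"` (synthetic training: labels
#'   are `theta_gt` plus centered Gaussian noise) or `"velocity_direction"`
#'   (weak labels from trajectories).
#' @param epochs,batch_size,learning_rate Adam optimizer settings.
#' @param augment Apply the O(2) orbit during training: each presented sample
#'   gets a fresh uniform rotation and a Bernoulli(0.5) horizontal flip, with
#'   the label transformed consistently (rotation adds the angle, flip negates
#'   it), so labels span the projective line uniformly.
#' @param min_speed_mps Trajectories slower on average than this are dropped
#'   when building velocity-label training sets (default 0.65 m/s).
#' @param subsample_dt_s Time spacing of retained frames within a trajectory
#'   (default 0.5 s), decorrelating training samples.
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(label_source = c("ground_truth_plus_noise",
                                          "velocity_direction"),
                         epochs = 12L, batch_size = 128L,
                         learning_rate = 1e-3, augment = TRUE,
                         min_speed_mps = 0.65, subsample_dt_s = 0.5,
                         seed = 1L) {
  structure(list(label_source = match.arg(label_source),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, augment = augment,
                 min_speed_mps = min_speed_mps,
                 subsample_dt_s = subsample_dt_s,
                 seed = as.integer(seed)),
            class = "train_config")
}

# stack list-of-matrices into a (S, S, n) array of normalized depth:
# (background - depth) / 1000, so the floor is 0 and a body ~1.0-1.7
imagelets_to_cube <- function(imagelets, background_mm) {
  S <- nrow(imagelets[[1]])
  n <- length(imagelets)
  bg <- rep_len(background_mm, n)
  arr <- array(0, dim = c(S, S, n))
  for (i in seq_len(n)) arr[, , i] <- (bg[i] - imagelets[[i]]) / 1000
  arr
}

#' Assemble a training set from imagelets and (optionally) trajectories
#'
#' For velocity-direction labels: trajectories slower than the mean-speed
#' threshold are dropped, the velocity direction is computed per frame and
#' attached to the imagelet frames by nearest time, frames flagged as
#' low-confidence are excluded, and each trajectory is subsampled at
#' `subsample_dt_s` to decorrelate samples. For ground-truth labels the
#' samples (from [generate_imagelets()]) already carry `theta_label` and are
#' passed through.
#'
#' @param frames Tibble with `imagelet`, `background_mm` and, for velocity
#'   labels, `id` and `t_s`; for ground-truth labels also `theta_label`.
#' @param trajectories Tibble with `id`, `t_s`, `x_m`, `y_m` (velocity labels
#'   only).
#' @param cfg A [train_config].
#' @return Tibble with `imagelet`, `theta_label`, `background_mm` (plus `id`,
#'   `t_s` for trajectory data).
#' @export
build_training_set <- function(frames, trajectories = NULL,
                               cfg = train_config()) {
  if (cfg$label_source == "ground_truth_plus_noise" || is.null(trajectories)) {
    if (!"theta_label" %in% names(frames))
      rlang::abort("`frames` must carry `theta_label` for ground-truth training.")
    if (nrow(frames) == 0)
      rlang::abort("empty training set.", class = "pedorient_empty_dataset")
    return(frames)
  }
  keep <- trajectories |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(v_hat = trajectory_speed(dplyr::pick(dplyr::everything())),
                     .groups = "drop") |>
    dplyr::filter(.data$v_hat >= cfg$min_speed_mps)
  out <- purrr::map(keep$id, function(pid) {
    traj <- dplyr::filter(trajectories, .data$id == pid)
    fr <- dplyr::filter(frames, .data$id == pid)
    if (nrow(fr) == 0) return(NULL)
    tv <- velocity_direction(traj)
    step <- max(1L, round(cfg$subsample_dt_s * signal_rate(tv)))
    fr <- fr[order(fr$t_s), ]
    fr <- fr[seq(1L, nrow(fr), by = step), ]
    idx <- vapply(fr$t_s, function(tt) which.min(abs(tv$t_s - tt)), integer(1))
    fr$theta_label <- wrap_p1(tv$theta[idx])
    fr$low_conf <- tv$low_conf[idx]
    dplyr::filter(fr, !.data$low_conf)
  })
  out <- dplyr::bind_rows(out)
  if (is.null(out) || nrow(out) == 0)
    rlang::abort("no training samples survive the speed/confidence filters.",
                 class = "pedorient_empty_dataset")
  dplyr::select(out, -dplyr::any_of("low_conf"))
}

#' Apply a random O(2) orbit to a sample set
#'
#' The augmentation used during training, exposed for inspection: each sample
#' receives an independent uniform rotation and a Bernoulli(0.5) horizontal
#' flip; imagelets are transformed with bilinear interpolation (background
#' fill) and labels as `wrap_p1((theta + alpha) * det)`.
#'
#' @param samples Tibble with `imagelet`, `theta_label`, `background_mm`.
#' @param seed Optional integer seed.
#' @return Tibble of the same shape with transformed imagelets and labels.
#' @export
augment_samples <- function(samples, seed = NULL) {
  local_seed(seed)
  n <- nrow(samples)
  alphas <- stats::runif(n, 0, 2 * pi)
  flips <- stats::runif(n) < 0.5
  cube <- simplify2array(samples$imagelet)
  bg <- rep_len(samples$background_mm, n)
  out_cube <- rotate_flip_batch(cube, alphas, as.integer(flips), fill = bg[1])
  samples$imagelet <- purrr::map(seq_len(n), function(i) out_cube[, , i])
  samples$theta_label <- wrap_p1((samples$theta_label + alphas) *
                                   ifelse(flips, -1, 1))
  samples
}

#' Train the orientation estimator
#'
#' Minimizes the average cross-entropy between the softmax output and the
#' two-hot encoding of the (noisy) labels with Adam, applying a fresh O(2)
#' augmentation orbit every epoch when `cfg$augment` is on. Training with
#' zero-mean noisy labels is self-amending: the softmax converges to the
#' label distribution of similar imagelets, whose circular average is the
#' noise-free orientation.
#'
#' @param samples Training tibble (see [build_training_set()]): columns
#'   `imagelet`, `theta_label`, `background_mm`.
#' @param net A [net_config]; its `input_size` must match the imagelets.
#' @param cfg A [train_config].
#' @return Object of class `"orientation_net"`: weights, configs, loss
#'   history, the training-set size, and the residual training bias
#'   (degrees, measured against the training labels on up to 2000 samples).
#' @export
train_orientation_net <- function(samples, net = net_config(),
                                  cfg = train_config()) {
  if (nrow(samples) == 0)
    rlang::abort("empty training set.", class = "pedorient_empty_dataset")
  S <- nrow(samples$imagelet[[1]])
  if (S != net$input_size)
    rlang::abort("imagelet size does not match `net$input_size`.")
  cube <- imagelets_to_cube(samples$imagelet, samples$background_mm)
  set.seed(cfg$seed)
  fit <- tryCatch(
    cnn_train(cube, wrap_p1(samples$theta_label), unclass(net),
              list(epochs = cfg$epochs, batch_size = cfg$batch_size,
                   learning_rate = cfg$learning_rate,
                   augment = cfg$augment, fill = 0)),
    error = function(e)
      rlang::abort(paste("training failure:", conditionMessage(e)),
                   class = "pedorient_training_failure"))
  est <- structure(list(weights = fit$weights, net = net, train = cfg,
                        n_train = nrow(samples),
                        loss_history = fit$loss_history,
                        train_bias_deg = NA_real_),
                   class = "orientation_net")
  m <- min(2000L, nrow(samples))
  pr <- predict(est, samples[seq_len(m), ])
  est$train_bias_deg <- orientation_bias(pr$theta_o,
                                         samples$theta_label[seq_len(m)],
                                         warn_wrap = FALSE)
  est
}

#' @export
print.orientation_net <- function(x, ...) {
  cat(sprintf("<orientation_net: N=%s, %d epochs, final loss %.4f, train bias %.3f deg>\n",
              format(x$n_train, big.mark = ","), length(x$loss_history),
              utils::tail(x$loss_history, 1), x$train_bias_deg))
  print(x$net)
  invisible(x)
}

# coerce prediction inputs to a normalized cube
as_pred_cube <- function(newdata, input_size) {
  if (is.data.frame(newdata)) {
    imgs <- newdata$imagelet
    bg <- newdata$background_mm
  } else if (is.list(newdata)) {
    imgs <- newdata
    bg <- attr(newdata, "background_mm") %||%
      rlang::abort("supply imagelets in a tibble with `background_mm`.")
  } else if (is.matrix(newdata)) {
    rlang::abort("wrap a single imagelet in a one-row tibble with `background_mm`.")
  } else rlang::abort("unsupported `newdata`.")
  S <- nrow(imgs[[1]])
  if (S != input_size)
    rlang::abort(sprintf("imagelet size %d does not match network input %d.",
                         S, input_size))
  imagelets_to_cube(imgs, bg)
}

# circular-mean decoding of softmax rows (n x B) -> canonical angles
decode_softmax <- function(P, tol = 1e-8) {
  ctr <- p1_bin_centers(ncol(P))
  cx <- as.numeric(P %*% cos(2 * ctr))
  sx <- as.numeric(P %*% sin(2 * ctr))
  r <- sqrt(cx^2 + sx^2)
  if (any(r < tol))
    rlang::abort("degenerate softmax output: circular mean undefined.",
                 class = "pedorient_degenerate")
  wrap_p1(atan2(sx, cx) / 2)
}

#' Predict orientations
#'
#' Runs the network and decodes the softmax distribution with the projective
#' circular mean. With `group_k > 0` the strictly O(2)-equivariant group
#' average is used instead (see [group_average_orientation()]).
#'
#' @param object An `orientation_net`.
#' @param newdata Tibble with `imagelet` and `background_mm` columns.
#' @param group_k Number of rotation samples for the O(2) group average
#'   (0 = plain prediction).
#' @param sampling `"uniform"` or `"random"` rotation sampling for the group
#'   average.
#' @param return_dist Also return the softmax distributions (`h_pred`
#'   list-column of [angular_dist]).
#' @param seed Seed for random-mode group averaging.
#' @param ... Unused.
#' @return Tibble with `theta_o` (canonical radians; plus `h_pred` if
#'   requested).
#' @export
predict.orientation_net <- function(object, newdata, group_k = 0,
                                    sampling = c("uniform", "random"),
                                    return_dist = FALSE, seed = NULL, ...) {
  sampling <- match.arg(sampling)
  if (group_k > 0) {
    th <- group_average_orientation(object, newdata, k = group_k,
                                    sampling = sampling, seed = seed)
    return(tibble::tibble(theta_o = th))
  }
  cube <- as_pred_cube(newdata, object$net$input_size)
  P <- cnn_forward(object$weights, unclass(object$net), cube)
  out <- tibble::tibble(theta_o = decode_softmax(P))
  if (return_dist)
    out$h_pred <- purrr::map(seq_len(nrow(P)), function(i) angular_dist(P[i, ]))
  out
}

#' Training-loss curve of a fitted estimator
#' @param x An `orientation_net`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`.
#' @export
tidy.orientation_net <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' One-row summary of a fitted estimator
#' @param x An `orientation_net`.
#' @param ... Unused.
#' @return Tibble with training-set size, parameter count, final loss and
#'   residual training bias.
#' @export
glance.orientation_net <- function(x, ...) {
  tibble::tibble(n_train = x$n_train,
                 n_params = cnn_param_count(unclass(x$net)),
                 epochs = length(x$loss_history),
                 final_loss = utils::tail(x$loss_history, 1),
                 train_bias_deg = x$train_bias_deg)
}
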
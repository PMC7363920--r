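# Error protocol: per-network bias, aggregate bias (root-mean-square of the
# per-network biases), ARMSE (average over replicate networks of the RMS
# residual), and the learning-curve driver.

#' Mean prediction bias of one network (degrees)
#'
#' Arithmetic mean of the signed projective residuals `theta_o - theta_r`.
#' Residuals live in `(-pi/2, pi/2]`, so the plain mean is valid as long as
#' they stay away from the wrap point; residuals beyond 85 degrees trigger a
#' wrap-ambiguity warning.
#'
#' @param preds,refs Angle vectors in radians (equal length >= 1).
#' @param warn_wrap Emit the near-wrap warning (default TRUE).
#' @return Bias in degrees.
#' @export
orientation_bias <- function(preds, refs, warn_wrap = TRUE) {
  if (length(preds) != length(refs) || length(preds) < 1)
    rlang::abort("`preds` and `refs` must have equal length >= 1.")
  res <- p1_signed_diff(preds, refs)
  if (warn_wrap && any(abs(res) > 85 * pi / 180))
    rlang::warn("residuals near the +/-90 deg wrap point: bias may be ambiguous.")
  mean(res) * 180 / pi
}

#' Aggregate bias over replicate networks (degrees)
#'
#' Root-mean-square of the individual network biases: systematic errors of
#' either sign count, but independent statistical fluctuations do not average
#' away as they would in a plain mean.
#'
#' @param biases_deg Per-network biases (degrees).
#' @return Aggregate bias in degrees.
#' @export
aggregate_bias <- function(biases_deg) {
  if (length(biases_deg) < 1) rlang::abort("need at least one bias.")
  sqrt(mean(biases_deg^2))
}

#' Average root-mean-square error over replicate networks (degrees)
#'
#' Mean over replicates of the RMS residual; per replicate this equals
#' `sqrt(bias^2 + variance)`, decomposing the total error into systematic and
#' random parts.
#'
#' @param residuals List with one numeric vector of signed residuals
#'   (radians) per replicate network, or a single numeric vector.
#' @return ARMSE in degrees.
#' @export
armse <- function(residuals) {
  if (is.numeric(residuals)) residuals <- list(residuals)
  if (length(residuals) < 1 || any(lengths(residuals) == 0))
    rlang::abort("each replicate must contribute at least one residual.")
  mean(vapply(residuals, function(r) sqrt(mean(r^2)), numeric(1))) * 180 / pi
}

#' Evaluate replicate networks against a reference
#'
#' @param preds List of prediction vectors (radians), one per replicate.
#' @param refs Reference angles (radians), shared across replicates.
#' @return List with the per-replicate tibble (`replicate`, `bias_deg`,
#'   `rmse_deg`), `aggregate_bias_deg` and `armse_deg`.
#' @export
evaluate_replicates <- function(preds, refs) {
  res <- purrr::map(preds, function(p) p1_signed_diff(p, refs))
  per <- tibble::tibble(
    replicate = seq_along(res),
    bias_deg = purrr::map_dbl(res, function(r) mean(r) * 180 / pi),
    rmse_deg = purrr::map_dbl(res, function(r) sqrt(mean(r^2)) * 180 / pi))
  list(per_replicate = per,
       aggregate_bias_deg = aggregate_bias(per$bias_deg),
       armse_deg = armse(res))
}

#' Learning-curve experiment driver
#'
#' For each training-set size `N`, trains `replicates` networks on independent
#' synthetic datasets (noisy labels) and evaluates them on one shared
#' held-out test set against both the noise-free ground truth and the noisy
#' labels. A power law `log(ARMSE) ~ log(N)` is fitted to the ground-truth
#' ARMSE (zero floor); the smallest-N point is excluded from the fit when its
#' replicate spread exceeds its mean, and the exponent gets a bootstrap CI
#' (resampling replicates within cells). A training failure marks the cell
#' invalid and the run continues.
#'
#' @param n_grid Ascending training-set sizes.
#' @param replicates Networks per size (`M`).
#' @param noise_sd_deg Label-noise sd in degrees (default 20).
#' @param params [imagelet_params] for the generator.
#' @param net [net_config].
#' @param cfg [train_config] (its seed is re-derived per cell).
#' @param test_n Held-out test-set size.
#' @param group_k Group-average samples at prediction time (0 = plain).
#' @param seed Master seed.
#' @param n_boot Bootstrap draws for the exponent CI.
#' @return Object of class `"learning_curve"`: `cells` (per-network tibble),
#'   `summary` (per-N tibble), `exponent` (fit, CI), and the settings.
#' @export
learning_curve <- function(n_grid, replicates = 4, noise_sd_deg = 20,
                           params = imagelet_params(), net = net_config(),
                           cfg = train_config(), test_n = 5000, group_k = 0,
                           seed = 1, n_boot = 200) {
  if (is.unsorted(n_grid)) rlang::abort("`n_grid` must be ascending.")
  test <- generate_imagelets(test_n, noise_sd_deg = noise_sd_deg,
                             params = params, seed = derive_seed(seed, 0))
  cells <- list()
  for (i in seq_along(n_grid)) {
    for (m in seq_len(replicates)) {
      cell_seed <- derive_seed(seed, i * 1000 + m)
      cell <- tryCatch({
        train <- generate_imagelets(n_grid[i], noise_sd_deg = noise_sd_deg,
                                    params = params, seed = cell_seed)
        cfg_m <- cfg
        cfg_m$seed <- cell_seed
        estm <- train_orientation_net(train, net, cfg_m)
        pr <- predict(estm, test, group_k = group_k)$theta_o
        res_gt <- p1_signed_diff(pr, test$theta_gt)
        res_ny <- p1_signed_diff(pr, test$theta_label)
        tibble::tibble(N = n_grid[i], replicate = m,
                       bias_deg = mean(res_gt) * 180 / pi,
                       rmse_gt_deg = sqrt(mean(res_gt^2)) * 180 / pi,
                       rmse_noisy_deg = sqrt(mean(res_ny^2)) * 180 / pi,
                       failed = FALSE)
      }, error = function(e) {
        rlang::warn(sprintf("cell N=%d replicate %d failed: %s",
                            n_grid[i], m, conditionMessage(e)))
        tibble::tibble(N = n_grid[i], replicate = m, bias_deg = NA_real_,
                       rmse_gt_deg = NA_real_, rmse_noisy_deg = NA_real_,
                       failed = TRUE)
      })
      cells[[length(cells) + 1]] <- cell
    }
  }
  cells <- dplyr::bind_rows(cells)
  summary <- cells |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(N = .data$N) |>
    dplyr::summarise(
      aggregate_bias_deg = aggregate_bias(.data$bias_deg),
      armse_gt_deg = mean(.data$rmse_gt_deg),
      armse_noisy_deg = mean(.data$rmse_noisy_deg),
      spread_gt_deg = stats::sd(.data$rmse_gt_deg),
      m = dplyr::n(), .groups = "drop")
  exponent <- fit_learning_exponent(cells, n_boot = n_boot,
                                    boot_seed = derive_seed(seed, 99))
  structure(list(cells = cells, summary = summary, exponent = exponent,
                 settings = list(n_grid = n_grid, replicates = replicates,
                                 noise_sd_deg = noise_sd_deg, test_n = test_n,
                                 group_k = group_k, seed = seed)),
            class = "learning_curve")
}

fit_learning_exponent <- function(cells, n_boot = 200, boot_seed = 1) {
  ok <- dplyr::filter(cells, !.data$failed)
  per_n <- ok |>
    dplyr::group_by(N = .data$N) |>
    dplyr::summarise(armse = mean(.data$rmse_gt_deg),
                     spread = stats::sd(.data$rmse_gt_deg), .groups = "drop")
  use <- per_n
  if (nrow(per_n) >= 3 && is.finite(per_n$spread[1]) &&
      per_n$spread[1] > per_n$armse[1])
    use <- per_n[-1, ]
  if (nrow(use) < 2)
    return(list(exponent = NA_real_, ci = c(NA_real_, NA_real_),
                n_used = nrow(use)))
  fit <- stats::lm(log(armse) ~ log(N), data = use)
  expo <- unname(stats::coef(fit)[2])
  local_seed(boot_seed)
  boots <- replicate(n_boot, {
    bs <- ok |>
      dplyr::group_by(N = .data$N) |>
      dplyr::slice_sample(prop = 1, replace = TRUE) |>
      dplyr::summarise(armse = mean(.data$rmse_gt_deg), .groups = "drop") |>
      dplyr::filter(.data$N %in% use$N)
    if (nrow(bs) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(log(armse) ~ log(N), data = bs))[2])
  })
  list(exponent = expo,
       ci = stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE),
       n_used = nrow(use))
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("<learning_curve>\n")
  print(x$summary)
  cat(sprintf("fitted ARMSE exponent: %.3f [%.3f, %.3f]\n",
              x$exponent$exponent, x$exponent$ci[1], x$exponent$ci[2]))
  invisible(x)
}

#' Per-cell results of a learning-curve run
#' @param x A `learning_curve`.
#' @param ... Unused.
#' @return The per-network cells tibble.
#' @export
tidy.learning_curve <- function(x, ...) x$cells

#' One-row summary of a learning-curve run
#' @param x A `learning_curve`.
#' @param ... Unused.
#' @return Tibble with the largest-N error metrics and the fitted exponent.
#' @export
glance.learning_curve <- function(x, ...) {
  last <- x$summary[which.max(x$summary$N), ]
  tibble::tibble(n_max = last$N,
                 aggregate_bias_deg = last$aggregate_bias_deg,
                 armse_gt_deg = last$armse_gt_deg,
                 armse_noisy_deg = last$armse_noisy_deg,
                 exponent = x$exponent$exponent,
                 exponent_lo = x$exponent$ci[1],
                 exponent_hi = x$exponent$ci[2])
}

#' Reference labels from smoothed per-trajectory predictions
#'
#' For real-life validation no ground truth exists, so references are built
#' from a heavily trained estimator plus a physical time-regularity
#' assumption: predict every frame of a trajectory, lift to a continuous
#' signal, low-pass filter (zero-phase Butterworth, order 1, 2 Hz, window
#' 52), and keep one independent time instant per trajectory. Trajectories
#' shorter than the filter window are excluded (with a message).
#'
#' @param est An `orientation_net` (or a function for oracle testing).
#' @param frames Tibble with `id`, `t_s`, `imagelet`, `background_mm`
#'   (per-trajectory 30 Hz imagelet streams).
#' @param group_k Group-average samples at prediction (default 0).
#' @param order,cutoff_hz,window Filter settings.
#' @param seed Seed for choosing the retained instant per trajectory.
#' @return Tibble with `id`, `t_s`, `theta_r` (canonical radians).
#' @export
make_reference_labels <- function(est, frames, group_k = 0, order = 1,
                                  cutoff_hz = 2, window = 52, seed = NULL) {
  local_seed(seed)
  ids <- unique(frames$id)
  out <- purrr::map(ids, function(pid) {
    fr <- dplyr::arrange(dplyr::filter(frames, .data$id == pid), .data$t_s)
    if (nrow(fr) <= window) {
      rlang::inform(sprintf("trajectory %s shorter than filter window: excluded",
                            as.character(pid)))
      return(NULL)
    }
    th <- if (inherits(est, "orientation_net")) {
      predict(est, fr, group_k = group_k)$theta_o
    } else {
      vapply(seq_len(nrow(fr)),
             function(i) est(fr$imagelet[[i]], fr$background_mm[i]), numeric(1))
    }
    rate <- 1 / stats::median(diff(fr$t_s))
    smooth <- lowpass_signal(unwrap_p1(th), order = order,
                             cutoff_hz = cutoff_hz, window = window,
                             rate_hz = rate)
    pick <- sample.int(nrow(fr), 1)
    tibble::tibble(id = pid, t_s = fr$t_s[pick],
                   theta_r = wrap_p1(smooth[pick]))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) rlang::abort("no trajectory long enough for references.")
  out
}

# deterministic seed derivation (stays within 32-bit range)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 8191) %% 2147483629)
}
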
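# Interchange formats: imagelet datasets (16-bit grayscale TIFF + CSV
# manifest, depth quantized to 1 mm integers), trajectory tables and signal
# tables (CSV, degrees/seconds/metres with unit suffixes in column names).

#' Write an imagelet dataset to disk
#'
#' One 16-bit grayscale TIFF per imagelet (pixel value = depth in mm; smaller
#' = closer to the overhead sensor) plus a `manifest.csv` with the labels in
#' degrees and a provenance hash.
#'
#' @param samples Tibble from [generate_imagelets()] (columns `id`,
#'   `theta_gt`, `theta_label`, `imagelet`, `background_mm`,
#'   `pixel_pitch_m`).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_imagelet_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("imagelet_%06d.tif", samples$id)
  hash <- rlang::hash(list(samples$theta_gt, samples$background_mm,
                           samples$pixel_pitch_m))
  for (i in seq_len(nrow(samples))) {
    px <- round(samples$imagelet[[i]])
    px[px < 0] <- 0; px[px > 65535] <- 65535
    tiff::writeTIFF(px / 65535, file.path(dir, files[i]),
                    bits.per.sample = 16L)
  }
  manifest <- tibble::tibble(
    id = samples$id, file = files,
    theta_gt_deg = samples$theta_gt * 180 / pi,
    theta_label_deg = samples$theta_label * 180 / pi,
    background_mm = samples$background_mm,
    pixel_pitch_m = samples$pixel_pitch_m,
    params_hash = hash)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read an imagelet dataset written by [write_imagelet_dataset()]
#'
#' Depth values round-trip losslessly (1 mm quantization). Files referenced
#' by the manifest but missing on disk are a hard error naming the ids, as is
#' a raster that is not 16-bit grayscale.
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return Tibble in the [generate_imagelets()] layout (angles in radians).
#' @export
read_imagelet_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) rlang::abort("no manifest.csv in `dir`.")
  manifest <- readr::read_csv(mpath, show_col_types = FALSE)
  paths <- file.path(dir, manifest$file)
  missing <- !file.exists(paths)
  if (any(missing))
    rlang::abort(paste("missing imagelet files for ids:",
                       paste(manifest$id[missing], collapse = ", ")))
  imgs <- purrr::map2(paths, manifest$id, function(p, id) {
    x <- tiff::readTIFF(p, as.is = TRUE, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (is.null(bits) || bits != 16L)
      rlang::abort(sprintf("imagelet %s is not 16-bit grayscale.", id))
    matrix(as.numeric(x), nrow(x), ncol(x))
  })
  tibble::tibble(
    id = manifest$id,
    theta_gt = manifest$theta_gt_deg * pi / 180,
    theta_label = manifest$theta_label_deg * pi / 180,
    imagelet = imgs,
    background_mm = manifest$background_mm,
    pixel_pitch_m = manifest$pixel_pitch_m)
}

#' Write pedestrian trajectories to CSV
#' @param traj Tibble with `id`, `t_s`, `x_m`, `y_m`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  readr::write_csv(traj[, c("id", "t_s", "x_m", "y_m")], path)
  invisible(path)
}

#' Read pedestrian trajectories from CSV
#'
#' Groups rows by pedestrian id and sorts by time. Non-monotone time within
#' an id is an error; a sampling rate deviating from `rate_hz` by more than
#' 5% yields a warning and sets the `resample_needed` attribute.
#'
#' @param path CSV with columns `id`, `t_s`, `x_m`, `y_m`.
#' @param rate_hz Expected sampling rate (default 30).
#' @return Tibble sorted by (`id`, `t_s`) with attribute `resample_needed`.
#' @export
read_trajectories <- function(path, rate_hz = 30) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("id", "t_s", "x_m", "y_m")
  if (!all(need %in% names(df)))
    rlang::abort(paste("trajectory CSV must have columns:",
                       paste(need, collapse = ", ")))
  df <- dplyr::arrange(df, .data$id, .data$t_s)
  flag <- FALSE
  for (pid in unique(df$id)) {
    dt <- diff(df$t_s[df$id == pid])
    if (any(dt <= 0))
      rlang::abort(sprintf("non-monotone time in trajectory %s.",
                           as.character(pid)))
    if (abs(stats::median(dt) - 1 / rate_hz) > 0.05 / rate_hz) flag <- TRUE
  }
  if (flag)
    rlang::warn(sprintf("sampling deviates from %g Hz; resampling recommended.",
                        rate_hz))
  attr(df, "resample_needed") <- flag
  df
}

#' Write an orientation signal to CSV (degrees)
#' @param sig An [orientation_signal].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(sig, path) {
  readr::write_csv(tibble::tibble(t_s = sig$t_s,
                                  theta_deg = sig$theta * 180 / pi), path)
  invisible(path)
}

#' Read an orientation signal from CSV (degrees on disk, radians in memory)
#' @param path CSV with columns `t_s`, `theta_deg`.
#' @return An [orientation_signal].
#' @export
read_signal <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t_s", "theta_deg") %in% names(df)))
    rlang::abort("signal CSV must have columns t_s, theta_deg.")
  orientation_signal(df$t_s, df$theta_deg * pi / 180,
                     rate_hz = 1 / stats::median(diff(df$t_s)))
}

#' Run configuration with derived per-stage seeds
#'
#' One master seed deterministically spawns a seed per pipeline stage, so any
#' stage can be rerun in isolation; the configuration hash is embedded in
#' artifacts for provenance.
#'
#' @param master_seed Integer master seed.
#' @param stages Character vector of stage names.
#' @return List of class `"run_config"` with `seeds` (named) and `hash`.
#' @export
run_config <- function(master_seed,
                       stages = c("generate", "train", "predict", "evaluate",
                                  "simulate")) {
  seeds <- stats::setNames(
    vapply(seq_along(stages), function(i) derive_seed(master_seed, i),
           integer(1)), stages)
  structure(list(master_seed = as.integer(master_seed), seeds = seeds,
                 hash = rlang::hash(list(master_seed, stages))),
            class = "run_config")
}
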
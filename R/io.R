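# TIFF round trips use 16-bit pages; intensities are stored as value/65535
# and restored on read, so synthetic intensities must stay below 65535.
TIFF_SCALE <- 65535

#' Write a Z-stack or movie as a multi-page TIFF
#'
#' One page per plane (stack) or per frame (movie), 16-bit. Values are
#' clamped to `[0, 65535]`.
#'
#' @param arr numeric array `[row, col, page]` or matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(arr, path) {
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1))
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) {
    m <- arr[, , k]
    m[m < 0] <- 0
    m[m > TIFF_SCALE] <- TIFF_SCALE
    m / TIFF_SCALE
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF file.
#' @param pixel_size µm per pixel, stored as an attribute.
#' @return numeric array `[row, col, page]` on the original intensity scale.
#' @export
read_stack_tiff <- function(path, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!length(pages)) stop("empty TIFF: ", path)
  arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , k] <- pg * TIFF_SCALE
  }
  if (!is.null(pixel_size)) attr(arr, "pixel_size") <- pixel_size
  arr
}

#' Write the ground-truth sidecar table of a synthetic NMJ
#'
#' @param gt a [make_geometry()] object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(gt, path) {
  stopifnot(inherits(gt, "nmj_ground_truth"))
  s <- gt$synapses
  write.csv(data.frame(az_id = s$az_id, x_um = s$x_um, y_um = s$y_um,
                       true_pr = s$true_pr, spont_per_min = s$spont_per_min,
                       age_days = s$age_days, cac_positive = s$cac_positive,
                       bouton_index = s$bouton_index),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a ROI table (id, x_um, y_um) from CSV
#'
#' Replaces manual ROI addition: users supply additional or corrected ROIs
#' as a plain table.
#'
#' @param path CSV with columns `id`, `x_um`, `y_um`.
#' @param radius_um common ROI radius.
#' @return a [roi_set()].
#' @export
read_roi_csv <- function(path, radius_um = 0.5) {
  df <- read.csv(path)
  stopifnot(all(c("id", "x_um", "y_um") %in% names(df)))
  roi_set(df$id, df$x_um, df$y_um, radius_um)
}

#' Write events or release-map tables to CSV
#'
#' @param x data.frame (events or release map).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration for [run_pipeline()]
#'
#' All simulator conditions and analysis thresholds in one nested list;
#' [read_run_config()] merges a YAML file over these defaults.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1, out_dir = "quantalmap-out") {
  list(
    seed = seed,
    out_dir = out_dir,
    pixel_size = 0.133,
    geometry = list(n_boutons = 3, az_per_bouton = 6,
                    cac_negative_fraction = 0.1, orphan_psd_fraction = 0),
    movie = list(frame_rate = 8, stim_rate = 1, duration = 60,
                 flash_amplitude = 60, flash_sigma = 0.25, noise_sd = 10,
                 background = 100),
    detection = list(baseline_window = 16, baseline_prob = 0.2, k_sigma = 5,
                     min_separation = 2, smooth_sigma_px = 1),
    assignment = list(max_dist = 0.8, roi_radius = 0.5),
    classify = list(min_simultaneous = 3),
    timestamp = list(days_since_pc = 2),
    turnover = list(half_life_days = 2.56, dt_days = 1)
  )
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys override [default_run_config()].
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  modifyList(cfg, user)
}
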
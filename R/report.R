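#' Pearson product-moment correlation with validation
#'
#' @param x,y numeric vectors of equal length >= 3, finite, non-constant.
#' @return correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(1:5, c(2, 4, 6, 8, 10))  # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Compare two groups: means, SEM, fold change, t test
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @param var_equal use the classical Student t test (default, the
#'   convention for two-group comparisons here); `FALSE` for Welch.
#' @return list of class `group_compare`: `mean_a`, `sem_a`, `n_a`,
#'   `mean_b`, `sem_b`, `n_b`, `fold` (= mean_a / mean_b), `p_value`
#'   (`NA` when both groups are constant), `method`.
#' @examples
#' group_compare(c(1.1, 1.2, 1.0), c(0.5, 0.4, 0.6))
#' @export
group_compare <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs n >= 2")
  }
  sem <- function(v) sd(v) / sqrt(length(v))
  p <- if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) 1 else NA_real_
  } else {
    t.test(values_a, values_b, var.equal = var_equal)$p.value
  }
  structure(list(mean_a = mean(values_a), sem_a = sem(values_a),
                 n_a = length(values_a),
                 mean_b = mean(values_b), sem_b = sem(values_b),
                 n_b = length(values_b),
                 fold = mean(values_a) / mean(values_b), p_value = p,
                 method = if (var_equal) "Student t" else "Welch t"),
            class = "group_compare")
}

#' @export
print.group_compare <- function(x, ...) {
  cat(sprintf("<group_compare> %.4g +/- %.3g (n=%d) vs %.4g +/- %.3g (n=%d): fold %.3g, p = %.3g (%s)\n",
              x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b, x$fold,
              x$p_value, x$method))
  invisible(x)
}

#' Render a per-ROI release heatmap over a projected background
#'
#' Draws the ROIs coloured by evoked Pr (or spontaneous rate) on a grayscale
#' background image, with a colour bar, and writes a PNG.
#'
#' @param rmap a [release_map()].
#' @param rois the matching [roi_set()].
#' @param background background image matrix (e.g. AZ-channel projection);
#'   `NULL` for a black field sized to the ROIs.
#' @param file output PNG path.
#' @param value which statistic to map: `"pr"` or `"spont_per_min"`.
#' @param pixel_size µm per pixel of the background.
#' @param n_colors colour resolution.
#' @return invisibly, a data.frame `roi_id`, `value`, `color_index` — colour
#'   indices are the rank-preserving bin of each value.
#' @export
render_pr_heatmap <- function(rmap, rois, background = NULL,
                              file = "release_map.png",
                              value = c("pr", "spont_per_min"),
                              pixel_size = NULL, n_colors = 64) {
  stopifnot(inherits(rmap, "release_map"), inherits(rois, "roi_set"))
  value <- match.arg(value)
  v <- rmap[[value]][match(rois$id, rmap$roi_id)]
  if (is.null(pixel_size)) {
    pixel_size <- if (!is.null(background)) attr(background, "pixel_size") else NULL
  }
  if (is.null(pixel_size)) pixel_size <- 0.133
  if (is.null(background)) {
    ext <- c(max(rois$x_um) + 2, max(rois$y_um) + 2)
    background <- matrix(0, ceiling(ext[2] / pixel_size),
                         ceiling(ext[1] / pixel_size))
  }
  pal <- hcl.colors(n_colors, "viridis")
  rng <- range(v)
  idx <- if (diff(rng) == 0) rep(1L, length(v)) else {
    pmin(n_colors, 1L + as.integer(floor((v - rng[1]) / diff(rng) * (n_colors - 1) + 0.5)))
  }
  ny <- nrow(background); nx <- ncol(background)
  png(file, width = 720, height = 720 * ny / nx + 80)
  op <- par(mar = c(4, 4, 3, 1))
  on.exit({ par(op); dev.off() })
  bgn <- background - min(background)
  if (max(bgn) > 0) bgn <- bgn / max(bgn)
  image(x = px_to_um(seq_len(nx), pixel_size),
        y = px_to_um(seq_len(ny), pixel_size),
        z = t(bgn)[, rev(seq_len(ny)), drop = FALSE],
        col = gray(seq(0, 1, length.out = 256)), useRaster = TRUE,
        xlab = "x (um)", ylab = "y (um)",
        main = if (value == "pr") "Evoked Pr" else "Spontaneous rate (events/min)")
  # y axis flipped so row 1 is at the top, as in image display convention
  symbols(rois$x_um, (ny * pixel_size) - rois$y_um,
          circles = rep(attr(rois, "radius_um"), nrow(rois)),
          inches = FALSE, add = TRUE, fg = pal[idx], lwd = 3)
  # colour bar
  xr <- range(px_to_um(seq_len(nx), pixel_size))
  yb <- -0.5
  for (i in seq_len(n_colors)) {
    rect(xr[1] + (i - 1) / n_colors * diff(xr),
         yb, xr[1] + i / n_colors * diff(xr), yb + 0.4,
         col = pal[i], border = NA, xpd = NA)
  }
  mtext(sprintf("%.3g", rng[1]), side = 1, line = 2.5, adj = 0, cex = 0.8)
  mtext(sprintf("%.3g", rng[2]), side = 1, line = 2.5, adj = 1, cex = 0.8)
  invisible(data.frame(roi_id = rois$id, value = v, color_index = idx))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full synthetic-to-report pipeline
#'
#' Simulates an NMJ (geometry, AZ/PSD stacks, quantal movie, photoconversion
#' series), writes the imagery to TIFF, then runs the full analysis from
#' those files: puncta detection, ROI derivation, event detection,
#' assignment, evoked/spontaneous classification, release mapping, PSD age
#' classification with age–output correlation, and turnover estimation.
#' All tables, the Pr heatmap and a machine-readable run log are written to
#' the output directory.
#'
#' @param config nested configuration list ([default_run_config()] or
#'   [read_run_config()]).
#' @return invisibly, a list with the main result objects (`gt`, `rois`,
#'   `events`, `map`, `age`, `age_cor`, `turnover`, `paths`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  gt <- run_stage("simulate", {
    g <- config$geometry
    make_geometry(g$n_boutons, g$az_per_bouton,
                  cac_negative_fraction = g$cac_negative_fraction,
                  orphan_psd_fraction = g$orphan_psd_fraction,
                  pixel_size = config$pixel_size, seed = config$seed)
  })
  paths$ground_truth <- file.path(config$out_dir, "ground_truth.csv")
  write_ground_truth_csv(gt, paths$ground_truth)

  sim <- run_stage("simulate", {
    m <- config$movie
    spec <- movie_spec(frame_rate = m$frame_rate, stim_rate = m$stim_rate,
                       duration = m$duration,
                       flash_amplitude = m$flash_amplitude,
                       flash_sigma = m$flash_sigma, noise_sd = m$noise_sd,
                       background = m$background)
    simulate_quantal_movie(gt, spec, seed = config$seed + 1)
  })
  paths$movie <- file.path(config$out_dir, "movie.tif")
  write_stack_tiff(sim$movie, paths$movie)

  az_stack <- run_stage("simulate",
    render_puncta_stack(gt, "az", seed = config$seed + 2))
  paths$az_stack <- file.path(config$out_dir, "az_stack.tif")
  write_stack_tiff(az_stack, paths$az_stack)

  ts <- config$timestamp
  glur_green <- run_stage("simulate",
    render_puncta_stack(gt, "glur_green", days_since_pc = ts$days_since_pc,
                        seed = config$seed + 3))
  glur_red <- run_stage("simulate",
    render_puncta_stack(gt, "glur_red", days_since_pc = ts$days_since_pc,
                        seed = config$seed + 4))

  # --- puncta stage: detect AZs from the written TIFF and derive ROIs
  az_set <- run_stage("puncta", {
    stack <- read_stack_tiff(paths$az_stack, pixel_size = config$pixel_size)
    detect_puncta(max_project(stack), pixel_size = config$pixel_size,
                  channel = "az", nmj_area_um2 = gt$nmj_area_um2)
  })
  rois <- run_stage("puncta",
    rois_from_puncta(az_set, config$assignment$roi_radius))

  # --- quantal stage
  res <- run_stage("quantal", {
    movie <- read_stack_tiff(paths$movie, pixel_size = config$pixel_size)
    d <- config$detection
    map_release(movie, rois,
                n_stimulations = sim$n_stimulations,
                duration_s = config$movie$duration,
                assign_max_dist = config$assignment$max_dist,
                min_simultaneous = config$classify$min_simultaneous,
                pixel_size = config$pixel_size,
                baseline_window = d$baseline_window,
                baseline_prob = d$baseline_prob, k_sigma = d$k_sigma,
                min_separation = d$min_separation,
                smooth_sigma_px = d$smooth_sigma_px)
  })
  paths$events <- file.path(config$out_dir, "events.csv")
  write_table_csv(res$events, paths$events)
  paths$release_map <- file.path(config$out_dir, "release_map.csv")
  write_table_csv(res$map, paths$release_map)
  paths$heatmap <- file.path(config$out_dir, "pr_heatmap.png")
  run_stage("report",
    render_pr_heatmap(res$map, rois, max_project(az_stack),
                      file = paths$heatmap, pixel_size = config$pixel_size))

  # --- timestamp stage: PSD objects from total GluR, red measured over them
  age_res <- run_stage("timestamp", {
    total <- max_project(glur_green) + max_project(glur_red)
    attr(total, "pixel_size") <- config$pixel_size
    psd_set <- detect_puncta(total, pixel_size = config$pixel_size,
                             channel = "glur")
    age <- classify_age(psd_set, red_plane = max_project(glur_red),
                        green_plane = max_project(glur_green))
    pairing <- opposition_pairs(az_set, psd_set,
                                config$assignment$max_dist)
    list(age = age, pairing = pairing,
         cor = tryCatch(age_output_correlation(age, res$map, pairing),
                        error = function(e) NULL))
  })
  paths$age_labels <- file.path(config$out_dir, "age_labels.csv")
  write_table_csv(age_res$age, paths$age_labels)

  # --- turnover stage
  turn <- run_stage("turnover", {
    tv <- config$turnover
    pc <- simulate_photoconversion_series(gt, tv$half_life_days,
                                          timepoints = c(0, tv$dt_days),
                                          seed = config$seed + 5)
    estimate_turnover(pc$stacks[[1]]$red, pc$stacks[[2]]$red,
                      dt_days = tv$dt_days, pixel_size = config$pixel_size)
  })
  paths$turnover <- file.path(config$out_dir, "turnover.csv")
  write_table_csv(data.frame(remaining_pct = turn$remaining_pct,
                             half_life_days = turn$half_life_days,
                             n_puncta = turn$n_puncta), paths$turnover)

  # --- run log: everything needed to reproduce the run bit-exactly
  paths$run_log <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(
    list(package = "quantalmap",
         version = as.character(packageVersion("quantalmap")),
         r_version = R.version.string,
         config = config,
         n_events = nrow(res$events),
         n_rois = nrow(rois)),
    paths$run_log, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(gt = gt, rois = rois, events = res$events, map = res$map,
                 age = age_res$age, age_cor = age_res$cor, turnover = turn,
                 paths = paths))
}
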
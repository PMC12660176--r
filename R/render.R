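#' Acquisition parameters for a simulated quantal-imaging movie
#'
#' Describes the movie the simulator renders: an 8 Hz single-plane GCaMP
#' recording during 1 Hz nerve stimulation (the study conditions), with each
#' release event appearing as an additive 2D Gaussian flash that rises in one
#' frame and decays geometrically.
#'
#' Default signal and noise levels (flash amplitude 60 on background 100 with
#' Gaussian noise s.d. 10) put the raw single-pixel peak at 6x the noise
#' s.d., so reliable detection requires the spatial smoothing and rolling
#' baseline of [detect_events()] — detection is deliberately non-trivial.
#'
#' @param frame_rate imaging rate (Hz); must exceed `stim_rate`.
#' @param stim_rate nerve stimulation rate (Hz).
#' @param duration recording duration (s).
#' @param flash_amplitude peak added intensity of a single-vesicle flash.
#' @param flash_sigma spatial s.d. of the flash (µm).
#' @param flash_decay_frames number of frames a flash persists after onset.
#' @param flash_decay_factor per-frame geometric decay of the flash.
#' @param noise_sd per-pixel Gaussian noise s.d.
#' @param background constant baseline intensity.
#' @return object of class `movie_spec`.
#' @examples
#' movie_spec(duration = 60)
#' @export
movie_spec <- function(frame_rate = 8, stim_rate = 1, duration = 300,
                       flash_amplitude = 60, flash_sigma = 0.25,
                       flash_decay_frames = 3, flash_decay_factor = 0.5,
                       noise_sd = 10, background = 100) {
  stopifnot_scalar(frame_rate, "frame_rate", 1e-9)
  stopifnot_scalar(stim_rate, "stim_rate", 1e-9)
  stopifnot_scalar(duration, "duration", 1e-9)
  stopifnot_scalar(flash_amplitude, "flash_amplitude", 1e-9)
  stopifnot_scalar(flash_sigma, "flash_sigma", 1e-9)
  stopifnot_scalar(flash_decay_frames, "flash_decay_frames", 0)
  stopifnot_scalar(flash_decay_factor, "flash_decay_factor", 0, 1)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  stopifnot_scalar(background, "background", 0)
  if (frame_rate <= stim_rate) stop("frame_rate must exceed stim_rate")
  structure(list(frame_rate = frame_rate, stim_rate = stim_rate,
                 duration = duration, flash_amplitude = flash_amplitude,
                 flash_sigma = flash_sigma,
                 flash_decay_frames = as.integer(flash_decay_frames),
                 flash_decay_factor = flash_decay_factor,
                 noise_sd = noise_sd, background = background),
            class = "movie_spec")
}

# Add 2D Gaussian spots (possibly sub-pixel positions, µm) to a matrix.
# Each spot has peak `amplitude[i]` and s.d. `sigma_um`; only a +/- 4 sigma
# patch is touched per spot.
add_gaussian_spots <- function(img, x_um, y_um, amplitude, sigma_um, pixel_size) {
  if (length(x_um) == 0) return(img)
  ny <- nrow(img); nx <- ncol(img)
  s_px <- sigma_um / pixel_size
  r <- max(2L, as.integer(ceiling(4 * s_px)))
  for (i in seq_along(x_um)) {
    cx <- x_um[i] / pixel_size + 0.5  # fractional pixel coordinates
    cy <- y_um[i] / pixel_size + 0.5
    j0 <- max(1L, as.integer(floor(cx)) - r); j1 <- min(nx, as.integer(ceiling(cx)) + r)
    i0 <- max(1L, as.integer(floor(cy)) - r); i1 <- min(ny, as.integer(ceiling(cy)) + r)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    gx <- exp(-0.5 * ((jj - cx) / s_px)^2)
    gy <- exp(-0.5 * ((ii - cy) / s_px)^2)
    img[ii, jj] <- img[ii, jj] + amplitude[i] * (gy %o% gx)
  }
  img
}

# Per-synapse photoconvertible GluR channel amounts for a chase of
# `days_since_pc` days: synapses that existed at photoconversion carry red
# ("old") signal proportional to their age at that moment; green ("new")
# signal accumulates with time lived since photoconversion.
glur_channel_units <- function(age_days, days_since_pc) {
  old <- pmax(age_days - days_since_pc, 0)
  new <- pmin(age_days, days_since_pc)
  data.frame(red_units = old, green_units = new)
}

#' Render a synthetic multi-plane puncta Z-stack
#'
#' Renders each synapse of a ground-truth geometry as a diffraction-limited
#' Gaussian spot on a noisy background, spread over Z planes with a Gaussian
#' axial profile whose brightest plane carries the full amplitude (so the
#' max projection recovers spot intensities proportional to the requested
#' per-synapse values).
#'
#' @param gt a [make_geometry()] ground truth.
#' @param channel which centroids/values to render: `"az"` (active-zone
#'   marker, unit intensity), `"psd"` (all PSDs incl. orphans, unit
#'   intensity), `"glur_red"` (photoconverted old-receptor signal,
#'   proportional to age at photoconversion) or `"glur_green"` (receptor
#'   delivered since photoconversion).
#' @param intensity_per_unit intensity scale applied to the per-synapse values.
#' @param values optional explicit per-synapse values overriding the channel
#'   rule (length = number of rendered centroids).
#' @param days_since_pc chase time (days) used by the GluR channels.
#' @param psf_sigma lateral PSF s.d. (µm).
#' @param noise_sd additive Gaussian noise s.d. per plane.
#' @param background constant background intensity.
#' @param n_planes number of Z planes (>= 1).
#' @param z_sigma_planes axial profile s.d. in planes.
#' @param seed RNG seed (noise and per-synapse plane depths).
#' @return numeric array `[row, col, plane]` with attributes `pixel_size`,
#'   `channel` and `spot_values` (the rendered per-synapse values).
#' @examples
#' gt <- make_geometry(1, 3, pr_distribution = 0.2, seed = 1)
#' stk <- render_puncta_stack(gt, "az", noise_sd = 0, seed = 1)
#' dim(stk)
#' @export
render_puncta_stack <- function(gt, channel = c("az", "psd", "glur_red", "glur_green"),
                                intensity_per_unit = 500, values = NULL,
                                days_since_pc = 2, psf_sigma = 0.18,
                                noise_sd = 4, background = 20,
                                n_planes = 5, z_sigma_planes = 1, seed = 1) {
  stopifnot(inherits(gt, "nmj_ground_truth"))
  channel <- match.arg(channel)
  stopifnot_scalar(psf_sigma, "psf_sigma", 1e-9)
  stopifnot_scalar(n_planes, "n_planes", 1)
  n_planes <- as.integer(n_planes)
  s <- gt$synapses
  if (channel == "az") {
    x <- s$x_um; y <- s$y_um
    v <- rep(1, nrow(s))
  } else {
    x <- c(s$psd_x_um, gt$orphan_psds$psd_x_um)
    y <- c(s$psd_y_um, gt$orphan_psds$psd_y_um)
    age <- c(s$age_days, rep(days_since_pc / 2, nrow(gt$orphan_psds)))
    v <- switch(channel,
      psd = rep(1, length(x)),
      glur_red = glur_channel_units(age, days_since_pc)$red_units,
      glur_green = glur_channel_units(age, days_since_pc)$green_units
    )
  }
  if (!is.null(values)) {
    if (length(values) != length(x)) stop("'values' has wrong length")
    v <- values
  }
  fx <- gt$field_dim[2] * gt$pixel_size
  fy <- gt$field_dim[1] * gt$pixel_size
  if (any(x < 0 | x > fx | y < 0 | y > fy)) stop("centroid outside field")

  with_seed(seed, {
    zc <- runif(length(x), 1, n_planes)
    stack <- array(0, c(gt$field_dim[1], gt$field_dim[2], n_planes))
    for (k in seq_len(n_planes)) {
      w <- exp(-0.5 * ((k - zc) / z_sigma_planes)^2)
      # normalise so the brightest plane of each spot carries full amplitude
      wmax <- vapply(zc, function(z) {
        kk <- seq_len(n_planes)
        max(exp(-0.5 * ((kk - z) / z_sigma_planes)^2))
      }, numeric(1))
      amp <- intensity_per_unit * v * w / wmax
      plane <- matrix(background, gt$field_dim[1], gt$field_dim[2])
      keep <- amp > 0
      plane <- add_gaussian_spots(plane, x[keep], y[keep], amp[keep],
                                  psf_sigma, gt$pixel_size)
      if (noise_sd > 0) {
        plane <- plane + matrix(rnorm(length(plane), 0, noise_sd),
                                nrow(plane), ncol(plane))
      }
      stack[, , k] <- plane
    }
    attr(stack, "pixel_size") <- gt$pixel_size
    attr(stack, "channel") <- channel
    attr(stack, "spot_values") <- v
    stack
  })
}

#' Simulate a quantal-imaging movie with its true event log
#'
#' At every stimulus each AZ releases independently with its true Pr
#' (a Bernoulli trial); spontaneous events arise as per-AZ Poisson processes
#' over the non-stimulus frames. Each release renders as an additive Gaussian
#' flash at the AZ position with single-frame rise and geometric decay. The
#' true event log (frame, AZ, evoked/spontaneous) is returned alongside the
#' movie, so detection and classification can be scored against ground truth.
#'
#' @param gt a [make_geometry()] ground truth.
#' @param spec a [movie_spec()].
#' @param render if `FALSE`, skip rendering and return only the event log
#'   (fast path for statistical checks).
#' @param seed RNG seed.
#' @return list of class `quantal_movie_sim` with elements `movie` (array
#'   `[row, col, frame]`, or `NULL` when `render = FALSE`), `events`
#'   (data.frame: `frame`, `az_id`, `x_um`, `y_um`, `kind`), `stim_frames`,
#'   `n_stimulations`, `spec`, `pixel_size`, `gt`.
#' @examples
#' gt <- make_geometry(1, 4, pr_distribution = 0.3, seed = 2)
#' sim <- simulate_quantal_movie(gt, movie_spec(duration = 20), seed = 3,
#'                               render = FALSE)
#' table(sim$events$kind)
#' @export
simulate_quantal_movie <- function(gt, spec = movie_spec(), render = TRUE,
                                   seed = 1) {
  stopifnot(inherits(gt, "nmj_ground_truth"), inherits(spec, "movie_spec"))
  s <- gt$synapses
  n_az <- nrow(s)
  nframes <- as.integer(round(spec$duration * spec$frame_rate))
  n_stim <- as.integer(floor(spec$duration * spec$stim_rate))
  stim_times <- (seq_len(n_stim) - 1L) / spec$stim_rate
  # stimulus -> frame: floor(t * frame_rate), 0-based, stored 1-based
  stim_frames <- as.integer(floor(stim_times * spec$frame_rate)) + 1L
  non_stim <- setdiff(seq_len(nframes), stim_frames)

  with_seed(seed, {
    ev <- vector("list", n_az)
    for (i in seq_len(n_az)) {
      hit <- which(rbinom(n_stim, 1L, s$true_pr[i]) == 1L)
      evoked_frames <- stim_frames[hit]
      # spontaneous: Poisson over the time not occupied by stimulus frames
      t_non <- spec$duration * length(non_stim) / nframes
      n_sp <- rpois(1L, s$spont_per_min[i] / 60 * t_non)
      sp_frames <- if (n_sp > 0 && length(non_stim) > 0) {
        sample(non_stim, n_sp, replace = TRUE)
      } else integer(0)
      n_i <- length(evoked_frames) + length(sp_frames)
      if (n_i == 0) next
      ev[[i]] <- data.frame(
        frame = c(evoked_frames, sp_frames),
        az_id = s$az_id[i],
        x_um = s$x_um[i], y_um = s$y_um[i],
        kind = rep(c("evoked", "spontaneous"),
                   c(length(evoked_frames), length(sp_frames)))
      )
    }
    events <- do.call(rbind, ev)
    if (is.null(events)) {
      events <- data.frame(frame = integer(0), az_id = integer(0),
                           x_um = numeric(0), y_um = numeric(0),
                           kind = character(0))
    }
    events <- events[order(events$frame, events$az_id), , drop = FALSE]
    rownames(events) <- NULL

    movie <- NULL
    if (render) {
      movie <- array(spec$background,
                     c(gt$field_dim[1], gt$field_dim[2], nframes))
      if (nrow(events)) {
        decay <- spec$flash_decay_factor^(0:spec$flash_decay_frames)
        for (e in seq_len(nrow(events))) {
          f0 <- events$frame[e]
          for (d in seq_along(decay)) {
            f <- f0 + d - 1L
            if (f > nframes) break
            movie[, , f] <- add_gaussian_spots(
              movie[, , f], events$x_um[e], events$y_um[e],
              spec$flash_amplitude * decay[d], spec$flash_sigma, gt$pixel_size)
          }
        }
      }
      if (spec$noise_sd > 0) {
        movie <- movie + array(rnorm(length(movie), 0, spec$noise_sd),
                               dim(movie))
      }
      attr(movie, "pixel_size") <- gt$pixel_size
    }

    structure(list(movie = movie, events = events, stim_frames = stim_frames,
                   n_stimulations = n_stim, spec = spec,
                   pixel_size = gt$pixel_size, gt = gt),
              class = "quantal_movie_sim")
  })
}

#' Simulate a photoconversion pulse-chase time series
#'
#' At photoconversion (t = 0) the entire pre-existing (green) pool of each
#' synapse converts to red, so the red channel at t = 0 equals the pre-PC
#' green total and no residual green remains. Red ("old") signal then decays
#' as `2^(-t / half_life)`; green ("new") signal accumulates either at
#' steady state (synthesis balancing first-order decay,
#' `base * (1 - 2^(-t/h))`) or linearly at a given delivery rate.
#'
#' @param gt a [make_geometry()] ground truth.
#' @param half_life_days protein half-life (days, > 0).
#' @param timepoints chase times in days, ascending from 0.
#' @param delivery_rate `"steady_state"` or a numeric delivery rate
#'   (units/day) for linear accumulation.
#' @param base_units optional per-synapse pre-PC protein amounts; default is
#'   a lognormal draw (median 100, sdlog 0.3).
#' @param intensity_per_unit,psf_sigma,noise_sd,background,n_planes rendering
#'   parameters, as in [render_puncta_stack()].
#' @param render if `FALSE`, return only the truth table.
#' @param seed RNG seed.
#' @return list of class `pc_series` with `timepoints`, `truth` (data.frame:
#'   `az_id`, `t_days`, `red_units`, `green_units`), `pre_pc_green` and
#'   `stacks` (per timepoint, a list with `red` and `green` Z-stack arrays).
#' @examples
#' gt <- make_geometry(1, 4, seed = 1)
#' pc <- simulate_photoconversion_series(gt, 2, c(0, 1), render = FALSE)
#' pc$truth[pc$truth$t_days == 1, "red_units"] / pc$pre_pc_green  # 2^(-1/2)
#' @export
simulate_photoconversion_series <- function(gt, half_life_days = 2.56,
                                            timepoints = c(0, 1),
                                            delivery_rate = "steady_state",
                                            base_units = NULL,
                                            intensity_per_unit = 5,
                                            psf_sigma = 0.18, noise_sd = 4,
                                            background = 20, n_planes = 5,
                                            render = TRUE, seed = 1) {
  stopifnot(inherits(gt, "nmj_ground_truth"))
  stopifnot_scalar(half_life_days, "half_life_days", 1e-9)
  if (length(timepoints) < 1 || any(timepoints < 0)) {
    stop("timepoints must be >= 0")
  }
  if (is.unsorted(timepoints)) stop("timepoints must be ascending")
  s <- gt$synapses
  n_az <- nrow(s)

  with_seed(seed, {
    if (is.null(base_units)) {
      base_units <- rlnorm(n_az, meanlog = log(100), sdlog = 0.3)
    }
    stopifnot(length(base_units) == n_az, all(base_units > 0))
    truth <- do.call(rbind, lapply(timepoints, function(t) {
      red <- base_units * 2^(-t / half_life_days)
      green <- if (identical(delivery_rate, "steady_state")) {
        base_units * (1 - 2^(-t / half_life_days))
      } else {
        stopifnot_scalar(delivery_rate, "delivery_rate", 0)
        rep(delivery_rate * t, n_az)
      }
      data.frame(az_id = s$az_id, t_days = t, red_units = red,
                 green_units = green)
    }))
    stacks <- NULL
    if (render) {
      seeds <- sample.int(.Machine$integer.max, 2 * length(timepoints))
      stacks <- lapply(seq_along(timepoints), function(k) {
        tr <- truth[truth$t_days == timepoints[k], ]
        list(
          red = render_puncta_stack(gt, "az", intensity_per_unit,
                                    values = tr$red_units,
                                    psf_sigma = psf_sigma, noise_sd = noise_sd,
                                    background = background,
                                    n_planes = n_planes,
                                    seed = seeds[2 * k - 1]),
          green = render_puncta_stack(gt, "az", intensity_per_unit,
                                      values = tr$green_units,
                                      psf_sigma = psf_sigma,
                                      noise_sd = noise_sd,
                                      background = background,
                                      n_planes = n_planes,
                                      seed = seeds[2 * k])
        )
      })
      names(stacks) <- paste0("t", timepoints)
    }
    structure(list(timepoints = timepoints, truth = truth,
                   pre_pc_green = base_units, stacks = stacks,
                   half_life_days = half_life_days, gt = gt),
              class = "pc_series")
  })
}
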
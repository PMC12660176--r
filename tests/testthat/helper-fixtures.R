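# Shared fixture builders; everything is generated in code at test time.

# Small deterministic geometry for unit tests
tiny_geometry <- function(n_boutons = 1, az_per_bouton = 4, seed = 1, ...) {
  make_geometry(n_boutons, az_per_bouton,
                pr_distribution = dist_spec("uniform", min = 0.1, max = 0.5),
                spont_distribution = dist_spec("constant", value = 1),
                seed = seed, ...)
}

# Independent dense renderer used as an oracle against add_gaussian_spots /
# render_puncta_stack: plain double loop over all pixels.
oracle_spot_image <- function(ny, nx, x_um, y_um, amp, sigma_um, pixel_size,
                              background = 0) {
  img <- matrix(background, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      px <- (j - 0.5) * pixel_size
      py <- (i - 0.5) * pixel_size
      for (k in seq_along(x_um)) {
        img[i, j] <- img[i, j] + amp[k] *
          exp(-((px - x_um[k])^2 + (py - y_um[k])^2) / (2 * sigma_um^2))
      }
    }
  }
  img
}

# Build a movie array with injected flashes at given frames/positions on a
# noisy constant background (independent of the package's renderer).
injected_movie <- function(ny, nx, nt, pixel_size, flashes,
                           amplitude = 50, sigma_um = 0.3, noise_sd = 1,
                           background = 100, seed = 99) {
  set.seed(seed)
  mov <- array(rnorm(ny * nx * nt, background, noise_sd), c(ny, nx, nt))
  for (r in seq_len(nrow(flashes))) {
    f <- flashes$frame[r]
    mov[, , f] <- mov[, , f] +
      oracle_spot_image(ny, nx, flashes$x_um[r], flashes$y_um[r], amplitude,
                        sigma_um, pixel_size)
  }
  attr(mov, "pixel_size") <- pixel_size
  mov
}

# Build a release_map from explicit per-ROI counts (helper around the
# public constructor path).
rmap_from_counts <- function(roi_id, evoked, spont, n_stim = 100,
                             duration_s = 300) {
  rois <- roi_set(roi_id, x_um = seq_along(roi_id), y_um = rep(0, length(roi_id)))
  ev <- do.call(rbind, lapply(seq_along(roi_id), function(i) {
    n <- evoked[i] + spont[i]
    if (n == 0) return(NULL)
    data.frame(frame = seq_len(n), x_um = i, y_um = 0, roi_id = roi_id[i],
               klass = rep(c("evoked", "spontaneous"), c(evoked[i], spont[i])))
  }))
  if (is.null(ev)) {
    ev <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                     roi_id = integer(0), klass = character(0))
  }
  release_map(ev, rois, n_stim, duration_s)
}
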
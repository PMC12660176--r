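#' Define a set of equal-size circular ROIs
#'
#' One ROI per release site (AZ or PSD), all with a common radius, in
#' physical coordinates.
#'
#' @param id integer ids (unique).
#' @param x_um,y_um centre positions (µm).
#' @param radius_um common ROI radius (µm, default 0.5).
#' @return data.frame of class `roi_set` with attribute `radius_um`.
#' @export
roi_set <- function(id, x_um, y_um, radius_um = 0.5) {
  stopifnot(length(id) == length(x_um), length(x_um) == length(y_um))
  if (anyDuplicated(id)) stop("ROI ids must be unique")
  stopifnot_scalar(radius_um, "radius_um", 1e-9)
  out <- data.frame(id = as.integer(id), x_um = x_um, y_um = y_um)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("roi_set", "data.frame"), radius_um = radius_um)
}

#' Derive ROIs from detected puncta
#'
#' @param set a `puncta_set` (e.g. the AZ-marker channel).
#' @param radius_um common ROI radius (µm).
#' @return a [roi_set()].
#' @export
rois_from_puncta <- function(set, radius_um = 0.5) {
  stopifnot(inherits(set, "puncta_set"))
  roi_set(set$puncta$id, set$puncta$x_um, set$puncta$y_um, radius_um)
}

#' Detect GCaMP flash events in a time-lapse movie
#'
#' Per-pixel fluorescence change is computed against a rolling-percentile
#' baseline (20th percentile over a trailing window), spatially smoothed, and
#' normalised by a robust per-pixel noise estimate (median absolute
#' deviation). Frames are scanned for 8-neighbour local maxima above
#' `k_sigma`; each peak becomes an event with a sub-pixel intensity-weighted
#' position. A per-position refractory rule suppresses re-detections of the
#' same flash during its decay: a candidate within `refractory_radius_um` of
#' an event accepted in the previous `min_separation` frames is dropped.
#'
#' @param movie numeric array `[row, col, frame]`, or a
#'   [simulate_quantal_movie()] result (its rendered movie is used).
#' @param pixel_size µm per pixel; taken from the movie attribute if absent.
#' @param baseline_window trailing baseline window (frames, default 16).
#' @param baseline_prob baseline percentile (default 0.2).
#' @param k_sigma detection threshold in units of per-pixel noise s.d.
#' @param min_separation refractory period (frames, default 2).
#' @param refractory_radius_um refractory radius (µm, default 0.5).
#' @param smooth_sigma_px spatial Gaussian smoothing s.d. (pixels).
#' @return data.frame of class `quantal_events`: `frame`, `x_um`, `y_um`,
#'   `peak_z` (noise-normalised amplitude), `peak_dff` (baseline-subtracted
#'   amplitude). Attributes: `n_frames`, `pixel_size`, detection parameters.
#' @examples
#' gt <- make_geometry(1, 3, pr_distribution = 0.5, seed = 1)
#' sim <- simulate_quantal_movie(gt, movie_spec(duration = 10), seed = 1)
#' ev <- detect_events(sim)
#' @export
detect_events <- function(movie, pixel_size = NULL, baseline_window = 16,
                          baseline_prob = 0.2, k_sigma = 5,
                          min_separation = 2, refractory_radius_um = 0.5,
                          smooth_sigma_px = 1) {
  if (inherits(movie, "quantal_movie_sim")) {
    if (is.null(movie$movie)) stop("simulation was run with render = FALSE")
    pixel_size <- movie$pixel_size
    movie <- movie$movie
  }
  stopifnot(is.array(movie), length(dim(movie)) == 3)
  if (is.null(pixel_size)) pixel_size <- attr(movie, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size not given and not an attribute of 'movie'")
  dm <- dim(movie)
  ny <- dm[1]; nx <- dm[2]; nt <- dm[3]
  if (nt < baseline_window) stop("movie shorter than baseline_window")

  px <- movie
  dim(px) <- c(ny * nx, nt)
  baseline <- cpp_roll_quantile(px, as.integer(baseline_window), baseline_prob)
  dff <- px - baseline
  rm(px, baseline)
  dim(dff) <- c(ny, nx, nt)
  sm <- cpp_gauss_smooth_frames(dff, ny, nx, nt, smooth_sigma_px)
  rm(dff)
  dim(sm) <- c(ny * nx, nt)
  # Robust per-pixel centre and noise of the smoothed trace: the rolling
  # percentile baseline sits below the mean, so dF/F carries a positive
  # offset that must be removed before noise-normalising.
  mm <- cpp_row_medmad(sm)
  # floor each pixel's noise at the field-wide median: sampling error of the
  # per-pixel MAD otherwise inflates z scores on short recordings
  noise <- pmax(mm[, "mad"], median(mm[, "mad"]), 1e-12)
  # an all-constant movie has identically zero dF everywhere: no events
  flat <- diff(range(sm)) <= 1e-12
  zmat <- (sm - mm[, "median"]) / noise
  dim(sm) <- c(ny, nx, nt)
  dim(zmat) <- c(ny, nx, nt)

  # accumulate events in a preallocated matrix (frame, x, y, z, dff)
  ev_buf <- matrix(NA_real_, 256L, 5L)
  n_ev <- 0L
  push_ev <- function(row) {
    if (n_ev == nrow(ev_buf)) {
      ev_buf <<- rbind(ev_buf, matrix(NA_real_, nrow(ev_buf), 5L))
    }
    n_ev <<- n_ev + 1L
    ev_buf[n_ev, ] <<- row
  }
  recent_from <- 1L  # events with index >= recent_from are recent candidates
  for (t in seq_len(nt)) {
    if (flat) break
    # drop events older than the refractory window
    while (recent_from <= n_ev && ev_buf[recent_from, 1] < t - min_separation) {
      recent_from <- recent_from + 1L
    }
    pk <- cpp_local_maxima(zmat[, , t], k_sigma)
    if (nrow(pk) == 0) next
    frame_start <- n_ev + 1L  # same-frame events never suppress each other
    for (i in seq_len(nrow(pk))) {
      r0 <- as.integer(pk[i, 1]); c0 <- as.integer(pk[i, 2])
      rr <- max(1L, r0 - 1L):min(ny, r0 + 1L)
      cc <- max(1L, c0 - 1L):min(nx, c0 + 1L)
      w <- pmax(sm[rr, cc, t], 0)
      if (sum(w) == 0) w[] <- 1
      x_um <- sum(w * matrix(px_to_um(cc, pixel_size), length(rr),
                             length(cc), byrow = TRUE)) / sum(w)
      y_um <- sum(w * matrix(px_to_um(rr, pixel_size), length(rr),
                             length(cc))) / sum(w)
      if (recent_from < frame_start) {
        prev <- seq.int(recent_from, frame_start - 1L)
        d2 <- (ev_buf[prev, 2] - x_um)^2 + (ev_buf[prev, 3] - y_um)^2
        if (any(d2 <= refractory_radius_um^2)) next  # decay of a counted flash
      }
      push_ev(c(t, x_um, y_um, pk[i, 3], sm[r0, c0, t]))
    }
  }
  ev <- data.frame(frame = as.integer(ev_buf[seq_len(n_ev), 1]),
                   x_um = ev_buf[seq_len(n_ev), 2],
                   y_um = ev_buf[seq_len(n_ev), 3],
                   peak_z = ev_buf[seq_len(n_ev), 4],
                   peak_dff = ev_buf[seq_len(n_ev), 5])
  structure(ev, class = c("quantal_events", "data.frame"),
            n_frames = nt, pixel_size = pixel_size, k_sigma = k_sigma,
            baseline_window = baseline_window,
            min_separation = min_separation)
}

#' Assign detected events to the nearest ROI within a distance threshold
#'
#' Each event is assigned to the nearest ROI centre if and only if the
#' centroid distance is at most `max_dist` µm (default 0.8 µm); otherwise it
#' is left unassigned. An event is assigned to at most one ROI; exact
#' distance ties go to the lowest ROI id.
#'
#' @param events a `quantal_events` data.frame (or any data.frame with
#'   `x_um`, `y_um`).
#' @param rois a [roi_set()].
#' @param max_dist assignment threshold (µm).
#' @return `events` with columns `roi_id` (`NA` = unassigned) and `roi_dist_um`.
#' @export
assign_events <- function(events, rois, max_dist = 0.8) {
  stopifnot(is.data.frame(events), inherits(rois, "roi_set"))
  stopifnot_scalar(max_dist, "max_dist", 0)
  events$roi_id <- NA_integer_
  events$roi_dist_um <- NA_real_
  if (nrow(events) && nrow(rois)) {
    d <- sqrt(outer(events$x_um, rois$x_um, "-")^2 +
              outer(events$y_um, rois$y_um, "-")^2)
    nearest <- apply(d, 1, which.min)  # rois sorted by id: ties -> lowest id
    dist <- d[cbind(seq_len(nrow(events)), nearest)]
    ok <- dist <= max_dist
    events$roi_id[ok] <- rois$id[nearest[ok]]
    events$roi_dist_um[ok] <- dist[ok]
  }
  events
}

#' Classify events as evoked or spontaneous by frame coincidence
#'
#' Frames with at least `min_simultaneous` simultaneous events across the
#' NMJ are evoked frames (action-potential-triggered multi-site release
#' under nerve stimulation); every event in such a frame is classified
#' evoked. Events in other frames are spontaneous, except that an event in
#' the frame immediately following an evoked frame and within
#' `decay_radius_um` of an evoked event's position is attributed to that
#' flash's decay (class `"decay"`) rather than counted as new release.
#'
#' @param events event data.frame (from [assign_events()] or
#'   [detect_events()]).
#' @param min_simultaneous coincidence threshold (default 3).
#' @param attribute_decay apply the decay-attribution rule (default TRUE).
#' @param decay_radius_um radius for decay attribution (µm).
#' @return `events` with a `klass` column (`"evoked"`, `"spontaneous"` or
#'   `"decay"`) and attribute `evoked_frames`.
#' @export
classify_frames <- function(events, min_simultaneous = 3,
                            attribute_decay = TRUE, decay_radius_um = 0.5) {
  stopifnot(is.data.frame(events))
  stopifnot_scalar(min_simultaneous, "min_simultaneous", 1)
  events$klass <- rep("spontaneous", nrow(events))
  evoked_frames <- integer(0)
  if (nrow(events)) {
    counts <- table(events$frame)
    evoked_frames <- as.integer(names(counts)[counts >= min_simultaneous])
    is_ev <- events$frame %in% evoked_frames
    events$klass[is_ev] <- "evoked"
    if (attribute_decay && length(evoked_frames)) {
      follow <- !is_ev & (events$frame - 1L) %in% evoked_frames
      for (i in which(follow)) {
        prev <- events[is_ev & events$frame == events$frame[i] - 1L, , drop = FALSE]
        d2 <- (prev$x_um - events$x_um[i])^2 + (prev$y_um - events$y_um[i])^2
        if (any(d2 <= decay_radius_um^2)) events$klass[i] <- "decay"
      }
    }
  }
  attr(events, "evoked_frames") <- evoked_frames
  events
}

#' Per-ROI release map: evoked Pr and spontaneous rate
#'
#' Evoked events per ROI divided by the number of stimulations give the
#' release probability Pr; spontaneous events per ROI divided by the
#' recording duration give the spontaneous rate in events/min. Unassigned
#' events and decay-attributed events are excluded from per-ROI tallies but
#' reported in the summary attributes.
#'
#' @param events classified, assigned event data.frame (needs `roi_id` and
#'   `klass` columns).
#' @param rois a [roi_set()]; every ROI appears in the map, silent sites with
#'   zero counts.
#' @param n_stimulations number of nerve stimulations delivered (>= 1).
#' @param duration_s recording duration in seconds (> 0).
#' @return data.frame of class `release_map`: `roi_id`, `evoked_count`, `pr`,
#'   `spont_count`, `spont_per_min`, `pr_flagged` (TRUE where the evoked
#'   count exceeded `n_stimulations`, suggesting double counting). Attributes
#'   `n_unassigned`, `n_decay`, `n_stimulations`, `duration_s`.
#' @examples
#' rois <- roi_set(1, 0, 0)
#' ev <- data.frame(frame = 1:4, x_um = 0, y_um = 0, roi_id = 1,
#'                  klass = c("evoked", "evoked", "spontaneous", "spontaneous"))
#' release_map(ev, rois, n_stimulations = 20, duration_s = 120)
#' @export
release_map <- function(events, rois, n_stimulations, duration_s) {
  stopifnot(is.data.frame(events), inherits(rois, "roi_set"))
  stopifnot_scalar(n_stimulations, "n_stimulations", 1)
  stopifnot_scalar(duration_s, "duration_s", 1e-9)
  if (!"roi_id" %in% names(events)) stop("events must be assigned (assign_events)")
  if (!"klass" %in% names(events)) stop("events must be classified (classify_frames)")
  cnt <- function(k) {
    sub <- events[events$klass == k & !is.na(events$roi_id), , drop = FALSE]
    tab <- table(factor(sub$roi_id, levels = rois$id))
    as.integer(tab)
  }
  evoked <- cnt("evoked")
  spont <- cnt("spontaneous")
  pr <- evoked / n_stimulations
  flagged <- pr > 1
  if (any(flagged)) {
    warning(sprintf("%d ROI(s) with more evoked events than stimulations; double counting suspected",
                    sum(flagged)))
  }
  out <- data.frame(roi_id = rois$id, evoked_count = evoked, pr = pr,
                    spont_count = spont,
                    spont_per_min = spont / (duration_s / 60),
                    pr_flagged = flagged)
  structure(out, class = c("release_map", "data.frame"),
            n_unassigned = sum(is.na(events$roi_id)),
            n_decay = sum(events$klass == "decay"),
            n_stimulations = n_stimulations, duration_s = duration_s)
}

#' Full quantal-imaging analysis of one movie
#'
#' Convenience wrapper: detect events, assign them to ROIs, classify frames
#' and build the release map.
#'
#' @param movie movie array or [simulate_quantal_movie()] result.
#' @param rois a [roi_set()].
#' @param n_stimulations,duration_s protocol parameters; taken from the
#'   simulation object if omitted.
#' @param ... passed to [detect_events()].
#' @param assign_max_dist assignment threshold (µm).
#' @param min_simultaneous evoked-frame coincidence threshold.
#' @return list with `events` (classified, assigned) and `map`
#'   (a [release_map()]).
#' @export
map_release <- function(movie, rois, n_stimulations = NULL, duration_s = NULL,
                        assign_max_dist = 0.8, min_simultaneous = 3, ...) {
  if (inherits(movie, "quantal_movie_sim")) {
    if (is.null(n_stimulations)) n_stimulations <- movie$n_stimulations
    if (is.null(duration_s)) duration_s <- movie$spec$duration
  }
  if (is.null(n_stimulations) || is.null(duration_s)) {
    stop("n_stimulations and duration_s are required for plain movie arrays")
  }
  ev <- detect_events(movie, ...)
  ev <- assign_events(ev, rois, max_dist = assign_max_dist)
  ev <- classify_frames(ev, min_simultaneous = min_simultaneous)
  list(events = ev, map = release_map(ev, rois, n_stimulations, duration_s))
}
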
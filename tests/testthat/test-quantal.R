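test_that("a flat noise movie yields no events", {
  set.seed(50)
  mov <- array(rnorm(20 * 20 * 60, 100, 1), c(20, 20, 60))
  attr(mov, "pixel_size") <- 0.133
  ev <- detect_events(mov, k_sigma = 6)
  expect_equal(nrow(ev), 0)
  # all-constant movie: zero events, no errors
  const <- array(100, c(10, 10, 40))
  expect_equal(nrow(detect_events(const, pixel_size = 0.1)), 0)
})

test_that("injected flashes are recovered at the right frame and position", {
  px <- 0.133
  fl <- data.frame(frame = 30, x_um = 1.33, y_um = 1.33)
  mov <- injected_movie(24, 24, 60, px, fl, amplitude = 10, noise_sd = 1,
                        seed = 51)
  ev <- detect_events(mov, k_sigma = 6)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 30)
  expect_lt(abs(ev$x_um - 1.33), px)
  expect_lt(abs(ev$y_um - 1.33), px)

  # two flashes in the same frame, 3 um apart -> two events
  fl2 <- data.frame(frame = c(25, 25), x_um = c(1.0, 4.0), y_um = c(2.0, 2.0))
  mov2 <- injected_movie(40, 44, 50, px, fl2, amplitude = 10, noise_sd = 1,
                         seed = 52)
  ev2 <- detect_events(mov2, k_sigma = 6)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$frame, c(25, 25))
  expect_equal(sort(ev2$x_um), c(1.0, 4.0), tolerance = px)
})

test_that("a decaying flash is counted once (refractory suppression)", {
  px <- 0.133
  # same position, consecutive frames with halving amplitude = one flash decay
  fl <- data.frame(frame = c(20, 21, 22), x_um = 1.5, y_um = 1.5)
  mov <- injected_movie(24, 24, 50, px, fl[1, ], amplitude = 12, noise_sd = 1,
                        seed = 53)
  mov[, , 21] <- mov[, , 21] + oracle_spot_image(24, 24, 1.5, 1.5, 6, 0.3, px)
  mov[, , 22] <- mov[, , 22] + oracle_spot_image(24, 24, 1.5, 1.5, 3, 0.3, px)
  ev <- detect_events(mov)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 20)
})

test_that("nearest-ROI assignment honours the distance threshold and tie rule", {
  rois <- roi_set(c(1, 2), x_um = c(0, 1.7), y_um = c(0, 0))
  ev <- data.frame(frame = 1:3,
                   x_um = c(0.5, 0.0, 0.85), y_um = c(0, 0.9, 0))
  out <- assign_events(ev, rois, max_dist = 0.8)
  expect_equal(out$roi_id[1], 1)       # 0.5 vs 1.2 um -> ROI 1
  expect_true(is.na(out$roi_id[2]))    # 0.9 um -> unassigned
  # exactly equidistant within the threshold -> lowest id wins
  rois2 <- roi_set(c(1, 2), x_um = c(0, 1), y_um = c(0, 0))
  tie <- assign_events(data.frame(frame = 1, x_um = 0.5, y_um = 0), rois2, 0.8)
  expect_equal(tie$roi_id, 1L)
})

test_that("assignment matches an all-pairs brute-force scan", {
  set.seed(60)
  for (rep in 1:200) {
    n_ev <- sample(1:12, 1)
    n_roi <- sample(1:10, 1)
    ev <- data.frame(frame = seq_len(n_ev),
                     x_um = runif(n_ev, 0, 6), y_um = runif(n_ev, 0, 6))
    rois <- roi_set(seq_len(n_roi), runif(n_roi, 0, 6), runif(n_roi, 0, 6))
    out <- assign_events(ev, rois, 0.8)
    for (i in seq_len(n_ev)) {
      best <- NA_integer_; bestd <- Inf
      for (j in seq_len(n_roi)) {
        d <- sqrt((ev$x_um[i] - rois$x_um[j])^2 + (ev$y_um[i] - rois$y_um[j])^2)
        if (d < bestd) { bestd <- d; best <- rois$id[j] }
      }
      if (bestd <= 0.8) expect_identical(out$roi_id[i], best)
      else expect_true(is.na(out$roi_id[i]))
    }
  }
})

test_that("frames with >= 3 simultaneous events are evoked, others spontaneous", {
  ev <- data.frame(frame = c(5, 5, 5, 9, 9, 12),
                   x_um = c(1, 3, 5, 1, 3, 5), y_um = 1)
  out <- classify_frames(ev, min_simultaneous = 3)
  expect_equal(out$klass, c("evoked", "evoked", "evoked",
                            "spontaneous", "spontaneous", "spontaneous"))
  expect_equal(attr(out, "evoked_frames"), 5L)

  none <- classify_frames(ev[0, ])
  expect_equal(attr(none, "evoked_frames"), integer(0))

  # event right after an evoked frame at an evoked position -> decay
  ev2 <- data.frame(frame = c(5, 5, 5, 6, 6),
                    x_um = c(1, 3, 5, 1.1, 9), y_um = 1)
  out2 <- classify_frames(ev2, min_simultaneous = 3)
  expect_equal(out2$klass[4], "decay")
  expect_equal(out2$klass[5], "spontaneous")
})

test_that("release map arithmetic and conservation", {
  rm1 <- rmap_from_counts(roi_id = 1:3, evoked = c(30, 0, 4),
                          spont = c(0, 0, 4), n_stim = 300, duration_s = 300)
  expect_equal(rm1$pr, c(0.1, 0, 4 / 300))
  expect_equal(rm1$spont_per_min, c(0, 0, 0.8))
  # silent site reported with zeros
  expect_equal(rm1$evoked_count[2] + rm1$spont_count[2], 0)

  # warning when evoked events exceed stimulation count
  expect_warning(
    rmap_from_counts(1, evoked = 31, spont = 0, n_stim = 30),
    "double counting")
})

test_that("event conservation holds through the full movie pipeline", {
  gt <- make_geometry(2, 5, cac_negative_fraction = 0.2, seed = 70)
  sim <- simulate_quantal_movie(gt, movie_spec(duration = 40), seed = 71)
  rois <- roi_set(gt$synapses$az_id, gt$synapses$x_um, gt$synapses$y_um)
  res <- map_release(sim, rois)
  ev <- res$events
  # every detected event has exactly one class
  expect_equal(sum(ev$klass == "evoked") + sum(ev$klass == "spontaneous") +
                 sum(ev$klass == "decay"), nrow(ev))
  # per-ROI tallies + unassigned + decay account for every event
  expect_equal(sum(res$map$evoked_count) + sum(res$map$spont_count) +
                 sum(is.na(ev$roi_id) & ev$klass != "decay") +
                 attr(res$map, "n_decay"),
               nrow(ev))
  expect_true(all(res$map$pr >= 0 & res$map$pr <= 1))
})

test_that("detection and mapping are deterministic for a fixed movie", {
  gt <- make_geometry(1, 5, seed = 80)
  sim <- simulate_quantal_movie(gt, movie_spec(duration = 30), seed = 81)
  rois <- roi_set(gt$synapses$az_id, gt$synapses$x_um, gt$synapses$y_um)
  a <- map_release(sim, rois)
  b <- map_release(sim, rois)
  expect_identical(a$events, b$events)
  expect_identical(as.data.frame(a$map), as.data.frame(b$map))
})

test_that("Cac-negative sites show no more evoked signal than detector false positives", {
  gt <- make_geometry(2, 8, cac_negative_fraction = 0.5,
                      spont_distribution = 1, seed = 90)
  sim <- simulate_quantal_movie(gt, movie_spec(duration = 120), seed = 91)
  rois <- roi_set(gt$synapses$az_id, gt$synapses$x_um, gt$synapses$y_um)
  res <- map_release(sim, rois)
  neg <- !gt$synapses$cac_positive
  pr_neg <- mean(res$map$pr[match(gt$synapses$az_id[neg], res$map$roi_id)])

  # detector false-positive rate: same geometry, no release at all
  gt0 <- make_geometry(2, 8, pr_distribution = 0, spont_distribution = 0,
                       cac_negative_fraction = 0, seed = 90)
  sim0 <- simulate_quantal_movie(gt0, movie_spec(duration = 120), seed = 92)
  ev0 <- assign_events(detect_events(sim0), rois)
  fp_rate <- sum(!is.na(ev0$roi_id)) / nrow(rois) / sim0$n_stimulations
  expect_lte(pr_neg, fp_rate)
})
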
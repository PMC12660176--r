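test_that("max projection equals the per-pixel maximum over planes", {
  one <- array(matrix(1:12, 3, 4), c(3, 4, 1))
  expect_equal(max_project(one), matrix(1:12, 3, 4))

  a <- matrix(0, 4, 4); a[1, 1] <- 5
  b <- matrix(0, 4, 4); b[3, 2] <- 7
  expect_equal(max_project(array(c(a, b), c(4, 4, 2))), pmax(a, b))

  set.seed(1)
  stk <- array(rnorm(5 * 6 * 5), c(5, 6, 5))
  oracle <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6) oracle[i, j] <- max(stk[i, j, ])
  expect_equal(max_project(stk), oracle)

  expect_error(max_project(array(0, c(2, 2, 0))), "plane")
})

test_that("well-separated rendered spots are each detected near their centroid", {
  gt <- make_geometry(1, 5, az_min_dist_um = 1.6, seed = 20)
  stk <- render_puncta_stack(gt, "az", noise_sd = 3, seed = 21)
  ps <- detect_puncta(max_project(stk))
  expect_equal(nrow(ps$puncta), 5)
  s <- gt$synapses
  for (k in seq_len(5)) {
    d <- sqrt((ps$puncta$x_um - s$x_um[k])^2 + (ps$puncta$y_um - s$y_um[k])^2)
    expect_lt(min(d), gt$pixel_size)  # centroid within 1 px of truth
  }
  expect_true(all(ps$puncta$area_um2 > 0))
  expect_true(all(ps$puncta$sum_intensity >= ps$puncta$mean_intensity))
})

test_that("blank planes and merged spots behave as defined", {
  blank <- matrix(rnorm(900, 10, 1), 30, 30)
  expect_equal(nrow(detect_puncta(blank, pixel_size = 0.1)$puncta), 0)

  # two overlapping spots become one 8-connected component
  img <- oracle_spot_image(30, 30, c(1.4, 1.7), c(1.5, 1.5), c(50, 50), 0.2,
                           0.1, background = 0)
  ps <- detect_puncta(img, threshold = 5, pixel_size = 0.1)
  expect_equal(nrow(ps$puncta), 1)

  expect_warning(detect_puncta(matrix(10, 20, 20), threshold = 5,
                               pixel_size = 0.1), "saturated|constant")
})

test_that("diagonally touching pixels join one component (8-connectivity)", {
  img <- matrix(0, 12, 12)
  img[3, 3] <- 10; img[4, 4] <- 10; img[5, 5] <- 10; img[6, 6] <- 10
  ps <- detect_puncta(img, threshold = 5, min_area_px = 1, pixel_size = 0.1)
  expect_equal(nrow(ps$puncta), 1)
  expect_equal(ps$puncta$area_px, 4)
})

test_that("detection is translation-equivariant for whole-pixel shifts", {
  gt <- make_geometry(1, 4, az_min_dist_um = 1.6, seed = 23)
  pl <- max_project(render_puncta_stack(gt, "az", noise_sd = 2, seed = 24))
  shift <- function(m, dy, dx) {
    out <- matrix(median(m), nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  ps0 <- detect_puncta(pl, pixel_size = gt$pixel_size)
  ps1 <- detect_puncta(shift(pl, 3, 5), pixel_size = gt$pixel_size,
                       threshold = ps0$threshold_used)
  expect_equal(nrow(ps1$puncta), nrow(ps0$puncta))
  o0 <- order(ps0$puncta$x_um)
  o1 <- order(ps1$puncta$x_um)
  expect_equal(ps1$puncta$x_um[o1], ps0$puncta$x_um[o0] + 5 * gt$pixel_size,
               tolerance = 1e-6)
  expect_equal(ps1$puncta$y_um[o1], ps0$puncta$y_um[o0] + 3 * gt$pixel_size,
               tolerance = 1e-6)
})

test_that("colocalization fractions match an all-pairs brute-force scan", {
  # identical sets: nothing lacking, at any radius
  a <- as_puncta_set(data.frame(x_um = runif(10, 0, 5), y_um = runif(10, 0, 5)))
  expect_equal(colocalize_fraction(a, a, 0.01)$pct_a_lacking_b, 0)

  # constructed: 3 of 10 lack a partner within 0.8
  xa <- seq(0, 18, by = 2)  # spacing well beyond the cutoff
  a2 <- as_puncta_set(data.frame(x_um = xa, y_um = 0))
  b2 <- as_puncta_set(data.frame(x_um = xa[1:7] + 0.2, y_um = 0.1))
  res <- colocalize_fraction(a2, b2, 0.8)
  expect_equal(res$pct_a_lacking_b, 30)

  # randomised positions against the O(n^2) oracle
  set.seed(31)
  for (rep in 1:20) {
    pa <- data.frame(x_um = runif(15, 0, 8), y_um = runif(15, 0, 8))
    pb <- data.frame(x_um = runif(12, 0, 8), y_um = runif(12, 0, 8))
    res <- colocalize_fraction(as_puncta_set(pa), as_puncta_set(pb), 0.8)
    lack <- 0
    for (i in seq_len(nrow(pa))) {
      has <- FALSE
      for (j in seq_len(nrow(pb))) {
        if (sqrt((pa$x_um[i] - pb$x_um[j])^2 + (pa$y_um[i] - pb$y_um[j])^2) <= 0.8) {
          has <- TRUE
        }
      }
      if (!has) lack <- lack + 1
    }
    expect_equal(res$pct_a_lacking_b, 100 * lack / nrow(pa))
  }

  # empty set reported missing, not zero
  empty <- as_puncta_set(data.frame(x_um = numeric(0), y_um = numeric(0)))
  expect_true(is.na(colocalize_fraction(empty, a, 0.8)$pct_a_lacking_b))
})

test_that("opposition pairing recovers identity pairs under jitter and conserves counts", {
  gt <- make_geometry(2, 5, psd_jitter_um = 0.2, seed = 33)  # sigma = max_dist/4
  s <- gt$synapses
  az <- as_puncta_set(data.frame(id = s$az_id, x_um = s$x_um, y_um = s$y_um))
  psd <- as_puncta_set(data.frame(id = s$az_id, x_um = s$psd_x_um,
                                  y_um = s$psd_y_um))
  pp <- opposition_pairs(az, psd, 0.8)
  paired <- pp[!is.na(pp$az_id) & !is.na(pp$psd_id), ]
  expect_equal(nrow(paired), nrow(s))       # 100% paired
  expect_equal(paired$az_id, paired$psd_id) # each AZ to its own PSD

  # one orphan PSD stays unpaired
  psd2 <- as_puncta_set(data.frame(id = c(s$az_id, 99),
                                   x_um = c(s$psd_x_um, max(s$x_um) + 5),
                                   y_um = c(s$psd_y_um, 1)))
  pp2 <- opposition_pairs(az, psd2, 0.8)
  unpaired_psd <- pp2$psd_id[is.na(pp2$az_id)]
  expect_equal(unpaired_psd, 99)

  # conservation: paired + unpaired entries equal the set sizes
  expect_equal(sum(!is.na(pp2$az_id)), nrow(az$puncta))
  expect_equal(sum(!is.na(pp2$psd_id)), nrow(psd2$puncta))
  expect_equal(attr(pp2, "n_paired"), nrow(s))
})

test_that("puncta density is count per 10 square microns", {
  mk <- function(n, area) as_puncta_set(
    data.frame(x_um = seq_len(n), y_um = rep(1, n)), nmj_area_um2 = area)
  expect_equal(puncta_density(mk(20, 10)), 20)
  expect_equal(puncta_density(mk(7, 35)), 2)
  empty <- as_puncta_set(data.frame(x_um = numeric(0), y_um = numeric(0)),
                         nmj_area_um2 = 12)
  expect_equal(puncta_density(empty), 0)
  expect_error(puncta_density(mk(3, NA)), "nmj_area")
})

test_that("measure_channel re-measures a second channel over identical masks", {
  img <- matrix(0, 20, 20)
  img[5:7, 5:7] <- 100
  img[14:16, 12:14] <- 80
  ps <- detect_puncta(img, threshold = 10, pixel_size = 0.1)
  other <- matrix(1, 20, 20)
  other[5:7, 5:7] <- 3
  m <- measure_channel(ps, other, background_subtract = FALSE)
  expect_equal(sort(m$sum), c(9 * 1, 9 * 3))
})
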
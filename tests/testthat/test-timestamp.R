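test_that("age classification basics: zero red is new, max red normalises to 1", {
  lab <- classify_age(data.frame(psd_id = 1:4, red_sum = c(0, 2, 8, 4)))
  expect_equal(lab$age_class, c("new", "old", "old", "old"))
  expect_equal(lab$norm_red, c(0, 0.25, 1, 0.5))
  expect_equal(lab$norm_red[which.max(lab$red_sum)], 1.0)

  # all-equal red: every PSD at the per-NMJ maximum
  same <- classify_age(data.frame(psd_id = 1:3, red_sum = c(5, 5, 5)))
  expect_equal(same$norm_red, rep(1, 3))

  empty <- classify_age(data.frame(psd_id = integer(0), red_sum = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("norm_red is invariant to global rescaling of the red channel", {
  red <- c(1.2, 7.5, 3.3, 0, 9.1)
  a <- classify_age(data.frame(psd_id = 1:5, red_sum = red))
  b <- classify_age(data.frame(psd_id = 1:5, red_sum = red * 37.5))
  expect_equal(a$norm_red, b$norm_red)
})

test_that("old/new classification is monotone in the red threshold", {
  set.seed(100)
  red <- rlnorm(40, 2, 1)
  prev_old <- rep(TRUE, 40)
  for (thr in sort(runif(12, 0, max(red)))) {
    lab <- classify_age(data.frame(psd_id = 1:40, red_sum = red),
                        red_threshold = thr)
    old <- lab$age_class == "old"
    expect_true(all(old <= prev_old))  # raising thr never makes new -> old
    prev_old <- old
  }
})

test_that("perfectly linear Pr in norm_red gives r = 1; permutation matches the hand formula", {
  red <- seq(10, 100, by = 10)
  lab <- classify_age(data.frame(psd_id = 1:10, red_sum = red))
  rmap <- rmap_from_counts(1:10, evoked = 2 * (1:10), spont = rep(1, 10),
                           n_stim = 100)
  res <- age_output_correlation(lab, rmap)
  expect_equal(res$r_pr, 1)

  set.seed(101)
  perm <- sample(10)
  rmap2 <- rmap_from_counts(1:10, evoked = (2 * (1:10))[perm],
                            spont = rep(1, 10), n_stim = 100)
  res2 <- age_output_correlation(lab, rmap2)
  x <- lab$norm_red; y <- rmap2$pr
  hand_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res2$r_pr, hand_r)
  expect_lt(abs(res2$r_pr), 0.7)

  expect_error(age_output_correlation(lab[1:2, ], rmap), "fewer than 3")
})

test_that("a maturation model's correlation is recovered from binomial Pr estimates", {
  # pr = a * norm_red + noise, estimated via binomial sampling at 300 stimuli
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 100
    red <- runif(n, 5, 100)
    norm_red <- red / max(red)
    p_true <- pmin(pmax(0.05 + 0.35 * norm_red + rnorm(n, 0, 0.05), 0), 1)
    counts <- rbinom(n, 300, p_true)
    lab <- classify_age(data.frame(psd_id = 1:n, red_sum = red))
    rmap <- rmap_from_counts(1:n, evoked = counts, spont = rep(0, n),
                             n_stim = 300)
    generative_r <- cor(norm_red, p_true)
    age_output_correlation(lab, rmap)$r_pr - generative_r
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.1)
  expect_lt(max(abs(errs)), 0.15)
})

test_that("mean Pr of old PSDs exceeds new whenever Pr increases with age", {
  set.seed(102)
  n <- 60
  red <- c(rep(0, 25), rlnorm(35, 3, 0.6))   # new PSDs have no old receptor
  p_true <- 0.02 + 0.4 * red / max(red)
  counts <- rbinom(n, 300, p_true)
  rmap <- rmap_from_counts(1:n, evoked = counts, spont = rep(0, n), n_stim = 300)
  for (thr in c(0, 5, 20, 60)) {
    lab <- classify_age(data.frame(psd_id = 1:n, red_sum = red),
                        red_threshold = thr)
    res <- age_output_correlation(lab, rmap)
    expect_gt(res$mean_pr_old, res$mean_pr_new)
  }
})

test_that("bouton position fractions pick out terminal and second boutons", {
  lab <- classify_age(data.frame(psd_id = 1:12,
                                 red_sum = c(rep(5, 6), rep(c(5, 0, 0), 2))))
  # terminal bouton (0): all 6 old -> 100%; bouton 1: 2 old of 6 -> 33.3%
  bi <- rep(c(0, 1), each = 6)
  bf <- bouton_position_fraction(lab, bi)
  expect_equal(bf$terminal_pct, 100)
  expect_equal(bf$second_pct, 100 / 3, tolerance = 1e-9)
  expect_equal(bf$per_bouton$n_psd, c(6, 6))

  # empty bouton excluded with a warning
  expect_warning(bouton_position_fraction(lab, rep(c(0, 2), each = 6)),
                 "without PSDs")
})

test_that("stretching growth enriches old PSDs at the terminal bouton", {
  gt <- make_geometry(5, 8, growth_mode = "stretching", seed = 104)
  s <- gt$synapses
  days_pc <- 3  # synapses older than the chase carry old receptor
  red <- pmax(s$age_days - days_pc, 0)
  lab <- classify_age(data.frame(psd_id = s$az_id, red_sum = red))
  bf <- bouton_position_fraction(lab, s$bouton_index)
  interior <- bf$per_bouton$pct_old[bf$per_bouton$bouton_index == 2]
  expect_gt(bf$terminal_pct, interior)
})

test_that("old-PSD count stability ratio", {
  mk <- function(n_old, n_new) classify_age(
    data.frame(psd_id = seq_len(n_old + n_new),
               red_sum = rep(c(5, 0), c(n_old, n_new))))
  expect_equal(count_old_psd_stability(mk(20, 0), mk(20, 5)), 100)
  expect_equal(count_old_psd_stability(mk(20, 0), mk(21, 0)), 105)
  expect_error(count_old_psd_stability(mk(0, 5), mk(3, 0)), "no old PSDs")

  # conservation by construction: old pool fixed while NMJ grows
  t1 <- mk(15, 10)
  t2 <- mk(15, 30)
  expect_equal(count_old_psd_stability(t1, t2), 100)
})

test_that("image-based age classification separates old from new PSDs", {
  gt <- make_geometry(2, 5, age_distribution = dist_spec("uniform", min = 0, max = 6),
                      az_min_dist_um = 1.6, seed = 105)
  days_pc <- 3
  red_stk <- render_puncta_stack(gt, "glur_red", days_since_pc = days_pc,
                                 noise_sd = 2, seed = 106)
  green_stk <- render_puncta_stack(gt, "glur_green", days_since_pc = days_pc,
                                   noise_sd = 2, seed = 107)
  total <- max_project(red_stk) + max_project(green_stk)
  attr(total, "pixel_size") <- gt$pixel_size
  psd <- detect_puncta(total, pixel_size = gt$pixel_size)
  lab <- classify_age(psd, red_plane = max_project(red_stk),
                      green_plane = max_project(green_stk))
  # match detected PSDs back to ground truth by position
  s <- gt$synapses
  truth_old <- vapply(seq_len(nrow(lab)), function(i) {
    k <- which.min((s$psd_x_um - psd$puncta$x_um[i])^2 +
                   (s$psd_y_um - psd$puncta$y_um[i])^2)
    s$age_days[k] > days_pc
  }, logical(1))
  expect_equal(lab$age_class == "old", truth_old)
})
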
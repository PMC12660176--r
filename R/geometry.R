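#' Specify a bounded random distribution for simulator parameters
#'
#' Small helper used by [make_geometry()] to describe how per-synapse
#' quantities (release probability, spontaneous rate, age) are drawn.
#'
#' Supported distributions:
#' \describe{
#'   \item{`constant`}{`value`}
#'   \item{`uniform`}{`min`, `max`}
#'   \item{`beta`}{`shape1`, `shape2`, optional `scale` (multiplies the draw)}
#'   \item{`gamma`}{`shape`, `rate`}
#'   \item{`lognormal`}{`meanlog`, `sdlog`}
#'   \item{`age_linear`}{`slope`, `intercept`, `sd` — only meaningful for
#'     release probability, which is then `intercept + slope * age + noise`,
#'     clamped to `[0, 1]`.}
#' }
#'
#' @param dist distribution name (see Details).
#' @param ... named distribution parameters.
#' @return a `dist_spec` list.
#' @examples
#' dist_spec("uniform", min = 0.02, max = 0.5)
#' @export
dist_spec <- function(dist, ...) {
  dist <- match.arg(dist, c("constant", "uniform", "beta", "gamma",
                            "lognormal", "age_linear"))
  out <- c(list(dist = dist), list(...))
  class(out) <- "dist_spec"
  out
}

as_dist_spec <- function(x, name) {
  if (inherits(x, "dist_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dist_spec("constant", value = x))
  if (is.list(x) && !is.null(x$dist)) return(do.call(dist_spec, x))
  stop(sprintf("'%s' must be a dist_spec, a list with $dist, or a single number",
               name), call. = FALSE)
}

need_par <- function(spec, nm) {
  for (p in nm) {
    if (is.null(spec[[p]]) || !is.numeric(spec[[p]]) || is.na(spec[[p]])) {
      stop(sprintf("distribution '%s' needs numeric parameter '%s'",
                   spec$dist, p), call. = FALSE)
    }
  }
}

# Draw n values from a dist_spec. For "age_linear", `age` must be supplied.
draw_dist <- function(spec, n, age = NULL) {
  switch(spec$dist,
    constant = {
      need_par(spec, "value")
      rep(spec$value, n)
    },
    uniform = {
      need_par(spec, c("min", "max"))
      if (spec$max < spec$min) stop("uniform: max < min", call. = FALSE)
      runif(n, spec$min, spec$max)
    },
    beta = {
      need_par(spec, c("shape1", "shape2"))
      if (spec$shape1 <= 0 || spec$shape2 <= 0)
        stop("beta: shapes must be > 0", call. = FALSE)
      sc <- if (is.null(spec$scale)) 1 else spec$scale
      sc * rbeta(n, spec$shape1, spec$shape2)
    },
    gamma = {
      need_par(spec, c("shape", "rate"))
      if (spec$shape <= 0 || spec$rate <= 0)
        stop("gamma: shape and rate must be > 0", call. = FALSE)
      rgamma(n, shape = spec$shape, rate = spec$rate)
    },
    lognormal = {
      need_par(spec, c("meanlog", "sdlog"))
      rlnorm(n, spec$meanlog, spec$sdlog)
    },
    age_linear = {
      need_par(spec, c("slope", "intercept", "sd"))
      if (is.null(age)) stop("age_linear requires ages", call. = FALSE)
      pmin(pmax(spec$intercept + spec$slope * age + rnorm(n, 0, spec$sd), 0), 1)
    }
  )
}

#' Generate ground-truth NMJ geometry with known release parameters
#'
#' Builds a synthetic neuromuscular junction: a chain of boutons (laid out on
#' a compact serpentine so the imaged field stays small), each containing
#' active zones (AZs) with a matched postsynaptic density (PSD) opposite each
#' one. Every synapse carries a true evoked release probability, spontaneous
#' release rate (events/min), age (days), Ca-channel (Cac) status and bouton
#' membership. A fraction of AZs can be made Cac-negative: these sites have
#' zero evoked release probability but retain spontaneous fusion, emulating
#' immature spontaneous-only release sites.
#'
#' @param n_boutons number of boutons (>= 1). The terminal bouton has
#'   `bouton_index = 0`, the second-from-end `1`, and so on.
#' @param az_per_bouton number of AZs per bouton (>= 1).
#' @param pr_distribution distribution of evoked release probability; see
#'   [dist_spec()]. Default `uniform(0.02, 0.5)`, spanning the large Pr
#'   heterogeneity seen across NMJ release sites. Use
#'   `dist_spec("age_linear", ...)` to couple Pr to synapse age
#'   (a maturation model).
#' @param spont_distribution distribution of spontaneous rate (events/min).
#' @param cac_negative_fraction fraction of AZs lacking Cac (true Pr forced
#'   to 0, spontaneous rate floored at `cac_negative_min_spont`).
#' @param age_distribution distribution of synapse age in days. Default
#'   uniform over 0–6 d, the span of larval development.
#' @param growth_mode how ages map onto boutons: `"random"` (no spatial
#'   structure), `"budding"` (terminal bouton youngest: branches bud from the
#'   axon end) or `"stretching"` (new boutons inserted internally, so the
#'   terminal bouton keeps the oldest synapses).
#' @param orphan_psd_fraction fraction (of the AZ count) of extra PSDs with
#'   no opposed AZ.
#' @param psd_jitter_um s.d. (µm) of the AZ–PSD offset.
#' @param az_min_dist_um minimum centre-to-centre AZ spacing (µm).
#' @param bouton_radius_um bouton radius; default scales with
#'   `sqrt(az_per_bouton)` so sites fit at the requested spacing.
#' @param cac_negative_min_spont floor (events/min) on the spontaneous rate
#'   of Cac-negative sites, which by construction still release.
#' @param pixel_size µm per pixel (default 0.133, a typical 60x/EMCCD scale).
#' @param margin_um empty margin around the boutons (µm).
#' @param seed integer RNG seed; the full geometry is reproducible for a
#'   fixed seed.
#' @return An object of class `nmj_ground_truth`: a list with `synapses`
#'   (data.frame: `az_id`, `x_um`, `y_um`, `psd_x_um`, `psd_y_um`, `true_pr`,
#'   `spont_per_min`, `age_days`, `cac_positive`, `bouton_index`),
#'   `orphan_psds`, `pixel_size`, `field_dim` (rows, cols), `bouton_centers`,
#'   `bouton_radius_um`, `nmj_area_um2` and `seed`.
#' @examples
#' gt <- make_geometry(2, 5, pr_distribution = 0.2, spont_distribution = 0.5,
#'                     cac_negative_fraction = 0, seed = 1)
#' gt$synapses$true_pr
#' @export
make_geometry <- function(n_boutons, az_per_bouton,
                          pr_distribution = dist_spec("uniform", min = 0.02, max = 0.5),
                          spont_distribution = dist_spec("gamma", shape = 2, rate = 2),
                          cac_negative_fraction = 0,
                          age_distribution = dist_spec("uniform", min = 0, max = 6),
                          growth_mode = c("random", "budding", "stretching"),
                          orphan_psd_fraction = 0,
                          psd_jitter_um = 0.08,
                          az_min_dist_um = 1.0,
                          bouton_radius_um = NULL,
                          cac_negative_min_spont = 0.3,
                          pixel_size = 0.133,
                          margin_um = 2.5,
                          seed = 1) {
  stopifnot_scalar(n_boutons, "n_boutons", 1)
  stopifnot_scalar(az_per_bouton, "az_per_bouton", 1)
  stopifnot_scalar(cac_negative_fraction, "cac_negative_fraction", 0, 1)
  stopifnot_scalar(orphan_psd_fraction, "orphan_psd_fraction", 0, 1)
  stopifnot_scalar(pixel_size, "pixel_size", 1e-6)
  growth_mode <- match.arg(growth_mode)
  pr_distribution <- as_dist_spec(pr_distribution, "pr_distribution")
  spont_distribution <- as_dist_spec(spont_distribution, "spont_distribution")
  age_distribution <- as_dist_spec(age_distribution, "age_distribution")

  n_boutons <- as.integer(n_boutons)
  az_per_bouton <- as.integer(az_per_bouton)
  n_az <- n_boutons * az_per_bouton
  r_b <- if (is.null(bouton_radius_um)) {
    max(1.5, 0.72 * az_min_dist_um * sqrt(az_per_bouton) + 0.5)
  } else bouton_radius_um

  with_seed(seed, {
    # bouton centres on a serpentine grid (keeps the field compact)
    ncol_g <- ceiling(sqrt(n_boutons))
    spacing <- 2 * r_b + 0.8
    centers <- t(vapply(seq_len(n_boutons) - 1L, function(i) {
      row <- i %/% ncol_g
      col <- i %% ncol_g
      if (row %% 2 == 1) col <- ncol_g - 1 - col   # serpentine
      c(x = margin_um + r_b + col * spacing,
        y = margin_um + r_b + row * spacing)
    }, numeric(2)))

    # AZ positions: rejection sampling inside each bouton with min spacing
    place_azs <- function(cx, cy, n, rad, min_d) {
      pts <- matrix(NA_real_, n, 2)
      got <- 0L
      d <- min_d
      tries <- 0L
      while (got < n) {
        u <- sqrt(runif(1)) * (rad - 0.25)
        th <- runif(1, 0, 2 * pi)
        p <- c(cx + u * cos(th), cy + u * sin(th))
        ok <- got == 0L ||
          all((pts[seq_len(got), 1] - p[1])^2 + (pts[seq_len(got), 2] - p[2])^2 >= d^2)
        if (ok) {
          got <- got + 1L
          pts[got, ] <- p
        }
        tries <- tries + 1L
        if (tries %% 400L == 0L) d <- d * 0.95  # guarantee termination
      }
      pts
    }
    az <- do.call(rbind, lapply(seq_len(n_boutons), function(b) {
      cbind(place_azs(centers[b, 1], centers[b, 2], az_per_bouton, r_b,
                      az_min_dist_um),
            bouton = b)
    }))
    bouton_of <- as.integer(az[, 3])
    bouton_index <- n_boutons - bouton_of  # terminal bouton = 0

    age <- draw_dist(age_distribution, n_az)
    if (any(age < 0)) stop("age distribution produced negative ages")
    if (growth_mode != "random" && n_boutons > 1) {
      # Reassign drawn ages across boutons to emulate the growth pattern;
      # boutons earlier in `ord` receive the youngest age block.
      sorted_age <- sort(age)  # ascending: youngest first
      ubi <- sort(unique(bouton_index))
      ord <- switch(growth_mode,
        # budding: branches bud from the axon end -> terminal bouton youngest
        budding = ubi[order(ubi)],
        # stretching: new boutons inserted internally -> interior youngest,
        # terminal and proximal origin keep the oldest synapses
        stretching = ubi[order(-pmin(ubi, max(ubi) - ubi))]
      )
      new_age <- numeric(n_az)
      pos <- 1L
      for (bi in ord) {
        idx <- which(bouton_index == bi)
        blk <- sorted_age[pos:(pos + length(idx) - 1L)]
        new_age[idx] <- blk[sample.int(length(blk))]
        pos <- pos + length(idx)
      }
      age <- new_age
    }

    pr <- draw_dist(pr_distribution, n_az, age = age)
    if (any(pr < 0 | pr > 1)) {
      stop("pr distribution produced values outside [0, 1]")
    }
    spont <- draw_dist(spont_distribution, n_az)
    if (any(spont < 0)) stop("spontaneous-rate distribution produced negative rates")

    n_neg <- round(cac_negative_fraction * n_az)
    cac_positive <- rep(TRUE, n_az)
    if (n_neg > 0) {
      neg <- sample.int(n_az, n_neg)
      cac_positive[neg] <- FALSE
      pr[neg] <- 0                                   # no evoked release without Cac
      spont[neg] <- pmax(spont[neg], cac_negative_min_spont)
    }

    psd <- az[, 1:2] + matrix(rnorm(2 * n_az, 0, psd_jitter_um), n_az, 2)

    n_orphan <- round(orphan_psd_fraction * n_az)
    orphan <- matrix(numeric(0), 0, 2)
    if (n_orphan > 0) {
      got <- 0L
      pts <- matrix(NA_real_, n_orphan, 2)
      while (got < n_orphan) {
        b <- sample.int(n_boutons, 1)
        u <- sqrt(runif(1)) * (r_b - 0.25)
        th <- runif(1, 0, 2 * pi)
        p <- c(centers[b, 1] + u * cos(th), centers[b, 2] + u * sin(th))
        if (all((az[, 1] - p[1])^2 + (az[, 2] - p[2])^2 >= 0.5^2)) {
          got <- got + 1L
          pts[got, ] <- p
        }
      }
      orphan <- pts
    }

    # field extent and pixel grid
    ext_x <- max(centers[, 1]) + r_b + margin_um
    ext_y <- max(centers[, 2]) + r_b + margin_um
    field_dim <- c(ceiling(ext_y / pixel_size), ceiling(ext_x / pixel_size))

    # NMJ (HRP-like) area: rasterised union of bouton discs
    gx <- px_to_um(seq_len(field_dim[2]), pixel_size)
    gy <- px_to_um(seq_len(field_dim[1]), pixel_size)
    inside <- matrix(FALSE, field_dim[1], field_dim[2])
    for (b in seq_len(n_boutons)) {
      inside <- inside | outer(gy, gx, function(y, x)
        (x - centers[b, 1])^2 + (y - centers[b, 2])^2 <= r_b^2)
    }
    nmj_area <- sum(inside) * pixel_size^2

    syn <- data.frame(
      az_id = seq_len(n_az),
      x_um = az[, 1], y_um = az[, 2],
      psd_x_um = psd[, 1], psd_y_um = psd[, 2],
      true_pr = pr, spont_per_min = spont, age_days = age,
      cac_positive = cac_positive, bouton_index = bouton_index
    )
    orphan_df <- if (nrow(orphan)) {
      data.frame(psd_id = n_az + seq_len(nrow(orphan)),
                 psd_x_um = orphan[, 1], psd_y_um = orphan[, 2])
    } else {
      data.frame(psd_id = integer(0), psd_x_um = numeric(0),
                 psd_y_um = numeric(0))
    }

    gt <- structure(list(
      synapses = syn, orphan_psds = orphan_df,
      pixel_size = pixel_size, field_dim = as.integer(field_dim),
      bouton_centers = centers, bouton_radius_um = r_b,
      nmj_area_um2 = nmj_area, seed = as.integer(seed)
    ), class = "nmj_ground_truth")
    validate_ground_truth(gt)
    gt
  })
}

validate_ground_truth <- function(gt) {
  s <- gt$synapses
  stopifnot(
    all(s$true_pr >= 0 & s$true_pr <= 1),
    all(s$spont_per_min >= 0),
    all(s$age_days >= 0),
    all(s$true_pr[!s$cac_positive] == 0),
    all(s$x_um > 0 & s$x_um < gt$field_dim[2] * gt$pixel_size),
    all(s$y_um > 0 & s$y_um < gt$field_dim[1] * gt$pixel_size),
    !anyDuplicated(s$az_id)
  )
  invisible(gt)
}

#' @export
print.nmj_ground_truth <- function(x, ...) {
  s <- x$synapses
  cat(sprintf(
    "<nmj_ground_truth> %d AZs in %d boutons | field %dx%d px (%.3f um/px)\n",
    nrow(s), length(unique(s$bouton_index)), x$field_dim[1], x$field_dim[2],
    x$pixel_size))
  cat(sprintf("  Pr: %.3f-%.3f | spont: %.2f-%.2f /min | %d Cac- | NMJ area %.1f um^2\n",
              min(s$true_pr), max(s$true_pr), min(s$spont_per_min),
              max(s$spont_per_min), sum(!s$cac_positive), x$nmj_area_um2))
  invisible(x)
}

#' @export
as.data.frame.nmj_ground_truth <- function(x, ...) x$synapses
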
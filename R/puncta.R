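#' Maximum-intensity projection of a Z-stack
#'
#' Merges a multi-plane stack into a single plane for 2D analysis; each
#' output pixel is the maximum over planes.
#'
#' @param stack numeric array `[row, col, plane]` or a single matrix.
#' @return matrix with the stack's `pixel_size` attribute preserved.
#' @examples
#' max_project(array(1:8, c(2, 2, 2)))
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3 || dim(stack)[3] < 1) {
    stop("'stack' must be a matrix or a [row, col, plane] array with >= 1 plane")
  }
  out <- Reduce(pmax, lapply(seq_len(dim(stack)[3]), function(k) stack[, , k]))
  attr(out, "pixel_size") <- attr(stack, "pixel_size")
  out
}

# Background level and spread from the median and scaled MAD of the whole
# plane: robust to the bright puncta (a small pixel fraction), and a
# reproducible analogue of an operator-set threshold.
estimate_background <- function(plane) {
  list(mean = median(plane), sd = mad(plane))
}

#' Detect fluorescent puncta on a projected image plane
#'
#' Thresholds the plane, labels 8-connected supra-threshold components,
#' filters them by minimum area and measures each object: intensity-weighted
#' centroid (µm), area (µm²), raw and background-subtracted sum intensity and
#' mean intensity. The default threshold is `background + 3 s.d.`, with the
#' background level and spread estimated robustly as the median and scaled
#' MAD of the plane (puncta occupy a small fraction of pixels).
#'
#' @param plane image matrix (e.g. from [max_project()]).
#' @param threshold intensity threshold; `NULL` for the automatic default.
#' @param min_area_px minimum object area in pixels (default 4).
#' @param pixel_size µm per pixel; taken from the plane's attribute if absent.
#' @param nmj_id,channel labels stored in the result.
#' @param nmj_area_um2 NMJ (e.g. HRP mask) area for density statistics.
#' @param keep_labels keep the label matrix (needed to re-measure other
#'   channels over the same masks).
#' @return object of class `puncta_set`: list with `puncta` (data.frame:
#'   `id`, `x_um`, `y_um`, `area_um2`, `area_px`, `sum_intensity`,
#'   `sum_bgsub`, `mean_intensity`), `threshold_used`, `background_mean`,
#'   `background_sd`, `nmj_id`, `channel`, `pixel_size`, `nmj_area_um2`,
#'   `field_dim` and (optionally) `labels`.
#' @examples
#' gt <- make_geometry(1, 4, seed = 1)
#' pl <- max_project(render_puncta_stack(gt, "az", seed = 1))
#' detect_puncta(pl)
#' @export
detect_puncta <- function(plane, threshold = NULL, min_area_px = 4,
                          pixel_size = NULL, nmj_id = "nmj", channel = "ch",
                          nmj_area_um2 = NA_real_, keep_labels = TRUE) {
  stopifnot(is.matrix(plane))
  if (is.null(pixel_size)) pixel_size <- attr(plane, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size not given and not an attribute of 'plane'")
  stopifnot_scalar(min_area_px, "min_area_px", 1)
  bg <- estimate_background(plane)
  if (is.null(threshold)) {
    if (is.na(bg$sd) || bg$sd == 0) bg$sd <- 0
    threshold <- bg$mean + 3 * bg$sd
  }
  mask <- plane > threshold
  if (all(mask) || all(!mask)) {
    if (all(mask)) {
      warning("image entirely above threshold: saturated or constant input")
    }
  }
  lab <- cpp_label8(mask)
  n_obj <- max(lab)
  puncta <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                       area_um2 = numeric(0), area_px = integer(0),
                       sum_intensity = numeric(0), sum_bgsub = numeric(0),
                       mean_intensity = numeric(0))
  if (n_obj > 0) {
    idx <- which(lab > 0)
    l <- lab[idx]
    inten <- plane[idx]
    rowi <- (idx - 1L) %% nrow(plane) + 1L
    coli <- (idx - 1L) %/% nrow(plane) + 1L
    area <- tabulate(l, n_obj)
    sumi <- as.numeric(rowsum(inten, l))
    wx <- as.numeric(rowsum(inten * px_to_um(coli, pixel_size), l)) / sumi
    wy <- as.numeric(rowsum(inten * px_to_um(rowi, pixel_size), l)) / sumi
    keep <- area >= min_area_px
    ids <- seq_len(sum(keep))
    puncta <- data.frame(
      id = ids,
      x_um = wx[keep], y_um = wy[keep],
      area_um2 = area[keep] * pixel_size^2,
      area_px = area[keep],
      sum_intensity = sumi[keep],
      sum_bgsub = sumi[keep] - area[keep] * bg$mean,
      mean_intensity = sumi[keep] / area[keep]
    )
    if (keep_labels) {
      # relabel kept objects 1..n, zero out the rest
      map <- integer(n_obj)
      map[which(keep)] <- ids
      lab[idx] <- map[l]
    }
  }
  structure(list(puncta = puncta, threshold_used = threshold,
                 background_mean = bg$mean, background_sd = bg$sd,
                 nmj_id = nmj_id, channel = channel, pixel_size = pixel_size,
                 nmj_area_um2 = nmj_area_um2,
                 field_dim = dim(plane),
                 labels = if (keep_labels) lab else NULL),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %s/%s: %d puncta (threshold %.2f)\n",
              x$nmj_id, x$channel, nrow(x$puncta), x$threshold_used))
  invisible(x)
}

#' Build a puncta set from a plain table of centroids
#'
#' Convenience for using ground-truth or externally supplied positions with
#' the pairing, colocalization and ROI tools.
#'
#' @param df data.frame with `x_um` and `y_um` (optionally `id`).
#' @param pixel_size µm per pixel.
#' @param nmj_id,channel,nmj_area_um2 metadata labels.
#' @return a `puncta_set`.
#' @export
as_puncta_set <- function(df, pixel_size = 0.133, nmj_id = "nmj",
                          channel = "ch", nmj_area_um2 = NA_real_) {
  stopifnot(is.data.frame(df), all(c("x_um", "y_um") %in% names(df)))
  n <- nrow(df)
  col_or <- function(v, default) if (is.null(v)) rep(default, n) else v
  p <- data.frame(id = col_or(df$id, NA)[seq_len(n)],
                  x_um = df$x_um, y_um = df$y_um,
                  area_um2 = col_or(df$area_um2, NA_real_),
                  area_px = rep(NA_integer_, n),
                  sum_intensity = col_or(df$sum_intensity, NA_real_),
                  sum_bgsub = rep(NA_real_, n),
                  mean_intensity = rep(NA_real_, n))
  if (all(is.na(p$id))) p$id <- seq_len(n)
  structure(list(puncta = p, threshold_used = NA_real_,
                 background_mean = NA_real_, background_sd = NA_real_,
                 nmj_id = nmj_id, channel = channel, pixel_size = pixel_size,
                 nmj_area_um2 = nmj_area_um2, field_dim = NULL, labels = NULL),
            class = "puncta_set")
}

#' Re-measure another channel over detected puncta masks
#'
#' Sums a second channel's intensities over the exact pixel masks of a
#' detected puncta set (e.g. red and green GluR channels over the same PSD
#' objects).
#'
#' @param set a `puncta_set` detected with `keep_labels = TRUE`.
#' @param plane image matrix of the other channel (same field).
#' @param background_subtract subtract this plane's lowest-quartile
#'   background mean (per pixel) from the sums.
#' @return data.frame `id`, `sum`, `mean`, `area_px`.
#' @export
measure_channel <- function(set, plane, background_subtract = TRUE) {
  stopifnot(inherits(set, "puncta_set"))
  if (is.null(set$labels)) stop("puncta_set has no label matrix; re-run detect_puncta(keep_labels = TRUE)")
  stopifnot(all(dim(plane) == dim(set$labels)))
  n <- nrow(set$puncta)
  out <- data.frame(id = set$puncta$id, sum = 0, mean = 0,
                    area_px = set$puncta$area_px)
  if (n == 0) return(out)
  idx <- which(set$labels > 0)
  l <- set$labels[idx]
  sums <- numeric(n)
  agg <- rowsum(plane[idx], l)
  sums[as.integer(rownames(agg))] <- as.numeric(agg)
  if (background_subtract) {
    bg <- estimate_background(plane)$mean
    sums <- sums - bg * set$puncta$area_px
  }
  out$sum <- sums
  out$mean <- sums / set$puncta$area_px
  out
}

#' Fraction of puncta lacking a partner within a distance
#'
#' For each punctum in A, checks whether any B centroid lies within
#' `max_dist` µm, and vice versa; reports the percentage lacking a partner in
#' both directions (the "percent lacking" statistic used for pairwise AZ
#' protein colocalization).
#'
#' @param set_a,set_b `puncta_set` objects from the same registered field.
#' @param max_dist distance threshold (µm).
#' @return list of class `coloc_fraction`: `pct_a_lacking_b`,
#'   `pct_b_lacking_a`, counts, and per-punctum logical vectors
#'   `a_has_b`, `b_has_a`. An empty set yields `NA` (reported missing, not 0).
#' @export
colocalize_fraction <- function(set_a, set_b, max_dist = 0.8) {
  stopifnot(inherits(set_a, "puncta_set"), inherits(set_b, "puncta_set"))
  stopifnot_scalar(max_dist, "max_dist", 0)
  a <- set_a$puncta; b <- set_b$puncta
  near <- function(p, q) {
    if (nrow(p) == 0) return(logical(0))
    if (nrow(q) == 0) return(rep(FALSE, nrow(p)))
    d2 <- outer(p$x_um, q$x_um, "-")^2 + outer(p$y_um, q$y_um, "-")^2
    apply(d2 <= max_dist^2, 1, any)
  }
  a_has_b <- near(a, b)
  b_has_a <- near(b, a)
  pct <- function(has) if (length(has) == 0) NA_real_ else 100 * mean(!has)
  structure(list(pct_a_lacking_b = pct(a_has_b), pct_b_lacking_a = pct(b_has_a),
                 n_a = nrow(a), n_b = nrow(b),
                 a_has_b = a_has_b, b_has_a = b_has_a,
                 max_dist = max_dist),
            class = "coloc_fraction")
}

#' Pair AZ and PSD puncta by greedy mutual-nearest matching
#'
#' Repeatedly pairs the globally closest AZ–PSD pair within `max_dist` µm and
#' removes both, until no pair remains. Ties are broken by smallest AZ id,
#' then smallest PSD id, so the pairing is deterministic. Unpaired puncta are
#' retained with `NA` partners.
#'
#' @param az,psd `puncta_set` objects from the same registered field.
#' @param max_dist maximum pairing distance (µm, default 0.8).
#' @return data.frame of class `opposition_pairs`: `az_id`, `psd_id`,
#'   `dist_um`; rows with `NA` in one column are unpaired entries. Attributes
#'   `n_paired`, `n_az`, `n_psd`.
#' @export
opposition_pairs <- function(az, psd, max_dist = 0.8) {
  stopifnot(inherits(az, "puncta_set"), inherits(psd, "puncta_set"))
  a <- az$puncta; b <- psd$puncta
  if (nrow(a) == 0 || nrow(b) == 0) {
    out <- data.frame(az_id = c(a$id, rep(NA_integer_, nrow(b))),
                      psd_id = c(rep(NA_integer_, nrow(a)), b$id),
                      dist_um = NA_real_)
  } else {
    d <- sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2)
    d[d > max_dist] <- Inf
    pa <- rep(NA_integer_, nrow(a))  # psd row paired to each az row
    free_a <- rep(TRUE, nrow(a)); free_b <- rep(TRUE, nrow(b))
    repeat {
      dd <- d[free_a, free_b, drop = FALSE]
      if (!length(dd) || all(!is.finite(dd))) break
      m <- min(dd)
      # global minimum; ties -> smallest az id then psd id (ids are sorted
      # within each set, so the first index in row-major order wins)
      ia_c <- which(free_a); ib_c <- which(free_b)
      hit <- which(dd == m, arr.ind = TRUE)
      hit <- hit[order(ia_c[hit[, 1]], ib_c[hit[, 2]]), , drop = FALSE]
      ia <- ia_c[hit[1, 1]]; ib <- ib_c[hit[1, 2]]
      pa[ia] <- ib
      free_a[ia] <- FALSE; free_b[ib] <- FALSE
    }
    paired <- !is.na(pa)
    out <- rbind(
      data.frame(az_id = a$id, psd_id = ifelse(paired, b$id[pa], NA_integer_),
                 dist_um = ifelse(paired,
                                  sqrt((a$x_um - b$x_um[ifelse(paired, pa, 1)])^2 +
                                       (a$y_um - b$y_um[ifelse(paired, pa, 1)])^2),
                                  NA_real_)),
      data.frame(az_id = rep(NA_integer_, sum(free_b)),
                 psd_id = b$id[free_b],
                 dist_um = rep(NA_real_, sum(free_b)))
    )
  }
  rownames(out) <- NULL
  structure(out, class = c("opposition_pairs", "data.frame"),
            n_paired = sum(!is.na(out$az_id) & !is.na(out$psd_id)),
            n_az = nrow(a), n_psd = nrow(b))
}

#' Puncta density per 10 µm² of NMJ area
#'
#' @param set a `puncta_set` with `nmj_area_um2` set.
#' @return count per 10 µm².
#' @examples
#' puncta_density(as_puncta_set(data.frame(x_um = 1:7, y_um = 1:7),
#'                              nmj_area_um2 = 35))  # 2 per 10 um^2
#' @export
puncta_density <- function(set) {
  stopifnot(inherits(set, "puncta_set"))
  area <- set$nmj_area_um2
  if (is.na(area) || area <= 0) stop("nmj_area_um2 must be set and > 0")
  10 * nrow(set$puncta) / area
}
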
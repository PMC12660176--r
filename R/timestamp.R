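#' Classify PSD age from photoconverted two-channel GluR signal
#'
#' A PSD is "old" (it existed at photoconversion) if its red
#' (photoconverted) sum intensity exceeds `red_threshold`; any other PSD is
#' "new". Red sums are additionally normalised per NMJ, with the brightest
#' PSD of each NMJ set to 1.0, so ages pool across animals on a common
#' scale.
#'
#' Input can be either a data.frame with `psd_id`, `red_sum` (and optionally
#' `green_sum`), or a `puncta_set` detected on the total-GluR (green)
#' channel plus `red_plane`/`green_plane` images measured over the identical
#' PSD masks.
#'
#' @param psd either a data.frame of per-PSD sums or a `puncta_set` with
#'   label masks.
#' @param red_plane,green_plane channel images (required in the
#'   `puncta_set` form).
#' @param red_threshold intensity threshold on the red sum; default 0 for
#'   tabular input ("any amount" of old receptor). In the image form the
#'   default is `(background mean + 3 s.d.) * mask area`, i.e. a mean-
#'   intensity positivity criterion.
#' @return data.frame of class `age_labels`: `psd_id`, `red_sum`,
#'   `green_sum`, `norm_red` (in `[0, 1]`), `age_class` (`"old"`/`"new"`).
#' @examples
#' classify_age(data.frame(psd_id = 1:3, red_sum = c(0, 5, 10)))
#' @export
classify_age <- function(psd, red_plane = NULL, green_plane = NULL,
                         red_threshold = NULL) {
  if (inherits(psd, "puncta_set")) {
    if (is.null(red_plane)) stop("red_plane required with a puncta_set input")
    red <- measure_channel(psd, red_plane, background_subtract = TRUE)
    green <- if (is.null(green_plane)) {
      data.frame(sum = rep(NA_real_, nrow(red)))
    } else {
      measure_channel(psd, green_plane, background_subtract = TRUE)
    }
    if (is.null(red_threshold)) {
      bg <- estimate_background(red_plane)
      # positivity: mean red intensity above background mean + 3 s.d.
      red_threshold <- 3 * bg$sd * psd$puncta$area_px
    }
    tab <- data.frame(psd_id = psd$puncta$id, red_sum = red$sum,
                      green_sum = green$sum)
  } else {
    stopifnot(is.data.frame(psd), all(c("psd_id", "red_sum") %in% names(psd)))
    tab <- data.frame(psd_id = psd$psd_id, red_sum = psd$red_sum,
                      green_sum = if (is.null(psd$green_sum))
                        rep(NA_real_, nrow(psd)) else psd$green_sum)
    if (is.null(red_threshold)) red_threshold <- 0
  }
  if (nrow(tab) == 0) {
    out <- cbind(tab, norm_red = numeric(0), age_class = character(0))
    return(structure(out, class = c("age_labels", "data.frame")))
  }
  mx <- max(tab$red_sum)
  tab$norm_red <- if (mx > 0) tab$red_sum / mx else rep(1, nrow(tab))
  tab$age_class <- ifelse(tab$red_sum > red_threshold, "old", "new")
  structure(tab, class = c("age_labels", "data.frame"),
            red_threshold = red_threshold)
}

#' Correlate PSD age with release output
#'
#' Joins age labels to a release map through an AZ–PSD opposition pairing
#' and computes the Pearson correlation between normalised old-receptor
#' signal and evoked Pr (and spontaneous rate), plus old-vs-new group means
#' and fold changes.
#'
#' @param labels an [classify_age()] result.
#' @param rmap a [release_map()] whose `roi_id`s are AZ ids.
#' @param pairing an [opposition_pairs()] table linking `az_id` to `psd_id`.
#'   If `NULL`, `psd_id` is matched to `roi_id` directly.
#' @return list of class `age_output_cor`: `n`, `r_pr`, `r_spont`,
#'   `mean_pr_old`, `mean_pr_new`, `pr_fold`, `mean_spont_old`,
#'   `mean_spont_new`, `spont_fold`, and the joined `data` table.
#' @export
age_output_correlation <- function(labels, rmap, pairing = NULL) {
  stopifnot(inherits(labels, "age_labels"), inherits(rmap, "release_map"))
  if (is.null(pairing)) {
    joined <- merge(labels, rmap, by.x = "psd_id", by.y = "roi_id")
  } else {
    pp <- pairing[!is.na(pairing$az_id) & !is.na(pairing$psd_id),
                  c("az_id", "psd_id")]
    joined <- merge(merge(labels, pp, by = "psd_id"), rmap,
                    by.x = "az_id", by.y = "roi_id")
  }
  if (nrow(joined) < 3) {
    stop("fewer than 3 paired PSD/ROI observations; correlation undefined")
  }
  grp <- function(v, cls) mean(v[joined$age_class == cls])
  r_pr <- pearson_r(joined$norm_red, joined$pr)
  r_spont <- if (sd(joined$spont_per_min) > 0) {
    pearson_r(joined$norm_red, joined$spont_per_min)
  } else NA_real_
  res <- list(
    n = nrow(joined), r_pr = r_pr, r_spont = r_spont,
    mean_pr_old = grp(joined$pr, "old"), mean_pr_new = grp(joined$pr, "new"),
    mean_spont_old = grp(joined$spont_per_min, "old"),
    mean_spont_new = grp(joined$spont_per_min, "new"),
    data = joined
  )
  res$pr_fold <- res$mean_pr_old / res$mean_pr_new
  res$spont_fold <- res$mean_spont_old / res$mean_spont_new
  class(res) <- "age_output_cor"
  res
}

#' @export
print.age_output_cor <- function(x, ...) {
  cat(sprintf("<age_output_cor> n = %d | r(age, Pr) = %.3f | Pr old/new = %.3f/%.3f (%.2f-fold)\n",
              x$n, x$r_pr, x$mean_pr_old, x$mean_pr_new, x$pr_fold))
  invisible(x)
}

#' Fraction of old PSDs per bouton position
#'
#' Percentage of old PSDs among all PSDs for every bouton, highlighting the
#' terminal bouton (index 0) and the second bouton from the end (index 1) —
#' the comparison used to distinguish NMJ growth by terminal budding from
#' growth by internal bouton insertion.
#'
#' @param labels an [classify_age()] result.
#' @param bouton_index integer bouton membership per PSD (terminal = 0).
#' @return list of class `bouton_fractions`: `per_bouton` (data.frame
#'   `bouton_index`, `n_psd`, `n_old`, `pct_old`), `terminal_pct`,
#'   `second_pct`.
#' @export
bouton_position_fraction <- function(labels, bouton_index) {
  stopifnot(inherits(labels, "age_labels"),
            length(bouton_index) == nrow(labels))
  if (nrow(labels) == 0) stop("no PSDs")
  tab <- data.frame(bouton_index = bouton_index,
                    old = labels$age_class == "old")
  agg <- do.call(rbind, lapply(split(tab, tab$bouton_index), function(g) {
    data.frame(bouton_index = g$bouton_index[1], n_psd = nrow(g),
               n_old = sum(g$old), pct_old = 100 * mean(g$old))
  }))
  agg <- agg[order(agg$bouton_index), , drop = FALSE]
  rownames(agg) <- NULL
  empty <- setdiff(seq(0, max(bouton_index)), agg$bouton_index)
  if (length(empty)) {
    warning("bouton(s) without PSDs excluded: ", paste(empty, collapse = ", "))
  }
  pct_at <- function(i) {
    v <- agg$pct_old[agg$bouton_index == i]
    if (length(v)) v else NA_real_
  }
  structure(list(per_bouton = agg, terminal_pct = pct_at(0),
                 second_pct = pct_at(1)),
            class = "bouton_fractions")
}

#' Stability of the old-PSD count between two sessions
#'
#' Ratio (percent) of old-PSD counts at a later timepoint to an earlier one;
#' 100 means the old pool is conserved (no lateral movement of
#' photoconverted receptor into new PSDs and no loss).
#'
#' @param labels_t1,labels_t2 [classify_age()] results for the two sessions.
#' @return percent, `100 * n_old(t2) / n_old(t1)`.
#' @examples
#' l1 <- classify_age(data.frame(psd_id = 1:3, red_sum = c(5, 5, 0)))
#' l2 <- classify_age(data.frame(psd_id = 1:4, red_sum = c(5, 5, 0, 0)))
#' count_old_psd_stability(l1, l2)  # 100
#' @export
count_old_psd_stability <- function(labels_t1, labels_t2) {
  stopifnot(inherits(labels_t1, "age_labels"), inherits(labels_t2, "age_labels"))
  n1 <- sum(labels_t1$age_class == "old")
  n2 <- sum(labels_t2$age_class == "old")
  if (n1 == 0) stop("no old PSDs at t1; ratio undefined")
  100 * n2 / n1
}
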
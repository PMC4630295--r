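#' Contrast t-map of a block-design volume series
#'
#' Per voxel, a two-sample pooled-variance t statistic between the
#' delay-shifted samples of two conditions. The hemodynamic delay (default:
#' the design's) is applied as a backward label shift of
#' `round(delay / sample_interval)` samples, discarding the unlabeled
#' leading volumes. Degenerate voxels (zero pooled variance) get `NaN`.
#'
#' Note the distinction from [realized_fsnr()]: single-voxel simulations
#' report the realized-fSNR statistic, while volume analyses report this
#' pooled t.
#'
#' @param x 4D array (z-scored magnitude, raw, or suppressed), or a
#'   [complex_volume_series()] (its magnitude is used), or a
#'   `suppressed_volume` (its suppressed series is used).
#' @param design A [block_design()] matching the 4th dimension.
#' @param cond_a,cond_b Condition labels contrasted as `a - b`.
#' @param delay Hemodynamic delay in seconds; defaults to the design's.
#' @return 3D array of t values.
#' @export
contrast_tmap <- function(x, design, cond_a = "on", cond_b = "off",
                          delay = NULL) {
  if (inherits(x, "complex_volume_series")) x <- x$magnitude
  if (inherits(x, "suppressed_volume")) x <- x$suppressed
  d <- dim(x)
  parts <- design_partition(design, n_timepoints = d[4],
                            delay = delay %||% design$hemodynamic_delay)
  if (!all(c(cond_a, cond_b) %in% names(parts))) {
    stop_config("conditions not present in design: ",
                paste(setdiff(c(cond_a, cond_b), names(parts)), collapse = ", "))
  }
  ia <- parts[[cond_a]]
  ib <- parts[[cond_b]]
  m <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
  na <- length(ia)
  nb <- length(ib)
  ma <- rowMeans(m[, ia, drop = FALSE])
  mb <- rowMeans(m[, ib, drop = FALSE])
  va <- rowSums((m[, ia, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((m[, ib, drop = FALSE] - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tval <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  tval[sp2 == 0] <- NaN
  array(tval, d[1:3])
}

# 6-connectivity (face-adjacency) connected components of a 3D logical array
label_components <- function(x) {
  d <- dim(x)
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(x)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      k <- (v - 1L) %/% (d[1] * d[2]) + 1L
      rem <- (v - 1L) %% (d[1] * d[2])
      j <- rem %/% d[1] + 1L
      i <- rem %% d[1] + 1L
      nb <- face_neighbors(c(i, j, k), d)
      if (nrow(nb)) {
        lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
        lin <- lin[x[lin] & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- cur
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

#' Threshold-and-cluster ROI definition per hemisphere
#'
#' Thresholds the t-map (`t > threshold`) within an optional mask, labels
#' connected components with 6-connectivity (face adjacency), and returns
#' the largest cluster in each hemisphere. Hemispheres are split by an
#' x-plane: voxels with x-index `<= split_x` are "left", the rest "right".
#' Size ties are broken deterministically by higher mean t, then lower
#' linear index. An empty ROI (no suprathreshold voxel) is a valid outcome.
#'
#' @param tmap 3D t-value array.
#' @param threshold Significance threshold (default 3.0).
#' @param mask Optional 3D logical array restricting the search.
#' @param split_x Hemisphere split plane: largest "left" x-index (default
#'   half the x extent).
#' @return Named list with `left` and `right` `roi_result` objects, each a
#'   list with `voxels` (tibble of x, y, z, t), `n_voxels`, `mean_t`,
#'   `hemisphere`.
#' @export
define_roi <- function(tmap, threshold = 3.0, mask = NULL, split_x = NULL) {
  d <- dim(tmap)
  split_x <- split_x %||% floor(d[1] / 2)
  keep <- is.finite(tmap) & tmap > threshold
  if (!is.null(mask)) keep <- keep & mask
  xs <- slice.index(tmap, 1)
  out <- list()
  for (hemi in c("left", "right")) {
    hk <- keep & (if (hemi == "left") xs <= split_x else xs > split_x)
    lab <- label_components(hk)
    roi_vox <- integer(0)
    if (max(lab) > 0) {
      stats <- lapply(seq_len(max(lab)), function(l) {
        w <- which(lab == l)
        list(size = length(w), mean_t = mean(tmap[w]), min_idx = min(w), which = w)
      })
      sizes <- vapply(stats, `[[`, numeric(1), "size")
      cand <- which(sizes == max(sizes))
      if (length(cand) > 1) {
        mt <- vapply(stats[cand], `[[`, numeric(1), "mean_t")
        cand <- cand[mt == max(mt)]
        if (length(cand) > 1) {
          mi <- vapply(stats[cand], `[[`, numeric(1), "min_idx")
          cand <- cand[which.min(mi)]
        }
      }
      roi_vox <- stats[[cand[1]]]$which
    }
    ar <- arrayInd(roi_vox, d)
    out[[hemi]] <- structure(
      list(
        voxels = tibble(x = ar[, 1], y = ar[, 2], z = ar[, 3],
                        t = tmap[roi_vox]),
        n_voxels = length(roi_vox),
        mean_t = if (length(roi_vox)) mean(tmap[roi_vox]) else NA_real_,
        hemisphere = hemi,
        threshold = threshold
      ),
      class = "roi_result"
    )
  }
  out
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("<roi_result> %s hemisphere: %d voxels (t > %g), mean t %.2f\n",
              x$hemisphere, x$n_voxels, x$threshold,
              if (x$n_voxels) x$mean_t else NA))
  invisible(x)
}

#' @export
tidy.roi_result <- function(x, ...) x$voxels

#' @export
glance.roi_result <- function(x, ...) {
  tibble(hemisphere = x$hemisphere, n_voxels = x$n_voxels,
         mean_t = x$mean_t, threshold = x$threshold)
}

#' Large-vein contribution of an ROI
#'
#' Quantifies how much of an ROI reflects large-vein signal by comparing its
#' definition with and without sPR suppression: `n_norm = N_sPR / N_mag`
#' (normalized ROI size), `percent_vein = (1 - n_norm) * 100`, `metric1 =
#' N_mag - N_sPR` (voxel-count difference), and `metric2` = mean ROI t
#' without minus with suppression (each mean over its own ROI's voxels).
#' `N_sPR > N_mag` is anomalous and flagged, not clamped.
#'
#' @param roi_mag `roi_result` from the unsuppressed magnitude t-map
#'   (must be non-empty).
#' @param roi_spr `roi_result` from the sPR-suppressed t-map.
#' @return A one-row tibble: `n_mag`, `n_spr`, `n_norm`, `percent_vein`,
#'   `metric1`, `metric2`, `mean_t_mag`, `mean_t_spr`, `flag`.
#' @export
vein_contribution <- function(roi_mag, roi_spr) {
  if (roi_mag$n_voxels == 0) {
    stop_data("empty magnitude ROI: normalized size undefined",
              subclass = "phasereg_error_undefined_ratio")
  }
  n_norm <- roi_spr$n_voxels / roi_mag$n_voxels
  m2 <- if (roi_spr$n_voxels > 0) roi_mag$mean_t - roi_spr$mean_t else NA_real_
  tibble(
    n_mag = roi_mag$n_voxels, n_spr = roi_spr$n_voxels,
    n_norm = n_norm, percent_vein = (1 - n_norm) * 100,
    metric1 = roi_mag$n_voxels - roi_spr$n_voxels,
    metric2 = m2,
    mean_t_mag = roi_mag$mean_t, mean_t_spr = roi_spr$mean_t,
    flag = if (n_norm > 1) "spr_roi_larger_than_mag" else "ok"
  )
}

#' Hemisphere laterality indices of an ROI pair
#'
#' `size_lat = (N_r - N_l) / (N_r + N_l)` and
#' `fsnr_lat = (t_r - t_l) / (t_r + t_l)` with `t` the hemisphere mean ROI
#' t-value; positive values indicate right-hemisphere laterality. Zero
#' denominators yield `NA` with an `undefined` flag, not an error.
#'
#' @param right,left `roi_result` objects for the two hemispheres.
#' @return One-row tibble: `size_lat`, `fsnr_lat`, `flag`.
#' @export
laterality <- function(right, left) {
  ns <- right$n_voxels + left$n_voxels
  size_lat <- if (ns > 0) (right$n_voxels - left$n_voxels) / ns else NA_real_
  tr <- if (right$n_voxels) right$mean_t else 0
  tl <- if (left$n_voxels) left$mean_t else 0
  fsnr_lat <- if ((tr + tl) != 0 && ns > 0) (tr - tl) / (tr + tl) else NA_real_
  flag <- if (ns == 0 || (tr + tl) == 0) "undefined" else "ok"
  tibble(size_lat = size_lat, fsnr_lat = fsnr_lat, flag = flag)
}

#' Group-level association between vein contribution and ROI properties
#'
#' Generic utilities over a table of per-ROI [vein_contribution()] rows
#' (plus any covariates): Pearson correlation tests between a contribution
#' metric and an ROI property, and a paired t-test of ROI size with vs
#' without suppression. These operate on any such table; they require
#' multiple ROIs/subjects to be meaningful.
#'
#' @param df Data frame with the named columns.
#' @param metric,covariate Column names to correlate.
#' @return `roi_metric_correlation()`: tidied `cor.test` result (one-row
#'   tibble). `roi_paired_test()`: tidied paired t-test of `n_mag` vs
#'   `n_spr`.
#' @export
roi_metric_correlation <- function(df, metric = "metric1",
                                   covariate = "mean_t_mag") {
  ct <- stats::cor.test(df[[metric]], df[[covariate]])
  tibble(metric = metric, covariate = covariate,
         estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p_value = ct$p.value, n = nrow(df))
}

#' @rdname roi_metric_correlation
#' @export
roi_paired_test <- function(df) {
  tt <- stats::t.test(df$n_mag, df$n_spr, paired = TRUE)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         p_value = tt$p.value, df = unname(tt$parameter))
}

#' Plot a t-map slice
#'
#' @param tmap 3D t array.
#' @param slice Axial slice index (default middle).
#' @param threshold Reference threshold drawn on the fill scale.
#' @return A ggplot.
#' @export
plot_tmap <- function(tmap, slice = ceiling(dim(tmap)[3] / 2), threshold = 3) {
  d <- dim(tmap)
  df <- tidyr::expand_grid(y = seq_len(d[2]), x = seq_len(d[1]))
  df$t <- as.vector(tmap[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "grey95",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("t-map, slice %d (threshold %g)", slice, threshold))
}
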
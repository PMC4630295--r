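#' Z-score a time series
#'
#' Normalizes to mean 0 and standard deviation 1, using the sample standard
#' deviation (denominator n - 1). This is the normalization applied to both
#' magnitude and phase voxel timecourses before any phase-regression fit.
#'
#' @param x Numeric vector, length >= 2 with non-zero standard deviation.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
#' @examples
#' zscore(c(1, 2, 3))
zscore <- function(x) {
  if (length(x) < 2) stop_insufficient("need at least 2 samples to z-score")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop_degenerate("cannot z-score a constant series")
  (x - mean(x)) / s
}

#' Remove a polynomial trend from a time series
#'
#' Subtracts the least-squares polynomial fit of the given degree (default
#' cubic, the convention for slow scanner drift). The residual is orthogonal
#' to all polynomials up to that degree.
#'
#' @param x Numeric vector, length > degree + 1.
#' @param degree Polynomial degree (default 3).
#' @return The detrended series (residuals), same length as `x`.
#' @export
detrend_poly <- function(x, degree = 3) {
  n <- length(x)
  if (n <= degree + 1) {
    stop_insufficient(sprintf(
      "need more than %d samples to remove a degree-%d trend", degree + 1, degree
    ))
  }
  X <- cbind(1, poly(seq_len(n), degree))
  as.numeric(lm.fit(X, x)$residuals)
}

#' Realized functional SNR of a block-design time series
#'
#' The realized fSNR statistic is
#' \deqn{(\bar S_{on} - \bar S_{off}) / (sd(S_{on})/2 + sd(S_{off})/2),}
#' i.e. the condition mean difference divided by the average of the two
#' within-condition sample standard deviations. The design's hemodynamic
#' delay is applied as a label shift before partitioning. This is also the
#' "t" statistic reported for single-voxel simulations; the volume-level
#' contrast t-map uses a pooled two-sample t instead (see [contrast_tmap()]).
#'
#' @param x Numeric vector (raw or z-scored; the statistic is invariant to
#'   affine rescaling of the whole series).
#' @param design A [block_design()] whose labels cover `x`. The two
#'   conditions compared are `cond_on` and `cond_off`.
#' @param cond_on,cond_off Condition labels to compare (defaults "on"/"off").
#' @return A single number.
#' @export
#' @examples
#' d <- block_design(n_blocks = 2, block_duration = 2, sample_interval = 1)
#' realized_fsnr(c(1, -1, 3, 1), d)  # sqrt(2)
realized_fsnr <- function(x, design, cond_on = "on", cond_off = "off") {
  parts <- design_partition(design, n_timepoints = length(x))
  if (!all(c(cond_on, cond_off) %in% names(parts))) {
    stop_config("conditions not present in design: ",
                paste(setdiff(c(cond_on, cond_off), names(parts)), collapse = ", "))
  }
  on <- x[parts[[cond_on]]]
  off <- x[parts[[cond_off]]]
  if (length(on) < 2 || length(off) < 2) {
    stop_insufficient("need at least 2 samples per condition")
  }
  denom <- (sd(on) + sd(off)) / 2
  if (denom == 0) stop_degenerate("both condition sets are constant")
  (mean(on) - mean(off)) / denom
}

#' Bundle a magnitude/phase voxel timecourse pair
#'
#' @param magnitude,phase Equal-length numeric vectors.
#' @param design Optional [block_design()] attached as an attribute.
#' @return A tibble with columns `time` (sample index), `condition` (if a
#'   design is given), `magnitude` and `phase`; class `voxel_timecourse`.
#' @export
voxel_timecourse <- function(magnitude, phase, design = NULL) {
  if (length(magnitude) != length(phase)) {
    stop_data("magnitude and phase must have equal length")
  }
  out <- tibble(time = seq_along(magnitude), magnitude = magnitude, phase = phase)
  if (!is.null(design)) {
    if (design$n_timepoints != nrow(out)) {
      stop_data("design length does not match the timecourse")
    }
    out <- tibble(
      time = out$time, condition = design$labels,
      magnitude = magnitude, phase = phase
    )
    attr(out, "design") <- design
  }
  class(out) <- c("voxel_timecourse", class(out))
  out
}
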
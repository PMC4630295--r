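#' Slice-wise homodyne filtering of background phase
#'
#' Removes large-scale background phase (field-inhomogeneity wraps) from a
#' complex 2D slice by subtracting the phase of its low-pass-filtered
#' version: the slice's k-space is windowed by a centered square window of
#' side `kernel_fraction` times the matrix size with a smooth raised-cosine
#' (Hann) taper over its outer half, inverse-transformed, and the resulting
#' smooth phase is divided out. Only the phase is corrected; the output
#' magnitude equals the input magnitude exactly. Pixels with zero magnitude
#' get phase 0 and are reported in a mask attribute.
#'
#' @param complex_slice 2D complex matrix.
#' @param kernel_fraction Low-pass window side as a fraction of the matrix
#'   size, in (0, 1].
#' @return Complex matrix of the same size, with attribute `zero_mask`
#'   (logical matrix of zero-magnitude pixels).
#' @export
homodyne_filter <- function(complex_slice, kernel_fraction = 0.25) {
  if (length(dim(complex_slice)) != 2) stop_data("expected a 2D complex slice")
  if (kernel_fraction <= 0 || kernel_fraction > 1) {
    stop_config("`kernel_fraction` must be in (0, 1]")
  }
  d <- dim(complex_slice)
  win <- outer(homodyne_window(d[1], kernel_fraction),
               homodyne_window(d[2], kernel_fraction))
  lp <- fft(fft(complex_slice) * win, inverse = TRUE) / prod(d)
  zero <- Mod(complex_slice) == 0
  out <- complex_slice * exp(-1i * Arg(lp))
  out[zero] <- 0
  attr(out, "zero_mask") <- zero
  out
}

# 1-D k-space window in fft (unshifted) frequency order: flat over the inner
# half of the kept band, Hann roll-off over the outer half, 0 beyond. When
# the band covers the whole spectrum the window is identically 1, so the
# filter reduces to self-division (zero output phase).
homodyne_window <- function(n, fraction) {
  freq <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))  # cycles across the slice
  half <- fraction * n / 2
  flat <- 0.6 * half
  a <- abs(freq)
  w <- numeric(n)
  w[a <= flat] <- 1
  ramp <- a > flat & a < half
  w[ramp] <- 0.5 * (1 + cos(pi * (a[ramp] - flat) / (half - flat)))
  if (half >= max(a)) w[] <- 1
  w
}

#' Preprocess a complex volume series for phase regression
#'
#' The fixed order of operations is: per-timepoint, per-slice homodyne
#' filtering of the complex data ([homodyne_filter()]), then per-voxel
#' polynomial detrending ([detrend_poly()]) and z-scoring ([zscore()]) of
#' the magnitude and phase timecourses separately. Voxels whose magnitude or
#' phase is constant (zero variance) are masked out, left as zeros, and
#' reported in the result's `mask`; they never raise an error.
#'
#' @param series A [complex_volume_series()] with raw magnitude/phase.
#' @param kernel_fraction Homodyne low-pass fraction (default 0.25). Use
#'   `NULL` to skip the homodyne step (e.g. for data already unwrapped).
#' @param degree Detrending polynomial degree (default 3).
#' @return A [complex_volume_series()] in z-score units (`zscored = TRUE`)
#'   with the degenerate-voxel `mask` filled in.
#' @export
preprocess_series <- function(series, kernel_fraction = 0.25, degree = 3) {
  d <- dim(series$magnitude)
  mag <- series$magnitude
  ph <- series$phase
  if (!is.null(kernel_fraction)) {
    for (t in seq_len(d[4])) {
      for (k in seq_len(d[3])) {
        cs <- mag[, , k, t] * exp(1i * ph[, , k, t])
        f <- homodyne_filter(cs, kernel_fraction)
        ph[, , k, t] <- Arg(f)
        # magnitude untouched by construction
      }
    }
  }
  mask <- array(FALSE, d[1:3])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        m <- mag[i, j, k, ]
        p <- ph[i, j, k, ]
        if (sd(m) == 0 || sd(p) == 0) {
          mask[i, j, k] <- TRUE
          mag[i, j, k, ] <- 0
          ph[i, j, k, ] <- 0
          next
        }
        dm <- detrend_poly(m, degree)
        dp <- detrend_poly(p, degree)
        if (sd(dm) == 0 || sd(dp) == 0) {
          mask[i, j, k] <- TRUE
          mag[i, j, k, ] <- 0
          ph[i, j, k, ] <- 0
        } else {
          mag[i, j, k, ] <- zscore(dm)
          ph[i, j, k, ] <- zscore(dp)
        }
      }
    }
  }
  complex_volume_series(mag, ph, voxel_size = series$voxel_size,
                        sample_interval = series$sample_interval,
                        zscored = TRUE, mask = mask)
}
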
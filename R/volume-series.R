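#' Paired magnitude/phase 4D volume time series
#'
#' The container for complex-valued fMRI data stored in the
#' acquisition-native convention: separate magnitude and phase 4D arrays
#' (x, y, z, t), phase in radians in (-pi, pi] (or z-score units after
#' preprocessing).
#'
#' @param magnitude,phase 4D numeric arrays of identical dimension.
#' @param voxel_size Length-3 voxel size in mm.
#' @param sample_interval Sampling interval (TR) in seconds.
#' @param zscored Logical: have the per-voxel series been detrended and
#'   z-scored (units are then z-scores, not raw signal/radians)?
#' @param mask Optional 3D logical array of voxels flagged degenerate.
#' @return A `complex_volume_series` object.
#' @export
complex_volume_series <- function(magnitude, phase,
                                  voxel_size = c(1, 1, 1),
                                  sample_interval = 1,
                                  zscored = FALSE, mask = NULL) {
  if (length(dim(magnitude)) != 4 || !identical(dim(magnitude), dim(phase))) {
    stop_data("magnitude and phase must be 4D arrays of identical dimension")
  }
  if (!zscored) {
    if (any(magnitude < 0, na.rm = TRUE)) stop_data("magnitude must be non-negative")
  }
  structure(
    list(
      magnitude = magnitude, phase = phase,
      voxel_size = voxel_size, sample_interval = sample_interval,
      zscored = zscored, mask = mask
    ),
    class = "complex_volume_series"
  )
}

#' @export
print.complex_volume_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "<complex_volume_series> %d x %d x %d voxels x %d timepoints, voxel %s mm, TR %g s%s\n",
    d[1], d[2], d[3], d[4], paste(signif(x$voxel_size, 3), collapse = " x "),
    x$sample_interval, if (x$zscored) " (z-scored)" else ""
  ))
  if (!is.null(x$mask)) cat(sprintf("  %d voxels flagged degenerate\n", sum(x$mask)))
  invisible(x)
}

#' Extract one voxel's timecourse from a volume series
#'
#' @param series A [complex_volume_series()].
#' @param ijk Length-3 integer voxel index.
#' @return A [voxel_timecourse()] tibble.
#' @export
series_voxel <- function(series, ijk) {
  voxel_timecourse(
    series$magnitude[ijk[1], ijk[2], ijk[3], ],
    series$phase[ijk[1], ijk[2], ijk[3], ]
  )
}
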
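#' Frozen phantom configurations
#'
#' Ready-made phantom specifications whose geometry and amplitudes were
#' calibrated once to realize, at desk scale, the magnitude/phase fSNR
#' taxonomy around a large vein: a vein-containing voxel with high magnitude
#' but low phase fSNR (the field it samples is symmetric about 0 Hz), a
#' vein-adjacent voxel with the converse (a weak, single-polarity field
#' lobe), and far-field voxels with neither. The voxels immediately flanking
#' the vein carry the strongest single-polarity phase lobes and serve as the
#' sPR phase sources; the `adjacent` key voxel two steps lateral shows the
#' clean low-magnitude/high-phase taxonomy. See the package vignette for the
#' calibration rationale.
#'
#' `phantom_single_vein()` contains one vein (radius 0.5 mm, about a quarter
#' of the voxel cross-section) perpendicular to B0 along y.
#' `phantom_two_vein()` adds hemisphere structure for laterality analyses: a
#' "right-hemisphere" vein of the same size, a smaller sub-voxel "left"
#' vein, and one purely parenchymal activation region per hemisphere (a
#' 1.2% fractional magnitude response with no phase signature), placed far
#' from either vein's phase halo.
#'
#' @return A list with elements `grid` ([phantom_grid()]), `veins` (list of
#'   [vein_model()]), `parenchyma`, `design` ([block_design()] at TR 2 s,
#'   112 volumes), `noise_sd`, `background_phase`, and `voxels`, a named
#'   list of key voxel ijk indices (`vein`, `adjacent`, `far`; for the
#'   two-vein phantom also `vein_left`, `parenchyma_right`,
#'   `parenchyma_left`) plus `split_x` for the two-vein phantom.
#' @export
phantom_single_vein <- function() {
  list(
    grid = phantom_grid(dim = c(16, 10, 5), voxel_size = c(2, 2, 2),
                        sample_interval = 2),
    veins = list(vein_model(center = c(15, 0, 5), radius = 0.5,
                            theta = pi / 2, azimuth = pi / 2,
                            oxygenation_active = 0.70)),
    parenchyma = NULL,
    design = block_design(n_blocks = 14, block_duration = 16,
                          sample_interval = 2),
    noise_sd = 0.005,
    background_phase = c(0.4, 0.25, 0.1, 0.08),
    voxels = list(
      vein = c(8L, 5L, 3L),
      adjacent = c(10L, 5L, 3L),
      source = c(9L, 5L, 3L),
      far = c(2L, 8L, 1L)
    )
  )
}

#' @rdname phantom_single_vein
#' @export
phantom_two_vein <- function() {
  list(
    grid = phantom_grid(dim = c(26, 10, 5), voxel_size = c(2, 2, 2),
                        sample_interval = 2),
    veins = list(
      vein_model(center = c(39, 0, 5), radius = 0.5,
                 theta = pi / 2, azimuth = pi / 2,
                 oxygenation_active = 0.70),
      vein_model(center = c(13, 0, 5), radius = 0.3,
                 theta = pi / 2, azimuth = pi / 2,
                 oxygenation_active = 0.70)
    ),
    parenchyma = list(
      list(lo = c(48, 6, 4), hi = c(52, 12, 6), delta = 0.012),
      list(lo = c(0, 6, 4), hi = c(4, 12, 6), delta = 0.012)
    ),
    design = block_design(n_blocks = 14, block_duration = 16,
                          sample_interval = 2),
    noise_sd = 0.005,
    background_phase = c(0.4, 0.25, 0.1, 0.08),
    split_x = 13L,
    voxels = list(
      vein = c(20L, 5L, 3L),
      adjacent = c(22L, 5L, 3L),
      vein_left = c(7L, 5L, 3L),
      parenchyma_right = c(25L, 5L, 3L),
      parenchyma_left = c(2L, 5L, 3L),
      far = c(13L, 9L, 1L)
    )
  )
}
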
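#' Read a magnitude/phase NIfTI pair as a complex volume series
#'
#' Loads paired 4D magnitude and phase volumes, validating that shapes and
#' orientations (affines) match. Phase stored in scaled-integer conventions
#' is auto-detected and rescaled to radians in (-pi, pi]: integer data
#' spanning about +/-4096 is divided by 4096/pi, and data in (0, 2*pi] is
#' re-wrapped; either rescaling is reported with a message. Phase outside
#' any plausible convention is a format error.
#'
#' @param mag_path,phase_path Paths to NIfTI files (.nii or .nii.gz).
#' @return A [complex_volume_series()] with voxel size and sampling interval
#'   taken from the NIfTI header.
#' @export
read_complex_series <- function(mag_path, phase_path) {
  for (p in c(mag_path, phase_path)) {
    if (!file.exists(p)) stop_data("file not found: ", p)
  }
  mag <- RNifti::readNifti(mag_path)
  ph <- RNifti::readNifti(phase_path)
  if (!identical(dim(mag), dim(ph))) {
    stop_data(sprintf("shape mismatch: magnitude %s vs phase %s",
                      paste(dim(mag), collapse = "x"),
                      paste(dim(ph), collapse = "x")))
  }
  if (length(dim(mag)) != 4) stop_data("expected 4D volumes")
  xm <- RNifti::xform(mag)
  xp <- RNifti::xform(ph)
  if (max(abs(xm - xp)) > 1e-4) stop_data("affine mismatch between magnitude and phase")
  pd <- RNifti::pixdim(mag)
  ph <- rescale_phase(as.array(ph))
  complex_volume_series(
    as.array(mag), ph,
    voxel_size = pd[1:3],
    sample_interval = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  )
}

rescale_phase <- function(ph, tol = 1e-3) {
  mx <- max(ph)
  mn <- min(ph)
  if (mx <= pi + tol && mn >= -pi - tol) return(ph)
  integerish <- max(abs(ph - round(ph))) < 1e-6
  if (integerish && max(abs(c(mx, mn))) <= 4096 + tol &&
      max(abs(c(mx, mn))) > 2048) {
    inform("phase stored as scaled integers (+/-4096); rescaling to radians")
    return(ph * (pi / 4096))
  }
  if (mn >= -tol && mx <= 2 * pi + tol) {
    inform("phase stored in (0, 2*pi]; re-wrapping to (-pi, pi]")
    out <- ph
    out[out > pi] <- out[out > pi] - 2 * pi
    return(out)
  }
  stop_data(sprintf(
    "phase range [%.3g, %.3g] matches no known convention", mn, mx
  ))
}

#' Write a complex volume series as a magnitude/phase NIfTI pair
#'
#' @param series A [complex_volume_series()].
#' @param mag_path,phase_path Output NIfTI paths.
#' @param sidecar Optional path for a JSON sidecar describing the series
#'   (voxel size, sampling interval, and any extra metadata passed in
#'   `meta`).
#' @param meta Optional named list merged into the sidecar.
#' @return Invisibly, the magnitude path.
#' @export
write_complex_series <- function(series, mag_path, phase_path,
                                 sidecar = NULL, meta = NULL) {
  pd <- c(series$voxel_size, series$sample_interval)
  m <- RNifti::asNifti(series$magnitude)
  p <- RNifti::asNifti(series$phase)
  RNifti::pixdim(m) <- pd
  RNifti::pixdim(p) <- pd
  RNifti::writeNifti(m, mag_path)
  RNifti::writeNifti(p, phase_path)
  if (!is.null(sidecar)) {
    info <- c(list(voxel_size = series$voxel_size,
                   sample_interval = series$sample_interval,
                   zscored = series$zscored), meta)
    jsonlite::write_json(info, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(mag_path)
}

#' Generate the frozen fixture set
#'
#' Writes seed-pinned reference data used by examples and tests: the
#' single-vein and two-vein phantom NIfTI pairs (with JSON sidecars), a
#' 50-point z-scored magnitude/phase fixture series (CSV), a reduced
#' 11 x 11 suppression grid (CSV), and a manifest with MD5 content hashes.
#' Outputs are byte-identical for a given seed.
#'
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
make_fixtures <- function(seed = 1L, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # 50-point PR fixture pair
  set.seed(seed)
  fdes <- block_design(n_blocks = 2, block_duration = 25, sample_interval = 1)
  tc <- simulate_voxel(3, 3, fdes, seed = seed)
  fx <- data.frame(time = tc$time, condition = tc$condition,
                   Sm = zscore(tc$magnitude), Sp = zscore(tc$phase))
  pr_path <- file.path(dir, "pr_fixture.csv")
  write.csv(format(fx, digits = 17, trim = TRUE), pr_path,
            row.names = FALSE, quote = FALSE)
  # reduced 11 x 11 grid, both methods
  grid <- run_grid(step = 1.0, seed = seed)
  grid_path <- file.path(dir, "grid11.csv")
  write.csv(format(as.data.frame(grid), digits = 17, trim = TRUE), grid_path,
            row.names = FALSE, quote = FALSE)
  # phantoms
  paths <- c(pr_path, grid_path)
  for (type in c("single", "two")) {
    spec <- if (type == "single") phantom_single_vein() else phantom_two_vein()
    series <- synthesize_phantom(spec$grid, spec$veins, spec$design,
                                 noise_sd = spec$noise_sd, seed = seed,
                                 parenchyma = spec$parenchyma,
                                 background_phase = spec$background_phase)
    mp <- file.path(dir, paste0("phantom_", type, "_mag.nii.gz"))
    pp <- file.path(dir, paste0("phantom_", type, "_phase.nii.gz"))
    sc <- file.path(dir, paste0("phantom_", type, ".json"))
    write_complex_series(series, mp, pp, sidecar = sc,
                         meta = list(type = type, seed = seed,
                                     design = spec$design[
                                       c("n_blocks", "block_duration",
                                         "sample_interval", "hemodynamic_delay")]))
    paths <- c(paths, mp, pp, sc)
  }
  manifest <- list(seed = seed,
                   files = lapply(paths, function(p) {
                     list(file = basename(p),
                          md5 = unname(tools::md5sum(p)))
                   }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
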
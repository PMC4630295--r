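#' Cylinder model of a vein and its acquisition parameters
#'
#' Describes one vein as an infinite cylinder of deoxygenated blood, plus the
#' acquisition constants needed to turn its susceptibility into an
#' off-resonance field and a measured signal. The susceptibility difference
#' between blood and tissue is `dchi_do * hematocrit * (1 - Y)` with `Y` the
#' blood oxygenation fraction; activation raises `Y` (shrinking the
#' difference), which is the BOLD effect the phantom generates.
#'
#' @param center Length-3 point on the vein axis, mm.
#' @param radius Vein radius, mm.
#' @param theta Tilt: angle between the vein axis and B0 (radians, 0..pi/2).
#'   B0 is along +z.
#' @param azimuth In-plane orientation of the axis (radians); the axis is
#'   `(sin(theta)cos(azimuth), sin(theta)sin(azimuth), cos(theta))`.
#' @param oxygenation_rest,oxygenation_active Blood oxygenation fraction Y at
#'   rest (default 0.54, a typical venous value) and during activation.
#' @param hematocrit Blood hematocrit fraction (default 0.40).
#' @param dchi_do Susceptibility of fully deoxygenated blood vs tissue, ppm
#'   (SI; default 4 * pi * 0.27).
#' @param field_strength B0 in Tesla (default 4).
#' @param echo_time TE in seconds (default 0.028 for fMRI; venograms use
#'   0.026).
#' @param t2star_blood,t2star_tissue T2* of venous blood and tissue in
#'   seconds (defaults 0.012 and 0.040 at 4 T; venous blood is much shorter
#'   than parenchyma).
#' @return A `vein_model` object (list).
#' @export
vein_model <- function(center = c(0, 0, 0), radius = 1, theta = pi / 2,
                       azimuth = pi / 2,
                       oxygenation_rest = 0.54, oxygenation_active = 0.64,
                       hematocrit = 0.40, dchi_do = 4 * pi * 0.27,
                       field_strength = 4, echo_time = 0.028,
                       t2star_blood = 0.012, t2star_tissue = 0.040) {
  if (radius <= 0) stop_config("radius must be positive")
  if (theta < 0 || theta > pi / 2) stop_config("theta must be in [0, pi/2]")
  for (y in c(oxygenation_rest, oxygenation_active)) {
    if (y < 0 || y > 1) stop_config("oxygenation fractions must be in [0, 1]")
  }
  structure(
    list(
      center = center, radius = radius, theta = theta, azimuth = azimuth,
      oxygenation_rest = oxygenation_rest,
      oxygenation_active = oxygenation_active,
      hematocrit = hematocrit, dchi_do = dchi_do,
      field_strength = field_strength, echo_time = echo_time,
      t2star_blood = t2star_blood, t2star_tissue = t2star_tissue
    ),
    class = "vein_model"
  )
}

#' @export
print.vein_model <- function(x, ...) {
  cat(sprintf(
    "<vein_model> R = %g mm, tilt %.1f deg, center (%s) mm, Y %g -> %g, B0 %g T, TE %g ms\n",
    x$radius, x$theta * 180 / pi, paste(x$center, collapse = ", "),
    x$oxygenation_rest, x$oxygenation_active, x$field_strength,
    x$echo_time * 1000
  ))
  invisible(x)
}

GAMMA_BAR <- 42.577478518e6  # proton gyromagnetic ratio / 2pi, Hz per Tesla

vein_axis <- function(model) {
  c(sin(model$theta) * cos(model$azimuth),
    sin(model$theta) * sin(model$azimuth),
    cos(model$theta))
}

#' Off-resonance field of a vein at given points
#'
#' Field shift in Hz of the infinite-cylinder susceptibility model. Outside
#' the vein the extravascular dipole form applies,
#' \deqn{\Delta f = (\Delta\chi/2) f_0 (R/r)^2 \sin^2\theta \cos 2\phi,}
#' and inside the vein
#' \deqn{\Delta f = (\Delta\chi/6) f_0 (3\cos^2\theta - 1),}
#' where `Delta chi = dchi_do * hematocrit * (1 - Y)` (ppm), `f0` the Larmor
#' frequency at the model's field strength, `r` the distance from the vein
#' axis, and `phi` the angle in the plane normal to the axis measured from
#' the projected B0 direction. Veins parallel to B0 produce no extravascular
#' shift; the intravascular shift vanishes at the magic angle
#' (`3 cos^2 theta = 1`, about 54.7 degrees).
#'
#' @param points N x 3 matrix (or a length-3 vector) of mm coordinates.
#' @param model A [vein_model()].
#' @param oxygenation Blood oxygenation Y used for the susceptibility
#'   difference (defaults to the model's resting value).
#' @return Numeric vector of field shifts in Hz, one per point.
#' @export
offres_field <- function(points, model, oxygenation = model$oxygenation_rest) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  u <- vein_axis(model)
  dchi <- model$dchi_do * model$hematocrit * (1 - oxygenation) * 1e-6
  f0 <- GAMMA_BAR * model$field_strength
  d <- sweep(points, 2, model$center)
  along <- as.numeric(d %*% u)
  perp <- d - outer(along, u)
  r2 <- rowSums(perp^2)
  sin2 <- sin(model$theta)^2
  cos2th <- cos(model$theta)^2
  inside <- r2 <= model$radius^2
  out <- numeric(nrow(points))
  out[inside] <- (dchi / 6) * f0 * (3 * cos2th - 1)
  if (any(!inside) && sin2 > 0) {
    # e1: unit projection of B0 (+z) onto the plane normal to the axis
    e1 <- c(0, 0, 1) - cos(model$theta) * u
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    p1 <- as.numeric(perp %*% e1)
    p2 <- as.numeric(perp %*% e2)
    i <- !inside
    cos2phi <- (p1[i]^2 - p2[i]^2) / r2[i]
    out[i] <- (dchi / 2) * f0 * (model$radius^2 / r2[i]) * sin2 * cos2phi
  }
  out
}

#' Voxel grid specification for the phantom
#'
#' @param dim Length-3 integer grid dimension (x, y, z; z is axial/slice).
#' @param voxel_size Length-3 voxel size, mm.
#' @param sample_interval Sampling interval (TR) for synthesized series,
#'   seconds.
#' @return A `phantom_grid` list. Voxel centers are at
#'   `(i - 0.5) * voxel_size`, a right-handed mm coordinate frame.
#' @export
phantom_grid <- function(dim = c(16, 10, 5), voxel_size = c(2, 2, 2),
                         sample_interval = 2) {
  structure(
    list(dim = as.integer(dim), voxel_size = voxel_size,
         sample_interval = sample_interval),
    class = "phantom_grid"
  )
}

voxel_centers_1d <- function(n, vs) (seq_len(n) - 0.5) * vs

in_box <- function(pts, box) {
  pts[, 1] >= box$lo[1] & pts[, 1] <= box$hi[1] &
    pts[, 2] >= box$lo[2] & pts[, 2] <= box$hi[2] &
    pts[, 3] >= box$lo[3] & pts[, 3] <= box$hi[3]
}

#' Noiseless phantom signal volumes for the rest and active states
#'
#' Computes, for every voxel, the noiseless complex signal at echo time as
#' the mean over a regular `subdivisions^3` grid of subvoxel sample points of
#' `w(p) * exp(i * 2 pi * Delta f(p) * TE)`. The weight `w` applies the T2*
#' decay of blood (inside any vein) or tissue; tissue inside a parenchymal
#' activation region gains a fractional signal increase `delta` in the active
#' state (a microvascular BOLD response with no phase signature). The active
#' state uses each vein's `oxygenation_active` for the field; rest uses
#' `oxygenation_rest`. An optional smooth background phase (offset plus
#' linear gradient) emulates large-scale field inhomogeneity.
#'
#' @param grid A [phantom_grid()].
#' @param veins A [vein_model()] or list of them. Acquisition constants
#'   (field strength, TE, T2*) are taken from the first vein.
#' @param parenchyma Optional list of activation regions, each a list with
#'   `lo`, `hi` (mm corners) and `delta` (fractional signal change when
#'   active).
#' @param subdivisions Subvoxel sampling density per dimension (default 15;
#'   minimum 5).
#' @param background_phase Length-4 numeric `c(offset, gx, gy, gz)`: phase
#'   offset (rad) and gradient (rad/mm) evaluated at voxel centers. NULL for
#'   none.
#' @param echo_time Optional TE override in seconds (e.g. 0.026 for a
#'   venogram).
#' @return List with complex 3D arrays `off` and `on`.
#' @export
phantom_signal <- function(grid, veins, parenchyma = NULL, subdivisions = 15,
                           background_phase = NULL, echo_time = NULL) {
  if (inherits(veins, "vein_model")) veins <- list(veins)
  if (subdivisions < 5) stop_config("subvoxel sampling density below minimum (5)")
  acq <- veins[[1]]
  TE <- echo_time %||% acq$echo_time
  w_blood <- exp(-TE / acq$t2star_blood)
  w_tissue <- exp(-TE / acq$t2star_tissue)
  nd <- grid$dim
  vs <- grid$voxel_size
  s <- as.integer(subdivisions)
  sub <- function(vsd) ((seq_len(s) - 0.5) / s - 0.5) * vsd
  xs <- voxel_centers_1d(nd[1], vs[1])
  ys <- voxel_centers_1d(nd[2], vs[2])
  zs <- voxel_centers_1d(nd[3], vs[3])
  states <- list(
    off = array(complex(real = 0), nd),
    on = array(complex(real = 0), nd)
  )
  # process slice by slice to bound memory
  for (k in seq_len(nd[3])) {
    px <- rep(rep(xs, each = s) + sub(vs[1]), times = nd[2] * s * s)
    py <- rep(rep(rep(ys, each = s) + sub(vs[2]), each = nd[1] * s), times = s)
    pz <- rep(zs[k] + sub(vs[3]), each = nd[1] * s * nd[2] * s)
    pts <- cbind(px, py, pz)
    # owning voxel of each subpoint, aligned with the orderings above
    ix <- rep(rep(seq_len(nd[1]), each = s), times = nd[2] * s * s)
    iy <- rep(rep(rep(seq_len(nd[2]), each = s), each = nd[1] * s), times = s)
    vox <- ix + nd[1] * (iy - 1L)
    h <- mean(vs) / s
    # the dipole field varies fastest at the vessel wall; subcells within
    # ~1.5 cells of a wall are refined by a finer local grid so the
    # dephasing integral converges at moderate base sampling
    wall_dist <- Reduce(pmin, lapply(veins, function(v) {
      u <- vein_axis(v)
      d <- sweep(pts, 2, v$center)
      along <- as.numeric(d %*% u)
      abs(sqrt(pmax(rowSums(d^2) - along^2, 0)) - v$radius)
    }))
    need <- wall_dist < 1.5 * h
    m <- 4L
    wt <- rep(1, sum(!need))
    cellscale <- rep(1, sum(!need))
    if (any(need)) {
      offs1 <- function(vsd) ((seq_len(m) - 0.5) / m - 0.5) * vsd / s
      og <- as.matrix(expand.grid(x = offs1(vs[1]), y = offs1(vs[2]),
                                  z = offs1(vs[3])))
      nref <- sum(need)
      ptsr <- pts[need, , drop = FALSE][rep(seq_len(nref), each = m^3), ] +
        og[rep(seq_len(m^3), times = nref), ]
      pts <- rbind(pts[!need, , drop = FALSE], ptsr)
      vox <- c(vox[!need], rep(vox[need], each = m^3))
      wt <- c(wt, rep(1 / m^3, nref * m^3))
      cellscale <- c(cellscale, rep(1 / m, nref * m^3))
    }
    # per-vein geometry: dimensionless field factors and the subcell blood
    # fraction (anti-aliased across the vessel wall over one subcell width)
    h_eff <- h * cellscale
    geom <- lapply(veins, function(v) {
      u <- vein_axis(v)
      d <- sweep(pts, 2, v$center)
      along <- as.numeric(d %*% u)
      perp <- d - outer(along, u)
      r2 <- rowSums(perp^2)
      fb <- pmin(1, pmax(0, (v$radius - sqrt(r2)) / h_eff + 0.5))
      sin2 <- sin(v$theta)^2
      g_out <- numeric(length(r2))
      grad <- matrix(0, length(r2), 3)
      if (sin2 > 0) {
        e1 <- c(0, 0, 1) - cos(v$theta) * u
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
                u[1] * e1[2] - u[2] * e1[1])
        r2c <- pmax(r2, (v$radius / 4)^2)  # keep finite on the axis
        rc <- sqrt(r2c)
        p1 <- as.numeric(perp %*% e1)
        p2 <- as.numeric(perp %*% e2)
        cos2phi <- (p1^2 - p2^2) / r2c
        sin2phi <- 2 * p1 * p2 / r2c
        g_out <- (v$radius^2 / r2c) * sin2 * cos2phi / 2
        # analytic in-plane gradient of g_out (per mm), for the first-order
        # intra-subcell dephasing correction; zero outside-the-wall only
        cphi <- p1 / rc
        sphi <- p2 / rc
        amp <- -(v$radius^2 / (r2c * rc)) * sin2
        gr <- amp * cos2phi   # radial derivative of g_out
        gphi <- amp * sin2phi # tangential derivative (1/r) d/dphi
        ge1 <- gr * cphi - gphi * sphi
        ge2 <- gr * sphi + gphi * cphi
        grad <- outer(ge1, e1) + outer(ge2, e2)
        grad[fb > 0, ] <- 0  # interior/wall handled by partial-volume blend
      }
      g_in <- (3 * cos(v$theta)^2 - 1) / 6
      list(fb = fb, g_out = g_out, g_in = g_in, grad = grad)
    })
    fb_tot <- Reduce(`+`, lapply(geom, `[[`, "fb"))
    fb_tot <- pmin(fb_tot, 1)
    for (state in c("off", "on")) {
      scale <- vapply(veins, function(v) {
        y <- if (state == "on") v$oxygenation_active else v$oxygenation_rest
        v$dchi_do * v$hematocrit * (1 - y) * 1e-6 * GAMMA_BAR * v$field_strength
      }, numeric(1))
      f_out <- Reduce(`+`, Map(function(g, sc) sc * g$g_out, geom, scale))
      # first-order intra-subcell dephasing: each subcell stands for a patch
      # with locally linear phase, contributing sinc factors per dimension
      gradsum <- Reduce(`+`, Map(function(g, sc) sc * g$grad, geom, scale))
      atten <- rep(1, nrow(pts))
      for (dimn in 1:3) {
        x <- pi * gradsum[, dimn] * TE * (vs[dimn] / s) * cellscale
        sn <- ifelse(abs(x) < 1e-8, 1, sin(x) / x)
        atten <- atten * sn
      }
      w_t <- rep(w_tissue, nrow(pts))
      if (state == "on" && !is.null(parenchyma)) {
        for (reg in parenchyma) {
          w_t <- ifelse(in_box(pts, reg), w_t * (1 + reg$delta), w_t)
        }
      }
      sig <- (1 - fb_tot) * w_t * atten * exp(2i * pi * f_out * TE)
      for (q in seq_along(veins)) {
        g <- geom[[q]]
        f_blood <- f_out - scale[q] * g$g_out + scale[q] * g$g_in
        sig <- sig + g$fb * w_blood * exp(2i * pi * f_blood * TE)
      }
      acc <- rowsum(wt * cbind(Re(sig), Im(sig)), vox, reorder = TRUE) / (s^3)
      full <- matrix(0, nd[1] * nd[2], 2)
      full[as.integer(rownames(acc)), ] <- acc
      states[[state]][, , k] <- complex(real = full[, 1], imaginary = full[, 2])
    }
  }
  if (!is.null(background_phase)) {
    bp <- outer(xs * background_phase[2], ys * background_phase[3], "+")
    for (k in seq_len(nd[3])) {
      ph <- background_phase[1] + bp + zs[k] * background_phase[4]
      rot <- exp(1i * ph)
      states$off[, , k] <- states$off[, , k] * rot
      states$on[, , k] <- states$on[, , k] * rot
    }
  }
  states
}

#' Synthesize a noisy complex-valued 4D phantom series
#'
#' Builds the rest/active noiseless volumes with [phantom_signal()] (or
#' reuses precomputed ones), then for every timepoint selects the volume for
#' that condition ("on" uses the active state), adds independent complex
#' Gaussian noise of standard deviation `noise_sd` per component, and splits
#' the result into magnitude and phase (wrapped into (-pi, pi]).
#'
#' @inheritParams phantom_signal
#' @param design A [block_design()] with "off"/"on" labels; its
#'   `sample_interval` should match the grid's.
#' @param noise_sd Complex noise standard deviation per component.
#' @param seed Integer seed.
#' @param states Optional precomputed result of [phantom_signal()].
#' @return A [complex_volume_series()].
#' @export
synthesize_phantom <- function(grid, veins, design, noise_sd, seed = 1L,
                               parenchyma = NULL, subdivisions = 15,
                               background_phase = NULL, states = NULL) {
  states <- states %||% phantom_signal(grid, veins, parenchyma = parenchyma,
                                       subdivisions = subdivisions,
                                       background_phase = background_phase)
  nd <- grid$dim
  nt <- design$n_timepoints
  set.seed(seed)
  mag <- array(0, c(nd, nt))
  ph <- array(0, c(nd, nt))
  nvox <- prod(nd)
  for (t in seq_len(nt)) {
    base <- if (design$labels[t] == "on") states$on else states$off
    noisy <- base + complex(real = rnorm(nvox, sd = noise_sd),
                            imaginary = rnorm(nvox, sd = noise_sd))
    mag[, , , t] <- Mod(noisy)
    ph[, , , t] <- Arg(noisy)
  }
  complex_volume_series(mag, ph, voxel_size = grid$voxel_size,
                        sample_interval = grid$sample_interval)
}

#' Minimum-intensity projection venogram
#'
#' Sliding-slab minimum intensity projection in the axial (z) plane: each
#' output slice is the voxelwise minimum over the centered slab of input
#' slices, with truncated slabs at the volume edges. Veins, being dark on
#' susceptibility-weighted magnitude images, propagate through the
#' projection.
#'
#' @param magnitude_volume 3D array.
#' @param slab Odd slab width in slices (default 3), at most the axial
#'   extent.
#' @return 3D array of the same dimension.
#' @export
venogram_mip <- function(magnitude_volume, slab = 3) {
  nz <- dim(magnitude_volume)[3]
  if (slab %% 2 != 1) stop_config("slab must be odd")
  if (slab > nz) stop_config("slab larger than the axial extent")
  h <- (slab - 1L) / 2L
  out <- magnitude_volume
  for (k in seq_len(nz)) {
    ks <- max(1L, k - h):min(nz, k + h)
    out[, , k] <- apply(magnitude_volume[, , ks, drop = FALSE], c(1, 2), min)
  }
  out
}
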
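# Vectorial Debye (Richards-Wolf) focal fields.
#
# The focal field of an aplanatic high-NA objective is the angular spectrum
# integral over the pupil directions s = (sx, sy), |s| <= NA/n:
#
#   E_c(r) = sum_pupil  K_c(s) exp(i k (sx x + sy y + cz z)),   cz = cos(theta)
#
# with k = 2 pi n / lambda and the strength kernels
#
#   K_c = sqrt(cz) * A(s) * R_c(s) / cz
#
# where A is the complex pupil field, sqrt(cz) the aplanatic apodization,
# 1/cz the solid-angle measure, and R the polarization rotation of the lens:
# the azimuthal component of the input field stays transverse while the
# radial component tilts onto (cz cos(phi), cz sin(phi), sin(theta)).
#
# Everything downstream evaluates these sums either exactly at arbitrary
# points (direct nonuniform DFT; cheap for small point sets and line
# profiles) or on Cartesian grids via the chirp-z transform (czt2d), which
# allows any voxel size independent of the pupil sampling. The pupil is kept
# split into its EOM-switchable and static parts so that a single
# diffraction computation yields the PSF at every EOM phase.

focal_kernels <- function(pupil) {
  g <- pupil$grid
  cz <- sqrt(pmax(1 - g$sr^2, 0))
  phi <- atan2(g$sy, g$sx)
  cphi <- cos(phi); sphi <- sin(phi)
  st <- g$sr
  ex <- pupil$polarization[1]; ey <- pupil$polarization[2]
  a <- -ex * sphi + ey * cphi          # azimuthal component
  b <- ex * cphi + ey * sphi           # radial component
  rot <- list(x = -a * sphi + b * cz * cphi,
              y = a * cphi + b * cz * sphi,
              z = b * st)
  fac <- sqrt(cz) / pmax(cz, .Machine$double.eps)
  mk <- function(amp) lapply(rot, function(r) amp * r * fac)
  list(on = mk(pupil$amp_on), off = mk(pupil$amp_off),
       cz = cz, g = g,
       k = 2 * pi * pupil$config$refractive_index / pupil$config$wavelength_nm,
       pupil = pupil)
}

# complex matrix product via four real BLAS products (R's complex %*% is slow)
cmatmul <- function(a, b) {
  ar <- Re(a); ai <- Im(a); br <- Re(b); bi <- Im(b)
  (ar %*% br - ai %*% bi) + 1i * (ar %*% bi + ai %*% br)
}

# Exact field evaluation at arbitrary points (nm). Returns a list with
# complex P x 3 matrices `on` and `off`.
field_at_points <- function(kern, x, y, z, chunk = 64L) {
  np <- length(x)
  stopifnot(length(y) == np, length(z) == np)
  sxf <- as.vector(kern$g$sx); syf <- as.vector(kern$g$sy)
  czf <- as.vector(kern$cz)
  kmat <- cbind(as.vector(kern$off$x), as.vector(kern$off$y),
                as.vector(kern$off$z), as.vector(kern$on$x),
                as.vector(kern$on$y), as.vector(kern$on$z))
  out <- matrix(0i, np, 6L)
  for (i0 in seq(1L, np, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, np)
    ph <- exp(1i * kern$k * (outer(x[ii], sxf) + outer(y[ii], syf) +
                               outer(z[ii], czf)))
    out[ii, ] <- cmatmul(ph, kmat)
  }
  list(off = out[, 1:3, drop = FALSE], on = out[, 4:6, drop = FALSE])
}

# Field on a Cartesian grid via chirp-z, one z-plane at a time. Returns
# complex arrays [nx, ny, nz, 3] for the on and off pupil parts.
field_on_grid <- function(kern, xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  dx <- if (nx > 1) xs[2] - xs[1] else 0
  dy <- if (ny > 1) ys[2] - ys[1] else 0
  ds <- kern$g$ds
  psi_x <- kern$k * ds * dx
  psi_y <- kern$k * ds * dy
  shift_x <- mean(xs); shift_y <- mean(ys)   # grids must be uniform, centered
  comp <- c("x", "y", "z")
  eon <- array(0i, c(nx, ny, nz, 3)); eoff <- array(0i, c(nx, ny, nz, 3))
  lin <- exp(1i * kern$k * (kern$g$sx * shift_x + kern$g$sy * shift_y))
  for (iz in seq_len(nz)) {
    defoc <- lin * exp(1i * kern$k * kern$cz * zs[iz])
    for (ic in 1:3) {
      eoff[, , iz, ic] <- czt2d(kern$off[[comp[ic]]] * defoc, nx, ny,
                                psi_x, psi_y)
      eon[, , iz, ic] <- czt2d(kern$on[[comp[ic]]] * defoc, nx, ny,
                               psi_x, psi_y)
    }
  }
  list(off = eoff, on = eon)
}

# intensity |E_off + e^{i phi} E_on|^2 summed over the three components;
# fields as [.., 3] arrays or P x 3 matrices.
modes_intensity <- function(modes, eom_phase) {
  e <- modes$off + exp(1i * eom_phase) * modes$on
  d <- dim(e)
  nc <- d[length(d)]
  stopifnot(nc == 3L)
  m <- matrix(e, ncol = 3L)
  ii <- rowSums(Mod(m)^2)
  if (length(d) > 2L) array(ii, d[-length(d)]) else ii
}

# --- Airy reference normalization ------------------------------------------

.airy_cache <- new.env(parent = emptyenv())

config_key <- function(config) {
  paste(config$na, config$refractive_index, config$wavelength_nm,
        config$aperture_diameter_mm, config$beam_diameter_mm,
        config$beam_profile, config$pupil_n, sep = "|")
}

#' Airy reference maximum of a configuration
#'
#' The central intensity of the flat-phase (Airy) PSF for the given
#' configuration, per unit pupil power. All PSFs are expressed in units of
#' this value \eqn{I_A(0)}: every PSF is first normalized by its total
#' integrated light (pupil power, which by Parseval equals the integrated
#' focal intensity in any plane) and then scaled so that the flat-phase
#' reference PSF of the same configuration has maximum exactly 1. Its value
#' is independent of the (uniform) input polarization.
#'
#' @param config An [optical_config()].
#' @return The raw central Airy intensity per unit pupil power (used
#'   internally to express PSFs in \eqn{I_A(0)} units).
#' @export
airy_reference <- function(config) {
  key <- config_key(config)
  hit <- .airy_cache[[key]]
  if (!is.null(hit)) return(hit)
  pu <- build_pupil(config, phase_mask("flat"), pol_linear(0), 0)
  kern <- focal_kernels(pu)
  f <- field_at_points(kern, 0, 0, 0)
  val <- modes_intensity(f, 0) / pupil_power(pu)
  .airy_cache[[key]] <- val
  val
}

# scale factor turning raw |E|^2 of this pupil into I_A(0) units
airy_scale <- function(pupil, eom_phase = pupil$eom_phase) {
  1 / (pupil_power(pupil, eom_phase) * airy_reference(pupil$config))
}

# --- PSF stacks -------------------------------------------------------------

grid_coords <- function(n, voxel) ((0:(n - 1)) - (n - 1) / 2) * voxel

#' Compute a 3D vectorial excitation PSF
#'
#' Evaluates the vectorial Debye integral of the pupil on a centered voxel
#' grid (via the chirp-z transform, one transverse plane per z) and returns
#' the intensity normalized to Airy-reference units: the flat-phase PSF of
#' the same configuration and total power has maximum 1, so voxel values are
#' directly interpretable as contrast relative to \eqn{I_A(0)}.
#'
#' @param pupil A [build_pupil()] result.
#' @param grid_shape,voxel_size_nm Override the configuration's focal grid.
#' @param center_nm Center of the evaluation grid (length-3 nm).
#' @param return_field If `TRUE`, attach the complex on/off field
#'   decomposition (for phase re-synthesis) to the result.
#' @param check_extent Warn when the lateral grid does not contain the first
#'   Airy ring (minimum-finding and normalization sanity can degrade on very
#'   small windows).
#' @return An object of class `psf_stack`: list with the 3D `intensity`
#'   array, voxel coordinates `x`, `y`, `z` (nm), and metadata.
#' @examples
#' cfg <- optical_config(pupil_n = 64, grid_shape = c(33, 33, 1),
#'                       voxel_size_nm = 8)
#' psf <- focus_field(build_pupil(cfg, phase_mask("flat")),
#'                    check_extent = FALSE)
#' max(psf$intensity)  # 1 by construction
#' @export
focus_field <- function(pupil, grid_shape = NULL, voxel_size_nm = NULL,
                        center_nm = c(0, 0, 0), return_field = FALSE,
                        check_extent = TRUE) {
  stopifnot(inherits(pupil, "pupil_field"))
  config <- pupil$config
  shape <- as.integer(rep_len(if (is.null(grid_shape)) config$grid_shape
                              else grid_shape, 3L))
  voxel <- rep_len(if (is.null(voxel_size_nm)) config$voxel_size_nm
                   else voxel_size_nm, 3L)
  if (check_extent) {
    airy_r <- 0.61 * config$wavelength_nm / config$na
    half_extent <- (shape[1] - 1) / 2 * voxel[1]
    if (half_extent < airy_r && shape[1] > 1)
      warning(sprintf(paste0("lateral grid half-extent (%.0f nm) does not ",
                             "contain the first Airy ring (%.0f nm)"),
                      half_extent, airy_r))
  }
  xs <- grid_coords(shape[1], voxel[1]) + center_nm[1]
  ys <- grid_coords(shape[2], voxel[2]) + center_nm[2]
  zs <- grid_coords(shape[3], voxel[3]) + center_nm[3]
  kern <- focal_kernels(pupil)
  modes <- field_on_grid(kern, xs, ys, zs)
  scale <- airy_scale(pupil)
  intensity <- modes_intensity(modes, pupil$eom_phase) * scale
  out <- structure(list(intensity = intensity, x = xs, y = ys, z = zs,
                        voxel_size_nm = voxel, config = config,
                        mask = pupil$mask, eom_phase = pupil$eom_phase,
                        polarization = pupil$polarization,
                        airy_scale = scale),
                   class = "psf_stack")
  if (return_field) out$modes <- modes
  out
}

#' Re-synthesize a PSF stack at a different EOM phase
#'
#' Uses the stored on/off field decomposition (requires
#' `focus_field(..., return_field = TRUE)`); no new diffraction computation
#' is performed.
#'
#' @param psf A `psf_stack` carrying its field modes.
#' @param eom_phase New EOM phase in radians.
#' @return A `psf_stack`.
#' @export
psf_at_phase <- function(psf, eom_phase) {
  if (is.null(psf$modes))
    stop("psf_stack carries no field modes; recompute with return_field = TRUE")
  psf$intensity <- modes_intensity(psf$modes, eom_phase) * psf$airy_scale
  psf$eom_phase <- eom_phase
  psf
}

#' @export
print.psf_stack <- function(x, ...) {
  cat(sprintf("psf_stack: %s mask, %s voxels at %s nm, EOM phase %.4g rad\n",
              x$mask$kind, paste(dim(x$intensity), collapse = "x"),
              paste(signif(x$voxel_size_nm, 3), collapse = "x"), x$eom_phase))
  cat(sprintf("  intensity range [%.3g, %.3g] (Airy-reference units)\n",
              min(x$intensity), max(x$intensity)))
  invisible(x)
}
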
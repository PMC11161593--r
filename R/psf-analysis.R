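# Analysis of PSF minima: sub-voxel localization of the intensity minimum,
# EOM-phase-to-displacement calibration, contrast, and scan-quality curves.

# 3-point parabolic interpolation of a discrete minimum; returns position in
# coordinate units. Errors when the minimum sits on the profile boundary.
parabolic_min <- function(coords, values) {
  i <- which.min(values)
  if (i == 1L || i == length(values))
    stop("intensity minimum lies on the grid boundary; enlarge the scan range")
  a <- values[i - 1]; b <- values[i]; c <- values[i + 1]
  denom <- a - 2 * b + c
  off <- if (denom > 0) (a - c) / (2 * denom) else 0
  coords[i] + off * (coords[2] - coords[1])
}

#' Sub-voxel position of a PSF intensity minimum
#'
#' Extracts the profile through the stack center along `axis` and locates
#' the interior minimum by 3-point parabolic interpolation (the voxel grid
#' alone cannot express nm/deg displacement slopes).
#'
#' @param psf A `psf_stack`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Minimum position in nm (sub-voxel).
#' @export
minimum_position <- function(psf, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  d <- dim(psf$intensity)
  ic <- (d + 1L) %/% 2L
  prof <- switch(axis,
                 x = psf$intensity[, ic[2], ic[3]],
                 y = psf$intensity[ic[1], , ic[3]],
                 z = psf$intensity[ic[1], ic[2], ])
  coords <- switch(axis, x = psf$x, y = psf$y, z = psf$z)
  if (length(prof) < 3L) stop("profile too short along ", axis)
  parabolic_min(coords, prof)
}

# Precompute on/off fields along a line through the focus and return a
# closure that finds the sub-voxel minimum position for any EOM phase.
# Cheap to call repeatedly: no diffraction recomputation per phase.
line_minimum_tracker <- function(pupil, axis, span_nm, step_nm = 0.25) {
  kern <- focal_kernels(pupil)
  t <- seq(-span_nm, span_nm, by = step_nm)
  zer <- numeric(length(t))
  lf <- switch(axis,
               x = field_at_points(kern, t, zer, zer),
               y = field_at_points(kern, zer, t, zer),
               z = field_at_points(kern, zer, zer, t))
  sc <- airy_scale(pupil)
  list(coords = t,
       intensity = function(phi) modes_intensity(lf, phi) * sc,
       minimum = function(phi) parabolic_min(t, modes_intensity(lf, phi)))
}

#' Find the EOM phase that places the minimum at a target position
#'
#' Inverts the minimum-position-versus-phase relation of a scanning mask by
#' root finding on a precomputed line profile.
#'
#' @param config An [optical_config()].
#' @param mask A scanning [phase_mask()] (`bisected_x`, `bisected_y`,
#'   `tophat` or `two_beam`).
#' @param target_nm Desired minimum position along the mask's scan axis.
#' @param polarization Input polarization (`NULL`: mask default).
#' @param bracket_deg Search bracket around pi, in degrees.
#' @return EOM phase in radians.
#' @export
phase_for_displacement <- function(config, mask, target_nm,
                                   polarization = NULL, bracket_deg = 26) {
  axis <- mask_axis(mask)
  if (is.na(axis)) stop("mask '", mask$kind, "' has no EOM scan axis")
  pupil <- build_pupil(config, mask, polarization)
  span <- max(60, abs(target_nm) * 2.5 + 60) * (if (axis == "z") 2 else 1)
  trk <- line_minimum_tracker(pupil, axis, span,
                              step_nm = if (axis == "z") 0.5 else 0.25)
  g <- function(phi) tryCatch(trk$minimum(phi) - target_nm,
                              error = function(e) NA_real_)
  # expand the bracket until the target displacement is straddled
  br <- deg2rad(bracket_deg)
  repeat {
    lo <- g(pi - br); hi <- g(pi + br)
    if (is.finite(lo) && is.finite(hi) && lo * hi <= 0) break
    br <- br * 1.6
    if (br > deg2rad(170))
      stop("target displacement ", target_nm,
           " nm is outside the usable EOM scan range")
  }
  stats::uniroot(g, c(pi - br, pi + br), tol = 1e-10)$root
}

#' EOM phase-to-displacement slope of a scanning PSF
#'
#' Simulates the PSF minimum position at EOM phases around pi (default
#' pi +/- 5, 10, 15, 20 degrees), locates each sub-voxel minimum, and fits a
#' line through displacement versus phase. The returned slope is the
#' magnitude in nm per degree of EOM phase; `direction` records the sign of
#' the displacement (along the mask's scan axis, with positive x/y/z as laid
#' out by [focus_field()]) per positive phase increment. An EOM phase
#' instability of d degrees therefore translates directly into a
#' localization bias of `slope * d` nm.
#'
#' @param config An [optical_config()].
#' @param mask A scanning [phase_mask()] (bisected for lateral, tophat for
#'   axial).
#' @param phase_offsets_deg Phase offsets from pi at which the minimum is
#'   tracked.
#' @param polarization Input polarization (`NULL`: mask default).
#' @return List with `slope_nm_per_deg` (magnitude), `direction` (+1/-1),
#'   `axis`, and the per-phase `fit` data frame.
#' @examples
#' \donttest{
#' cfg <- optical_config(pupil_n = 96)
#' phase_to_displacement(cfg, phase_mask("bisected_x"))$slope_nm_per_deg
#' }
#' @export
phase_to_displacement <- function(config, mask,
                                  phase_offsets_deg = c(-20, -15, -10, -5,
                                                        5, 10, 15, 20),
                                  polarization = NULL) {
  axis <- mask_axis(mask)
  if (is.na(axis)) stop("mask '", mask$kind, "' has no EOM scan axis")
  pupil <- build_pupil(config, mask, polarization)
  span <- max(abs(phase_offsets_deg)) * (if (axis == "z") 4.5 else 1.8) + 40
  trk <- line_minimum_tracker(pupil, axis, span,
                              step_nm = if (axis == "z") 0.5 else 0.25)
  disp <- vapply(phase_offsets_deg,
                 function(d) trk$minimum(pi + deg2rad(d)), numeric(1))
  ord <- order(phase_offsets_deg)
  dd <- diff(disp[ord])
  if (any(dd > 0) && any(dd < 0))
    stop("minimum displacement is not monotonic in the EOM phase over the window")
  fit <- stats::lm(disp ~ deg, data.frame(deg = phase_offsets_deg, disp = disp))
  slope <- unname(stats::coef(fit)[2])
  list(slope_nm_per_deg = abs(slope),
       direction = sign(slope),
       axis = axis,
       fit = data.frame(phase_offset_deg = phase_offsets_deg,
                        displacement_nm = disp))
}

#' PSF contrast relative to the Airy reference
#'
#' The intensity at the pattern minimum divided by the maximum
#' \eqn{I_A(0)} of a flat-phase Airy PSF of equal summed intensity. Since
#' `psf_stack` intensities are already expressed in \eqn{I_A(0)} units,
#' this is simply the central-voxel value (for the symmetric patterns at an
#' EOM phase of pi, the minimum lies at the center; for a flat mask the
#' "minimum" is the reference maximum itself and the contrast is 1).
#'
#' @param psf A `psf_stack`.
#' @param search If `TRUE`, return the smallest voxel value of the stack
#'   instead of the central value (use when the minimum is displaced).
#' @return Dimensionless contrast fraction (0 = perfect zero).
#' @export
psf_contrast <- function(psf, search = FALSE) {
  if (search) return(min(psf$intensity))
  d <- dim(psf$intensity)
  ic <- (d + 1L) %/% 2L
  psf$intensity[ic[1], ic[2], ic[3]]
}

#' Contrast and steepness along the EOM scan range
#'
#' For each requested displacement of the PSF minimum, finds the EOM phase
#' that realizes it, then reports the contrast (minimum intensity in
#' \eqn{I_A(0)} units) and the local quadratic steepness of the intensity
#' around the minimum (curvature of a parabola fit across +/- `fit_halfwidth`
#' points, in \eqn{I_A(0)} units per nm^2). Displacements that exceed the
#' usable scan range (minimum no longer bracketed) truncate the table with a
#' warning.
#'
#' @param config An [optical_config()].
#' @param mask A scanning [phase_mask()].
#' @param displacements_nm Displacements of the minimum to probe.
#' @param polarization Input polarization (`NULL`: mask default).
#' @param bracket_deg Phase search bracket around pi (degrees).
#' @return `data.frame(displacement_nm, eom_phase_deg, contrast, steepness)`.
#' @export
scan_quality_curves <- function(config, mask, displacements_nm,
                                polarization = NULL, bracket_deg = 80) {
  axis <- mask_axis(mask)
  if (is.na(axis)) stop("mask '", mask$kind, "' has no EOM scan axis")
  pupil <- build_pupil(config, mask, polarization)
  span <- max(abs(displacements_nm)) + 220
  step <- if (axis == "z") 1 else 0.5
  trk <- line_minimum_tracker(pupil, axis, span, step_nm = step)
  rows <- lapply(displacements_nm, function(d) {
    phi <- tryCatch(
      stats::uniroot(function(p) trk$minimum(p) - d,
                     pi + deg2rad(c(-bracket_deg, bracket_deg)),
                     tol = 1e-9)$root,
      error = function(e) NA_real_)
    if (is.na(phi)) return(NULL)
    ii <- trk$intensity(phi)
    im <- which.min(ii)
    hw <- 6L
    if (im <= hw || im > length(ii) - hw) return(NULL)
    sel <- (im - hw):(im + hw)
    pfit <- stats::lm(y ~ poly(t, 2, raw = TRUE),
                      data.frame(t = trk$coords[sel], y = ii[sel]))
    data.frame(displacement_nm = d,
               eom_phase_deg = rad2deg(phi),
               contrast = min(ii),
               steepness = unname(stats::coef(pfit)[3]))
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!all(keep))
    warning("scan range exceeded for ",
            paste(displacements_nm[!keep], collapse = ", "),
            " nm; table truncated")
  do.call(rbind, rows[keep])
}
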
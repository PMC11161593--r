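# Pupil sampling and construction of the complex pupil field.
#
# The pupil is sampled on an n x n Cartesian grid of direction sines
# s = (sx, sy) with |s| <= smax = NA/n_medium; the radial pupil coordinate
# in mm is r = |s|/smax * aperture_radius (sine condition). n is even and
# the grid is centered with a half-pixel offset, so no sample falls exactly
# on a bisecting phase boundary or on the optical axis.

pupil_grid <- function(config) {
  n <- config$pupil_n
  smax <- config$na / config$refractive_index
  ds <- 2 * smax / (n - 1)
  s1 <- ((0:(n - 1)) - (n - 1) / 2) * ds
  sx <- matrix(s1, n, n)
  sy <- matrix(s1, n, n, byrow = TRUE)
  sr <- sqrt(sx^2 + sy^2)
  list(n = n, smax = smax, ds = ds, s1 = s1, sx = sx, sy = sy, sr = sr)
}

# one-pixel antialiased edge: 1 inside, 0 outside, linear ramp across the edge
soft_edge <- function(r, r_edge, width) {
  pmin(pmax((r_edge - r) / width + 0.5, 0), 1)
}

# Illumination amplitude over the pupil (before the phase mask), clipped by
# the aperture.
beam_amplitude <- function(config, g) {
  ap_radius_mm <- config$aperture_diameter_mm / 2
  r_mm <- g$sr / g$smax * ap_radius_mm
  amp <- soft_edge(g$sr, g$smax, g$ds)       # aperture clip
  if (config$beam_profile == "gaussian") {
    w <- config$beam_diameter_mm / 2
    amp <- amp * exp(-(r_mm / w)^2)
  } else {
    beam_r <- config$beam_diameter_mm / 2
    dr_mm <- g$ds / g$smax * ap_radius_mm
    amp <- amp * soft_edge(r_mm, beam_r, dr_mm)
  }
  amp
}

#' Build the complex pupil field for a phase mask
#'
#' Assembles the pupil-plane amplitude (beam profile clipped by the
#' aperture), the mask phase, and the uniform input polarization. The pupil
#' is stored split into its EOM-switchable part (`amp_on`, the pixels that
#' carry the variable phase \eqn{e^{i\varphi}}) and the static part
#' (`amp_off`), so that PSFs at any EOM phase can be synthesized from a
#' single diffraction computation:
#' \eqn{E(\mathbf{r};\varphi) = E_\mathrm{off}(\mathbf{r}) +
#'      e^{i\varphi} E_\mathrm{on}(\mathbf{r})}.
#'
#' @param config An [optical_config()].
#' @param mask A [phase_mask()].
#' @param polarization A `polarization_state`, or `NULL` for the mask's
#'   default (boundary-parallel linear for bisected masks, circular for
#'   tophat/vortex).
#' @param eom_phase EOM phase \eqn{\varphi} in radians applied to the
#'   `on` region (default `pi`, the symmetric pattern).
#' @return An object of class `pupil_field`.
#' @examples
#' pu <- build_pupil(optical_config(pupil_n = 64), phase_mask("bisected_x"))
#' pupil_power(pu)
#' @export
build_pupil <- function(config, mask, polarization = NULL, eom_phase = pi) {
  stopifnot(inherits(config, "optical_config"), inherits(mask, "phase_mask"))
  if (is.null(polarization)) polarization <- default_polarization(mask)
  stopifnot(inherits(polarization, "polarization_state"))
  g <- pupil_grid(config)
  amp <- beam_amplitude(config, g)
  zero <- matrix(0, g$n, g$n)
  on_w <- zero   # graded membership of the EOM-phase region, in [0, 1]
  amp_off <- amp * (1 + 0i)
  amp_on <- zero * (0 + 0i)
  if (mask$kind %in% c("bisected_x", "bisected_y")) {
    s_perp <- if (mask$kind == "bisected_x") g$sx else g$sy
    on_w <- soft_edge(-s_perp, 0, g$ds)  # s_perp > 0 half carries the phase
    amp_on <- amp * on_w
    amp_off <- amp * (1 - on_w)
  } else if (mask$kind == "tophat") {
    r_in <- mask$tophat_radius_frac * g$smax
    on_w <- soft_edge(g$sr, r_in, g$ds)
    amp_on <- amp * on_w
    amp_off <- amp * (1 - on_w)
  } else if (mask$kind == "vortex") {
    amp_off <- amp * exp(1i * atan2(g$sy, g$sx))
    amp_on <- zero * (0 + 0i)
  } else if (mask$kind == "two_beam") {
    ap_radius_mm <- config$aperture_diameter_mm / 2
    x_mm <- g$sx / g$smax * ap_radius_mm
    y_mm <- g$sy / g$smax * ap_radius_mm
    w <- mask$beam_diameter_mm / 2
    clip <- soft_edge(g$sr, g$smax, g$ds)
    g1 <- clip * exp(-((x_mm + mask$beam_offset_mm)^2 + y_mm^2) / w^2)
    g2 <- clip * exp(-((x_mm - mask$beam_offset_mm)^2 + y_mm^2) / w^2)
    amp_off <- g1 * (1 + 0i)
    # at an EOM phase of pi the beams differ by exactly `relative_phase`
    amp_on <- g2 * exp(1i * (mask$relative_phase - pi))
  }
  structure(list(config = config, mask = mask,
                 polarization = unclass(polarization),
                 eom_phase = eom_phase,
                 grid = g, amp_on = amp_on, amp_off = amp_off),
            class = "pupil_field")
}

#' Total pupil power of a pupil field
#'
#' Integrated pupil intensity \eqn{\sum |A_\mathrm{off} + e^{i\varphi}
#' A_\mathrm{on}|^2} (in pupil-pixel units) at the pupil's EOM phase. For
#' masks with disjoint on/off regions this is independent of the phase; for
#' overlapping two-beam pupils it is not.
#'
#' @param pupil A `pupil_field`.
#' @param eom_phase Phase override (radians); default: the pupil's phase.
#' @return Scalar power (arbitrary units, consistent across masks for a
#'   given configuration).
#' @export
pupil_power <- function(pupil, eom_phase = pupil$eom_phase) {
  sum(Mod(pupil$amp_off + exp(1i * eom_phase) * pupil$amp_on)^2) *
    pol_intensity(pol_state(pupil$polarization[1], pupil$polarization[2]))
}

#' @export
print.pupil_field <- function(x, ...) {
  cat(sprintf("pupil_field: %s mask, %d x %d samples, EOM phase %.4g rad\n",
              x$mask$kind, x$grid$n, x$grid$n, x$eom_phase))
  invisible(x)
}
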
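#' Optical configuration of the focusing system
#'
#' Physical parameters of the objective and illumination used by the
#' vectorial PSF engine. Defaults describe a 100x / NA 1.35 silicone-oil
#' objective (aperture diameter 6.5 mm, immersion index 1.406) illuminated
#' at 635 nm by a flat beam of 7.0 mm diameter, sampled at 2 nm voxels.
#'
#' @param na Numerical aperture (must be below `refractive_index`).
#' @param refractive_index Index of the immersion/mounting medium.
#' @param wavelength_nm Vacuum wavelength in nm.
#' @param aperture_diameter_mm Back-aperture diameter in mm.
#' @param beam_diameter_mm Illumination beam diameter in mm (for
#'   `beam_profile = "gaussian"` this is the 1/e^2 intensity diameter).
#' @param beam_profile `"flat"` or `"gaussian"`.
#' @param voxel_size_nm Focal-space sampling in nm (scalar or length 3 for
#'   x/y/z).
#' @param grid_shape Focal grid size in voxels per axis (odd, so a center
#'   voxel exists); scalar or length 3.
#' @param pupil_n Pupil sampling (points across the aperture diameter).
#' @return An object of class `optical_config`.
#' @examples
#' optical_config()                      # the default high-NA system
#' optical_config(na = 0.15, pupil_n = 64)
#' @export
optical_config <- function(na = 1.35,
                           refractive_index = 1.406,
                           wavelength_nm = 635,
                           aperture_diameter_mm = 6.5,
                           beam_diameter_mm = 7.0,
                           beam_profile = c("flat", "gaussian"),
                           voxel_size_nm = 2,
                           grid_shape = 65L,
                           pupil_n = 128L) {
  beam_profile <- match.arg(beam_profile)
  if (!is.finite(na) || na <= 0) stop("invalid 'na'")
  if (na >= refractive_index)
    stop("numerical aperture must be smaller than the refractive index")
  if (wavelength_nm <= 0) stop("invalid 'wavelength_nm'")
  if (any(voxel_size_nm <= 0)) stop("invalid 'voxel_size_nm'")
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape %% 2L == 0L))
    stop("'grid_shape' must be odd in each axis so that a center voxel exists")
  voxel_size_nm <- rep_len(voxel_size_nm, 3L)
  structure(list(na = na, refractive_index = refractive_index,
                 wavelength_nm = wavelength_nm,
                 aperture_diameter_mm = aperture_diameter_mm,
                 beam_diameter_mm = beam_diameter_mm,
                 beam_profile = beam_profile,
                 voxel_size_nm = voxel_size_nm,
                 grid_shape = grid_shape,
                 pupil_n = as.integer(pupil_n)),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("optical_config: NA %.3g / n %.4g, lambda %g nm\n",
              x$na, x$refractive_index, x$wavelength_nm))
  cat(sprintf("  aperture %g mm, %s beam %g mm; voxel %s nm, grid %s, pupil %d\n",
              x$aperture_diameter_mm, x$beam_profile, x$beam_diameter_mm,
              paste(x$voxel_size_nm, collapse = "x"),
              paste(x$grid_shape, collapse = "x"), x$pupil_n))
  invisible(x)
}

#' Pupil-plane phase masks
#'
#' Describes the binary (or continuous) phase pattern imposed on the pupil.
#' Supported kinds:
#' \describe{
#'   \item{`flat`}{no pattern; the reference Airy PSF.}
#'   \item{`bisected_x` / `bisected_y`}{the aperture is split along a
#'     straight line through the center (the phase boundary lies along y
#'     resp. x); the half carrying the EOM phase interferes with the other
#'     half to form a bilobed PSF whose line minimum scans along x resp. y.}
#'   \item{`tophat`}{an inner disc (radius `tophat_radius_frac` of the
#'     aperture radius, default `1/sqrt(2)` for equal-energy halves under
#'     flat illumination) carries the EOM phase; at a phase of pi this
#'     yields the '3D donut' with an axial minimum.}
#'   \item{`vortex`}{continuous azimuthal phase ramp (lateral donut); has no
#'     EOM-switchable region.}
#'   \item{`two_beam`}{two offset Gaussian beams, the second carrying the
#'     EOM phase plus a static `relative_phase`; models interferometric
#'     MINFLUX excitation.}
#' }
#'
#' @param kind One of `"flat"`, `"bisected_x"`, `"bisected_y"`, `"tophat"`,
#'   `"vortex"`, `"two_beam"`.
#' @param tophat_radius_frac Inner-disc radius as a fraction of the aperture
#'   radius.
#' @param beam_diameter_mm,beam_offset_mm,relative_phase `two_beam`
#'   parameters: 1/e^2 beam diameter, center offset along x (both mm), and
#'   the static relative phase (radians) between the beams reached at an EOM
#'   phase of pi.
#' @return An object of class `phase_mask`.
#' @examples
#' phase_mask("bisected_x")
#' phase_mask("tophat", tophat_radius_frac = 0.7)
#' @export
phase_mask <- function(kind = c("flat", "bisected_x", "bisected_y", "tophat",
                                "vortex", "two_beam"),
                       tophat_radius_frac = 1 / sqrt(2),
                       beam_diameter_mm = 2.3,
                       beam_offset_mm = 2.3,
                       relative_phase = pi) {
  kind <- match.arg(kind)
  if (kind == "tophat" &&
      (tophat_radius_frac <= 0 || tophat_radius_frac >= 1))
    stop("'tophat_radius_frac' must lie in (0, 1)")
  structure(list(kind = kind,
                 tophat_radius_frac = tophat_radius_frac,
                 beam_diameter_mm = beam_diameter_mm,
                 beam_offset_mm = beam_offset_mm,
                 relative_phase = relative_phase),
            class = "phase_mask")
}

# Default input polarization per mask: linear parallel to the phase boundary
# for bisected masks, circular for tophat and vortex (the axial/lateral
# donuts need circular polarization for a symmetric zero), linear otherwise.
default_polarization <- function(mask) {
  switch(mask$kind,
         bisected_x = pol_linear(90),
         bisected_y = pol_linear(0),
         tophat = pol_circular("left"),
         vortex = pol_circular("left"),
         two_beam = pol_linear(90),
         pol_linear(0))
}

#' Scan-axis of a phase mask
#'
#' The focal axis along which the EOM phase displaces the PSF minimum.
#'
#' @param mask A [phase_mask()].
#' @return `"x"`, `"y"` or `"z"` (or `NA` for masks without a scan axis).
#' @export
mask_axis <- function(mask) {
  switch(mask$kind,
         bisected_x = "x", two_beam = "x",
         bisected_y = "y",
         tophat = "z",
         NA_character_)
}
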
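#' Jones vector of a polarization state
#'
#' Represents the transverse electric field as a complex two-vector
#' \eqn{(E_h, E_v)} in the horizontal/vertical laboratory frame. Global phase
#' factors carry no physical meaning here; only intensities (squared norms)
#' are contractual.
#'
#' @param e_h Complex amplitude of the horizontal component.
#' @param e_v Complex amplitude of the vertical component.
#' @return An object of class `polarization_state` (a complex length-2
#'   vector with names `h` and `v`).
#' @examples
#' pol_state(1, 0)                   # horizontal
#' pol_linear(45)                    # diagonal, (1, 1)/sqrt(2)
#' pol_intensity(pol_linear(45))     # 1
#' @export
pol_state <- function(e_h, e_v) {
  v <- complex(real = c(Re(e_h), Re(e_v)), imaginary = c(Im(e_h), Im(e_v)))
  if (any(!is.finite(Re(v))) || any(!is.finite(Im(v))))
    stop("polarization amplitudes must be finite")
  names(v) <- c("h", "v")
  class(v) <- "polarization_state"
  v
}

#' @rdname pol_state
#' @param angle_deg Orientation of the linear polarization in degrees,
#'   counterclockwise from horizontal.
#' @param amplitude Overall field amplitude \eqn{E_0}.
#' @export
pol_linear <- function(angle_deg, amplitude = 1) {
  a <- deg2rad(angle_deg)
  pol_state(amplitude * cos(a), amplitude * sin(a))
}

#' @rdname pol_state
#' @param handedness `"left"` or `"right"`.
#' @export
pol_circular <- function(handedness = c("left", "right"), amplitude = 1) {
  handedness <- match.arg(handedness)
  s <- if (handedness == "left") 1i else -1i
  pol_state(amplitude / sqrt(2), s * amplitude / sqrt(2))
}

#' @rdname pol_state
#' @param state A `polarization_state`.
#' @export
pol_intensity <- function(state) {
  sum(Mod(unclass(state))^2)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Optical elements of the phase-plate chain
#'
#' `retarder()` describes a wave plate (half-wave plate, EOM, or the
#' birefringent 'on'-pixels of a ferroelectric SLM) with phase delay
#' \eqn{\varphi} between its slow and fast axes and axis orientation
#' \eqn{\alpha} from horizontal. `polarizer()` describes an ideal linear
#' polarizer. Angles are taken in degrees at this interface and stored in
#' radians.
#'
#' @param phase_delay_deg Retardance in degrees (180 for a half-wave plate).
#' @param axis_deg Orientation of the birefringent (or transmission) axis in
#'   degrees, counterclockwise from horizontal.
#' @return An object of class `jones_element`.
#' @examples
#' retarder(180, 45)       # ideal SLM on-pixel
#' eom(90)                 # EOM at quarter-wave drive
#' polarizer(0)            # horizontal polarizer
#' @export
retarder <- function(phase_delay_deg, axis_deg = 0) {
  stopifnot(is.finite(phase_delay_deg), is.finite(axis_deg))
  structure(list(type = "retarder",
                 phase_delay = deg2rad(phase_delay_deg),
                 axis = deg2rad(axis_deg)),
            class = "jones_element")
}

#' @rdname retarder
#' @details `eom()` is a retarder with a vertical birefringent axis: its
#'   Jones matrix is `diag(1, exp(1i * phi))`, i.e. the EOM phase is carried
#'   by the vertical component.
#' @export
eom <- function(phase_delay_deg) retarder(phase_delay_deg, 0)

#' @rdname retarder
#' @export
polarizer <- function(axis_deg = 0) {
  stopifnot(is.finite(axis_deg))
  structure(list(type = "polarizer", axis = deg2rad(axis_deg)),
            class = "jones_element")
}

#' Jones matrix of an optical element
#'
#' For a retarder with phase delay \eqn{\varphi} and axis angle
#' \eqn{\alpha}:
#' \deqn{W(\varphi,\alpha)=\begin{pmatrix}
#'   \cos^2\alpha + e^{i\varphi}\sin^2\alpha &
#'   (1-e^{i\varphi})\cos\alpha\sin\alpha\\
#'   (1-e^{i\varphi})\cos\alpha\sin\alpha &
#'   \sin^2\alpha + e^{i\varphi}\cos^2\alpha\end{pmatrix}}
#' up to an irrelevant global phase; at \eqn{\alpha=0} this reduces to
#' `diag(1, exp(1i*phi))`. The matrix is unitary (lossless). A polarizer
#' yields the idempotent projector onto its transmission axis.
#'
#' @param element A `jones_element`.
#' @return A 2x2 complex matrix.
#' @export
jones_matrix <- function(element) {
  stopifnot(inherits(element, "jones_element"))
  a <- element$axis
  c2 <- cos(a)^2; s2 <- sin(a)^2; cs <- cos(a) * sin(a)
  if (element$type == "retarder") {
    e <- exp(1i * element$phase_delay)
    matrix(c(c2 + e * s2, (1 - e) * cs,
             (1 - e) * cs, s2 + e * c2), 2, 2)
  } else {
    matrix(c(c2, cs, cs, s2), 2, 2)
  }
}

#' Propagate a polarization state through a chain of elements
#'
#' Applies the elements in beam order (first element of `chain` is hit
#' first), i.e. the output is `J_n ... J_2 J_1 x`.
#'
#' @param chain A list of `jones_element` objects (see [retarder()],
#'   [polarizer()]), or a single element.
#' @param input A `polarization_state`.
#' @return The output `polarization_state`.
#' @examples
#' # ideal variable phase plate, on-pixels: EOM phase ends up on the output
#' out <- propagate(list(eom(90), retarder(180, 45), polarizer(0)),
#'                  pol_linear(45))
#' pol_intensity(out)  # 1/2
#' @export
propagate <- function(chain, input) {
  if (inherits(chain, "jones_element")) chain <- list(chain)
  if (length(chain) == 0L) stop("empty element chain")
  stopifnot(inherits(input, "polarization_state"))
  v <- unclass(input)
  for (el in chain) v <- drop(jones_matrix(el) %*% v)
  pol_state(v[1], v[2])
}

#' Two-beam interference intensity of the variable phase plate
#'
#' For the ideal chain the 'off'- and 'on'-pixel output fields are equal in
#' amplitude and differ by the EOM phase \eqn{\varphi}; interfering them near
#' focus gives \eqn{I = E_0^2 (1 + \cos(\varphi - \xi))}, where \eqn{\xi} is
#' the position-dependent extra phase between the two pupil parts.
#'
#' @param phi EOM phase in radians.
#' @param xi Position-dependent phase difference in radians.
#' @param e0 Field amplitude \eqn{E_0}.
#' @return Intensity (dimensionless, `e0^2` units).
#' @export
interference_intensity <- function(phi, xi = 0, e0 = 1) {
  e0^2 * (1 + cos(phi - xi))
}

#' SLM imperfection parameters
#'
#' Deviations of the binary SLM 'on'-pixels from an ideal half-wave plate at
#' 45 degrees: a retardance error and an axis error. The ferroelectric SLM
#' modeled here has its on-pixel axis at 33.5 degrees, i.e.
#' `delta_axis_deg = -11.5`.
#'
#' @param delta_phase_deg Retardance deviation from 180 degrees.
#' @param delta_axis_deg Axis deviation from 45 degrees.
#' @return An object of class `slm_imperfection`.
#' @export
slm_imperfection <- function(delta_phase_deg = 0, delta_axis_deg = 0) {
  if (abs(delta_phase_deg) >= 90 || abs(delta_axis_deg) >= 45)
    stop("imperfection outside model validity range (|dphi| < 90 deg, |dalpha| < 45 deg)")
  structure(list(delta_phase = deg2rad(delta_phase_deg),
                 delta_axis = deg2rad(delta_axis_deg)),
            class = "slm_imperfection")
}

# Residual interference intensity |E_off + E_on|^2 after the polarizer for
# a realistic chain with compensation HWP at `alpha` and EOM phase `phi`.
# Input is the 45-degree beam with unit intensity. Element-by-element
# propagate() version; used for cross-checks against the vectorized form.
.chain_residual <- function(alpha_rad, phi_rad, imp) {
  e_in <- pol_linear(45)
  pre <- list(eom(rad2deg(phi_rad)), retarder(180, rad2deg(alpha_rad)))
  e_mid <- propagate(pre, e_in)
  slm_on <- retarder(180 + rad2deg(imp$delta_phase), 45 + rad2deg(imp$delta_axis))
  p <- polarizer(0)
  e_on <- propagate(list(slm_on, p), e_mid)
  e_off <- propagate(p, e_mid)
  tot <- unclass(e_on) + unclass(e_off)
  sum(Mod(tot)^2)
}

# Vectorized closed form of the same residual (alpha, phi recycled):
# E_mid = W(pi, alpha) diag(1, e^{i phi}) (1,1)/sqrt(2); the horizontal
# output is E_mid[1] (off) plus the first row of W_SLM applied to E_mid (on).
.chain_residual_vec <- function(alpha, phi, imp) {
  eh <- 1 / sqrt(2)
  ev <- exp(1i * phi) / sqrt(2)
  e <- exp(1i * pi)  # HWP
  c2 <- cos(alpha)^2; s2 <- sin(alpha)^2; cs <- cos(alpha) * sin(alpha)
  mh <- (c2 + e * s2) * eh + (1 - e) * cs * ev
  mv <- (1 - e) * cs * eh + (s2 + e * c2) * ev
  as <- pi / 4 + imp$delta_axis
  es <- exp(1i * (pi + imp$delta_phase))
  c2s <- cos(as)^2; s2s <- sin(as)^2; css <- cos(as) * sin(as)
  on_h <- (c2s + es * s2s) * mh + (1 - es) * css * mv
  Mod(mh + on_h)^2
}

#' Compensate SLM imperfections with a half-wave plate
#'
#' Finds the compensation half-wave-plate angle \eqn{\alpha} and the static
#' EOM phase offset \eqn{\varphi} that minimize the summed on+off field
#' intensity after the polarizer (the interference minimum of the phase
#' plate). A coarse deterministic grid scan over
#' \eqn{\alpha \in [0, \pi)}, \eqn{\varphi \in [0, 2\pi)} is followed by
#' Nelder-Mead refinement, guaranteeing the global minimum of this smooth
#' two-parameter landscape. For any imperfection in the validity range the
#' residual can be driven to zero within numerical precision, i.e. the HWP
#' fully compensates both retardance and axis errors of the SLM.
#'
#' @param imperfection An [slm_imperfection()].
#' @param tolerance Residual intensity (relative to the input intensity)
#'   above which the result is flagged as not converged.
#' @param grid_n Number of coarse grid points per parameter.
#' @return An object of class `slm_compensation`: a list with `hwp_angle_deg`,
#'   `eom_offset_deg`, `residual_intensity` and `converged`. Failure to reach
#'   `tolerance` is reported in `converged`, not raised as an error, so that
#'   residual landscapes can be mapped.
#' @examples
#' compensate_slm(slm_imperfection(0, -11.5))$residual_intensity  # ~ 0
#' @export
compensate_slm <- function(imperfection, tolerance = 1e-9, grid_n = 181L) {
  stopifnot(inherits(imperfection, "slm_imperfection"))
  alphas <- seq(0, pi, length.out = grid_n + 1L)[seq_len(grid_n)]
  phis <- seq(0, 2 * pi, length.out = 2L * grid_n + 1L)[seq_len(2L * grid_n)]
  res <- outer(alphas, phis,
               function(a, p) .chain_residual_vec(a, p, imperfection))
  ij <- arrayInd(which.min(res), dim(res))
  fn <- function(x) .chain_residual_vec(x[1], x[2], imperfection)
  refine <- function(start) {
    opt <- stats::optim(start, fn, method = "Nelder-Mead",
                        control = list(reltol = 1e-16, maxit = 2000))
    # polish: Nelder-Mead near a quadratic zero stalls around sqrt(eps)
    opt2 <- stats::optim(opt$par, fn, method = "BFGS",
                         control = list(reltol = 1e-16))
    if (opt2$value < opt$value) opt2 else opt
  }
  # the landscape can hold several exact zeros (for an ideal SLM e.g. HWP
  # at 0 with EOM offset 0, and HWP at 45 deg with offset pi); refine from
  # the grid optimum and from the nominal configuration, and break
  # residual ties toward the nominal one (HWP at the ideal 45-degree SLM
  # axis, offset pi) with a penalty far below any physical residual
  cands <- list(refine(c(alphas[ij[1]], phis[ij[2]])),
                refine(c(pi / 4, pi)))
  score <- vapply(cands, function(o)
    o$value + 1e-9 * sum((o$par - c(pi / 4, pi))^2), numeric(1))
  opt <- cands[[which.min(score)]]
  structure(list(hwp_angle_deg = rad2deg(opt$par[1]) %% 180,
                 eom_offset_deg = rad2deg(opt$par[2]) %% 360,
                 residual_intensity = opt$value,
                 converged = opt$value < tolerance),
            class = "slm_compensation")
}

#' @export
print.slm_compensation <- function(x, ...) {
  cat(sprintf("SLM compensation: HWP at %.4f deg, EOM offset %.4f deg\n",
              x$hwp_angle_deg, x$eom_offset_deg))
  cat(sprintf("  residual intensity %.3g (converged: %s)\n",
              x$residual_intensity, x$converged))
  invisible(x)
}

#' Polarization rotation limits of a non-ideal half-wave element
#'
#' A half-wave retarder with its axis at angle \eqn{\alpha} reflects a linear
#' polarization about that axis, so the largest rotation it can impart to a
#' linear input is \eqn{2\alpha}. `halfwave_rotation()` computes the actual
#' rotation of a given linear input through the Jones matrix;
#' `max_rotation_angle()` returns the limit \eqn{2\alpha};
#' `polarization_deviation()` returns the best-case symmetric deviation
#' \eqn{(90 - 2\alpha)/2} from the two orthogonal boundary-parallel
#' polarizations required by the x and y phase patterns when a single
#' rotator must serve both (the double-reflection scheme).
#'
#' @param axis_deg Axis angle of the half-wave element in degrees.
#' @param input_deg Orientation of the linear input polarization in degrees.
#' @return Angle in degrees.
#' @examples
#' halfwave_rotation(33.5)      # 67: the SLM can rotate by at most 67 deg
#' polarization_deviation(33.5) # 11.5 deg short of the optimal polarization
#' @export
halfwave_rotation <- function(axis_deg, input_deg = 0) {
  out <- propagate(retarder(180, axis_deg), pol_linear(input_deg))
  v <- unclass(out)
  # output of a half-wave plate on linear input is linear: extract its angle
  ph <- Arg(v[which.max(Mod(v))])
  vr <- Re(v * exp(-1i * ph))
  ang <- rad2deg(atan2(vr[2], vr[1]))
  rot <- (ang - input_deg) %% 360
  if (rot > 180) rot <- rot - 360
  unname(abs(rot) %% 180)
}

#' @rdname halfwave_rotation
#' @export
max_rotation_angle <- function(axis_deg) {
  stopifnot(axis_deg >= 0, axis_deg <= 90)
  2 * axis_deg
}

#' @rdname halfwave_rotation
#' @export
polarization_deviation <- function(axis_deg) {
  stopifnot(axis_deg >= 0, axis_deg <= 45)
  (90 - 2 * axis_deg) / 2
}
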
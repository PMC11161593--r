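# MINFLUX scan patterns, probe intensities, Fisher information and
# Cramer-Rao bounds.
#
# A scan pattern is a set of K probe exposures. Each probe is a PSF (mask +
# polarization) whose minimum is placed either by the EOM phase (the
# physically faithful scan of the variable phase plate) or by a rigid
# displacement r_i of the whole PSF (the conventional beam-scanning model,
# evaluated exactly as I(r_E - r_i), no interpolation). From the probe
# intensities I_i(r_E) (plus the background offset b * I_A(0)) follow the
# multinomial probabilities p_i = I_i / sum_j I_j, the Fisher matrix
#
#   J(r_E) = N sum_i (1/p_i) grad(p_i) grad(p_i)^T
#
# with gradients taken as central finite differences of one voxel, and the
# CRB covariance J^{-1}. Reported precisions are dimension-averaged and
# normalized to a single photon: sigma_1 = sigma * sqrt(N).

new_probe <- function(mask, polarization = NULL, eom_phase = NULL,
                      target_nm = NULL, shift = c(0, 0, 0)) {
  list(mask = mask, polarization = polarization, eom_phase = eom_phase,
       target_nm = target_nm, shift = shift)
}

#' MINFLUX scan patterns
#'
#' `minflux_pattern()` builds the sequential per-axis pattern of the
#' variable phase plate: for each localized dimension, one scanning mask
#' (bisected x / bisected y for lateral, top-hat for axial) probed with its
#' minimum at `positions_per_axis` points spanning the scan range (diameter
#' `L_nm` laterally, `Lz_nm` axially), scanned via the EOM phase.
#' `donut_pattern()` builds conventional beam-displacement patterns from a
#' single donut PSF: the lateral (vortex) donut at a center point plus
#' points on a circle of diameter `L_nm`, and for 3D the top-hat donut
#' additionally displaced axially by +/- `Lz_nm / 2`.
#'
#' @param dims 2 or 3 localized dimensions.
#' @param L_nm Lateral scan-pattern diameter (nm).
#' @param Lz_nm Axial scan-pattern diameter (nm).
#' @param positions_per_axis Number of probe positions per axis (>= 2).
#' @param tophat_radius_frac Passed to the top-hat [phase_mask()].
#' @return An object of class `scan_pattern`.
#' @examples
#' minflux_pattern(2, L_nm = 50)
#' minflux_pattern(3, L_nm = 50, Lz_nm = 150)
#' @export
minflux_pattern <- function(dims = 2, L_nm = 50, Lz_nm = 150,
                            positions_per_axis = 3L,
                            tophat_radius_frac = 1 / sqrt(2)) {
  stopifnot(dims %in% c(1, 2, 3), positions_per_axis >= 2L)
  pos_l <- seq(-L_nm / 2, L_nm / 2, length.out = positions_per_axis)
  probes <- lapply(pos_l, function(d) new_probe(phase_mask("bisected_x"),
                                                target_nm = d))
  if (dims >= 2)
    probes <- c(probes, lapply(pos_l, function(d)
      new_probe(phase_mask("bisected_y"), target_nm = d)))
  if (dims >= 3) {
    pos_z <- seq(-Lz_nm / 2, Lz_nm / 2, length.out = positions_per_axis)
    probes <- c(probes, lapply(pos_z, function(d)
      new_probe(phase_mask("tophat", tophat_radius_frac = tophat_radius_frac),
                target_nm = d)))
  }
  structure(list(probes = probes, dims = dims, L_nm = L_nm, Lz_nm = Lz_nm,
                 probing = "eom"),
            class = "scan_pattern")
}

#' @rdname minflux_pattern
#' @param n_circle Number of displaced lateral probes on the circle.
#' @export
donut_pattern <- function(dims = 2, L_nm = 50, Lz_nm = 150, n_circle = 3L,
                          tophat_radius_frac = 1 / sqrt(2)) {
  stopifnot(dims %in% c(2, 3), n_circle >= 2L)
  mask <- if (dims == 2) phase_mask("vortex")
          else phase_mask("tophat", tophat_radius_frac = tophat_radius_frac)
  ang <- 2 * pi * (seq_len(n_circle) - 1) / n_circle
  probes <- c(list(new_probe(mask)),
              lapply(ang, function(a)
                new_probe(mask, shift = c(cos(a), sin(a), 0) * L_nm / 2)))
  if (dims == 3)
    probes <- c(probes,
                lapply(c(-1, 1), function(s)
                  new_probe(mask, shift = c(0, 0, s * Lz_nm / 2))))
  structure(list(probes = probes, dims = dims, L_nm = L_nm, Lz_nm = Lz_nm,
                 probing = "shift"),
            class = "scan_pattern")
}

#' @export
print.scan_pattern <- function(x, ...) {
  kinds <- vapply(x$probes, function(p) p$mask$kind, character(1))
  cat(sprintf("scan_pattern: %dD, K = %d probes (%s), L = %g nm, Lz = %g nm\n",
              x$dims, length(x$probes),
              paste(unique(kinds), collapse = ", "), x$L_nm, x$Lz_nm))
  invisible(x)
}

#' Add a background offset to a PSF
#'
#' Adds the constant offset \eqn{b \cdot I_A(0)} modeling an imperfect zero
#' and fluorescent background, as a fraction `b` of the maximum of the
#' flat-phase Airy PSF of equal summed intensity. `psf_stack` intensities
#' are in \eqn{I_A(0)} units, so the offset is simply `+ b`.
#'
#' @param psf A `psf_stack`.
#' @param b Background fraction (>= 0).
#' @return The offset `psf_stack`.
#' @export
add_background <- function(psf, b) {
  stopifnot(inherits(psf, "psf_stack"))
  if (!is.finite(b) || b < 0) stop("background fraction 'b' must be >= 0")
  psf$intensity <- psf$intensity + b
  psf$background_b <- (psf$background_b %||% 0) + b
  psf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

probe_group_key <- function(probe) {
  pol <- probe$polarization
  polkey <- if (is.null(pol)) "default" else
    paste(format(unclass(pol), digits = 10), collapse = ",")
  paste(probe$mask$kind, probe$mask$tophat_radius_frac, polkey,
        paste(probe$shift, collapse = ","), sep = "|")
}

# Resolve probe EOM phases (solving target positions once per mask kind)
resolve_phases <- function(pattern, config) {
  cache <- new.env(parent = emptyenv())
  lapply(pattern$probes, function(pr) {
    if (!is.null(pr$eom_phase)) return(pr$eom_phase)
    if (is.null(pr$target_nm) || pr$target_nm == 0) return(pi)
    key <- paste(probe_group_key(pr), pr$target_nm)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    phi <- phase_for_displacement(config, pr$mask, pr$target_nm,
                                  polarization = pr$polarization)
    cache[[key]] <- phi
    phi
  })
}

#' Probe intensities and probabilities over an emitter grid
#'
#' Evaluates every probe PSF of a scan pattern at emitter positions
#' `r_E` on a Cartesian grid, adds the background offset `b * I_A(0)`, and
#' normalizes to the multinomial probabilities
#' \eqn{p_i(r_E) = I_i(r_E) / \sum_j I_j(r_E)}. Probes defined by a target
#' minimum position are realized through the EOM phase (solved by root
#' finding); probes defined by a rigid shift are evaluated exactly at
#' \eqn{r_E - r_i}.
#'
#' @param pattern A `scan_pattern`.
#' @param config An [optical_config()].
#' @param x,y,z Grid coordinate vectors for the emitter positions (nm).
#' @param b Background offset fraction of \eqn{I_A(0)}.
#' @return An object of class `probe_set`: intensities and probabilities as
#'   `[nx, ny, nz, K]` arrays (in \eqn{I_A(0)} units), coordinates, and
#'   metadata.
#' @examples
#' \donttest{
#' cfg <- optical_config(pupil_n = 96)
#' ps <- probe_intensities(minflux_pattern(2), cfg,
#'                         x = seq(-4, 4, 2), y = seq(-4, 4, 2), z = 0,
#'                         b = 0.005)
#' range(apply(ps$p, 1:3, sum))  # 1, everywhere
#' }
#' @export
probe_intensities <- function(pattern, config, x, y, z = 0, b = 0) {
  stopifnot(inherits(pattern, "scan_pattern"), inherits(config, "optical_config"))
  if (b < 0) stop("background fraction 'b' must be >= 0")
  phases <- resolve_phases(pattern, config)
  pts <- expand.grid(x = x, y = y, z = z, KEEP.OUT.ATTRS = FALSE)
  keys <- vapply(pattern$probes, probe_group_key, character(1))
  field_cache <- new.env(parent = emptyenv())
  K <- length(pattern$probes)
  II <- matrix(0, nrow(pts), K)
  for (i in seq_len(K)) {
    pr <- pattern$probes[[i]]
    hit <- field_cache[[keys[i]]]
    if (is.null(hit)) {
      pupil <- build_pupil(config, pr$mask, pr$polarization)
      kern <- focal_kernels(pupil)
      f <- field_at_points(kern,
                           pts$x - pr$shift[1],
                           pts$y - pr$shift[2],
                           pts$z - pr$shift[3], chunk = 128L)
      hit <- list(f = f, pupil = pupil)
      field_cache[[keys[i]]] <- hit
    }
    II[, i] <- modes_intensity(hit$f, phases[[i]]) *
      airy_scale(hit$pupil, phases[[i]]) + b
  }
  dims <- c(length(x), length(y), length(z))
  p <- II / rowSums(II)
  structure(list(I = array(II, c(dims, K)), p = array(p, c(dims, K)),
                 x = x, y = y, z = z, b = b, K = K,
                 pattern = pattern, config = config,
                 eom_phases = unlist(phases)),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set: K = %d probes on %s emitter grid, b = %g\n",
              x$K, paste(c(length(x$x), length(x$y), length(x$z)),
                         collapse = "x"), x$b))
  invisible(x)
}

#' Fisher information matrix of a probe set
#'
#' Computes \eqn{J(r_E) = N \sum_i p_i^{-1} \nabla p_i \nabla p_i^T} with
#' central finite-difference gradients of one voxel. The full 3x3 matrix is
#' assembled from all probes; axes with a single grid plane get zero
#' gradient (and are excluded when inverting via the `dims` argument of
#' [crb_map()]).
#'
#' @param probe_set A [probe_intensities()] result; `p` must be strictly
#'   positive (guaranteed by `b > 0`).
#' @param N Total detected photons.
#' @return An object of class `precision_result` with the Fisher array
#'   `J[nx, ny, nz, 3, 3]` (`NA` on grid borders), the grid, and `N`.
#' @export
fisher_matrix <- function(probe_set, N = 1) {
  stopifnot(inherits(probe_set, "probe_set"))
  p <- probe_set$p
  if (any(p <= 0))
    stop("some p_i are zero on the grid; use a positive background offset b ",
         "or shrink the evaluation region")
  d <- dim(p)[1:3]
  steps <- c(if (d[1] > 1) probe_set$x[2] - probe_set$x[1] else NA,
             if (d[2] > 1) probe_set$y[2] - probe_set$y[1] else NA,
             if (d[3] > 1) probe_set$z[2] - probe_set$z[1] else NA)
  J <- array(NA_real_, c(d, 3, 3))
  ix <- if (d[1] > 2) 2:(d[1] - 1) else seq_len(d[1])
  iy <- if (d[2] > 2) 2:(d[2] - 1) else seq_len(d[2])
  iz <- if (d[3] > 2) 2:(d[3] - 1) else seq_len(d[3])
  gr <- array(0, c(d, 3))
  Jin <- array(0, c(length(ix), length(iy), length(iz), 3, 3))
  for (i in seq_len(probe_set$K)) {
    pi_arr <- p[, , , i, drop = FALSE]
    dim(pi_arr) <- d
    g <- array(0, c(d, 3))
    if (d[1] > 2)
      g[ix, , , 1] <- (pi_arr[ix + 1, , , drop = FALSE] -
                         pi_arr[ix - 1, , , drop = FALSE]) / (2 * steps[1])
    if (d[2] > 2)
      g[, iy, , 2] <- (pi_arr[, iy + 1, , drop = FALSE] -
                         pi_arr[, iy - 1, , drop = FALSE]) / (2 * steps[2])
    if (d[3] > 2)
      g[, , iz, 3] <- (pi_arr[, , iz + 1, drop = FALSE] -
                         pi_arr[, , iz - 1, drop = FALSE]) / (2 * steps[3])
    for (a in 1:3) for (bb in 1:3)
      Jin[, , , a, bb] <- Jin[, , , a, bb] +
        (g[ix, iy, iz, a] * g[ix, iy, iz, bb]) / pi_arr[ix, iy, iz]
  }
  J[ix, iy, iz, , ] <- N * Jin
  structure(list(J = J, x = probe_set$x, y = probe_set$y, z = probe_set$z,
                 N = N, probe_set = probe_set),
            class = "precision_result")
}

#' Cramer-Rao bound map from a Fisher result
#'
#' Inverts the Fisher matrix voxel-wise and returns the dimension-averaged
#' single-photon precision
#' \eqn{\sigma\sqrt{N} = \sqrt{\mathrm{tr}_d(J^{-1})/d} \cdot \sqrt{N}}
#' (\eqn{\sqrt{(CRB_x + CRB_y)/2}} for 2D,
#' \eqn{\sqrt{(CRB_x + CRB_y + CRB_z)/3}} for 3D). Singular matrices yield
#' `NA` entries; their count is reported in `n_singular`.
#'
#' @param precision A [fisher_matrix()] result.
#' @param dims 1, 2 or 3: which leading dimensions to invert and average.
#' @return A `crb_result`: list with the `sigma_sqrtN` array (nm), the
#'   per-axis `crb` array (nm^2, CRB at N photons times N), `center` value,
#'   and `n_singular`.
#' @export
crb_map <- function(precision, dims = 3) {
  stopifnot(inherits(precision, "precision_result"), dims %in% 1:3)
  J <- precision$J
  d <- dim(J)[1:3]
  idx <- seq_len(dims)
  sig <- array(NA_real_, d)
  crb <- array(NA_real_, c(d, dims))
  n_singular <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    Jm <- J[i, j, k, idx, idx]
    if (any(is.na(Jm))) next
    Cm <- tryCatch(solve(matrix(Jm, dims, dims)), error = function(e) NULL)
    if (is.null(Cm)) { n_singular <- n_singular + 1L; next }
    cr <- diag(Cm) * precision$N    # CRB at N photons, times N -> nm^2
    crb[i, j, k, ] <- cr
    sig[i, j, k] <- sqrt(mean(cr))
  }
  ic <- (d + 1L) %/% 2L
  structure(list(sigma_sqrtN = sig, crb = crb, dims = dims,
                 center = sig[ic[1], ic[2], ic[3]],
                 x = precision$x, y = precision$y, z = precision$z,
                 n_singular = n_singular),
            class = "crb_result")
}

#' @export
print.crb_result <- function(x, ...) {
  cat(sprintf("crb_result (%dD): center sigma*sqrt(N) = %.3f nm\n",
              x$dims, x$center))
  if (x$n_singular > 0)
    cat(sprintf("  %d singular Fisher matrices masked as NA\n", x$n_singular))
  invisible(x)
}

#' End-to-end MINFLUX localization precision at the pattern center
#'
#' Convenience pipeline: probe intensities on a small grid around the
#' pattern center, Fisher matrix, CRB, dimension-averaged center precision.
#'
#' @param config An [optical_config()].
#' @param pattern A `scan_pattern`.
#' @param b Background offset fraction of \eqn{I_A(0)}.
#' @param center_nm Pattern center (emitter grid center).
#' @param half_points Grid half-width in voxels around the center.
#' @param step_nm Grid step (default: the configuration's voxel size).
#' @return A `crb_result` (see [crb_map()]); `$center` is the
#'   dimension-averaged \eqn{\sigma\sqrt{N}} in nm.
#' @examples
#' \donttest{
#' cfg <- optical_config(pupil_n = 96)
#' minflux_crb(cfg, minflux_pattern(2, L_nm = 50), b = 0.005)$center
#' }
#' @export
minflux_crb <- function(config, pattern, b = 0.005, center_nm = c(0, 0, 0),
                        half_points = 2L, step_nm = NULL) {
  step <- rep_len(step_nm %||% config$voxel_size_nm, 3L)
  hp <- half_points
  gx <- center_nm[1] + seq(-hp, hp) * step[1]
  gy <- center_nm[2] + seq(-hp, hp) * step[2]
  gz <- center_nm[3] + seq(-hp, hp) * step[3]
  ps <- probe_intensities(pattern, config, gx, gy, gz, b = b)
  crb_map(fisher_matrix(ps), dims = pattern$dims)
}

#' Compare localization performance of scan patterns
#'
#' Computes the center precision and its growth with lateral emitter
#' distance from the pattern center for several patterns under identical
#' background and normalization, enabling the standard orderings (e.g.
#' bilobed + top-hat versus 3D-donut-only center precision, and
#' field-of-view flatness of bilobed versus donut patterns).
#'
#' @param patterns Named list of `scan_pattern` objects.
#' @param config An [optical_config()].
#' @param b Background offset fraction.
#' @param offsets_nm Lateral emitter offsets (along x) at which precision is
#'   evaluated.
#' @return `data.frame(pattern, offset_nm, sigma_sqrtN)`.
#' @export
compare_patterns <- function(patterns, config, b = 0.005,
                             offsets_nm = c(0, 50, 100)) {
  stopifnot(length(names(patterns)) == length(patterns))
  rows <- lapply(names(patterns), function(nm) {
    pat <- patterns[[nm]]
    sig <- vapply(offsets_nm, function(off)
      minflux_crb(config, pat, b = b, center_nm = c(off, 0, 0))$center,
      numeric(1))
    data.frame(pattern = nm, offset_nm = offsets_nm, sigma_sqrtN = sig)
  })
  do.call(rbind, rows)
}
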
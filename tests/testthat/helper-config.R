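# Shared reduced-resolution configurations. Tests trade pupil sampling for
# speed; the acceptance tests use the full published configuration.

cfg_small <- function(...) optical_config(pupil_n = 64L, ...)
cfg_mid <- function(...) optical_config(pupil_n = 96L, ...)

# direct (slow, loop-based) scalar Fourier-optics focal intensity: plain
# sum of amp * exp(i k (sx x + sy y)) over the pupil, no apodization or
# polarization rotation. Independent oracle for the low-NA limit.
scalar_focus_oracle <- function(config, mask, xs, ys) {
  pu <- build_pupil(config, mask)
  g <- pu$grid
  amp <- pu$amp_off + exp(1i * pu$eom_phase) * pu$amp_on
  k <- 2 * pi * config$refractive_index / config$wavelength_nm
  out <- matrix(0, length(xs), length(ys))
  for (i in seq_along(xs)) for (j in seq_along(ys)) {
    e <- sum(amp * exp(1i * k * (g$sx * xs[i] + g$sy * ys[j])))
    out[i, j] <- Mod(e)^2
  }
  out
}

# probe_set built directly from analytic intensities on a 1D grid
manual_probe_set_1d <- function(x, I) {
  K <- ncol(I)
  p <- I / rowSums(I)
  structure(list(I = array(I, c(length(x), 1, 1, K)),
                 p = array(p, c(length(x), 1, 1, K)),
                 x = x, y = 0, z = 0, b = 0, K = K,
                 pattern = NULL, config = NULL),
            class = "probe_set")
}
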
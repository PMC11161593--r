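# Monte-Carlo simulation of MINFLUX probing: Poisson photon counts over
# probe cycles, two-state flicker of the emitter, maximum-likelihood
# position estimation, and EOM-phase-drift bias.

# run `code` under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Emitter model
#'
#' A single fluorophore at position `position_nm` emitting
#' `brightness_per_us` expected detected photons per microsecond when
#' illuminated at the Airy reference intensity \eqn{I_A(0)}. Optional
#' two-state telegraph flicker models transient dark states: `off_rate` is
#' the on-to-off switching rate and `on_rate` the off-to-on rate (1/us).
#'
#' @param position_nm Emitter position, length-3 nm.
#' @param brightness_per_us Expected photons per us at unit PSF intensity.
#' @param flicker `NULL`, or `list(off_rate = , on_rate = )` in 1/us.
#' @return An object of class `emitter_model`.
#' @export
emitter_model <- function(position_nm = c(0, 0, 0), brightness_per_us = 100,
                          flicker = NULL) {
  stopifnot(length(position_nm) == 3, brightness_per_us >= 0)
  if (!is.null(flicker)) {
    stopifnot(is.list(flicker), flicker$off_rate >= 0, flicker$on_rate >= 0)
  }
  structure(list(position_nm = position_nm,
                 brightness_per_us = brightness_per_us,
                 flicker = flicker),
            class = "emitter_model")
}

#' Probing schedule
#'
#' Timing of the probe sequence: each of the pattern's K probes is visited
#' for `dwell_us` per cycle, for `cycles` cycles. `eom_phase_error_deg` adds
#' a static error to every probe's EOM phase (models EOM drift).
#' `deadtime_us` is the SLM pattern-switching dead time; it affects only the
#' reported wall time, never the photon statistics.
#'
#' @param pattern A `scan_pattern`.
#' @param dwell_us Dwell per probe position per cycle (us).
#' @param cycles Number of probing cycles (>= 1).
#' @param eom_phase_error_deg Static EOM phase error in degrees.
#' @param deadtime_us SLM switching dead time (metadata only).
#' @return An object of class `probing_schedule`.
#' @export
probing_schedule <- function(pattern, dwell_us = 1, cycles = 60,
                             eom_phase_error_deg = 0, deadtime_us = 60) {
  stopifnot(inherits(pattern, "scan_pattern"), dwell_us > 0, cycles >= 1)
  structure(list(pattern = pattern, dwell_us = dwell_us,
                 cycles = as.integer(cycles),
                 eom_phase_error_deg = eom_phase_error_deg,
                 deadtime_us = deadtime_us),
            class = "probing_schedule")
}

# Probe intensities (I_A(0) units, background included) at a single point.
probe_point_rates <- function(pattern, config, position_nm, b = 0,
                              phase_error_rad = 0) {
  pat <- pattern
  if (phase_error_rad != 0) {
    phases <- resolve_phases(pat, config)
    pat$probes <- lapply(seq_along(pat$probes), function(i) {
      pr <- pat$probes[[i]]
      pr$eom_phase <- phases[[i]] + phase_error_rad
      pr$target_nm <- NULL
      pr
    })
  }
  ps <- probe_intensities(pat, config, position_nm[1], position_nm[2],
                          position_nm[3], b = b)
  ps$I[1, 1, 1, ]
}

# Per-slot on-state fraction of the two-state telegraph process over
# n_slots consecutive dwells of length dwell_us. Exact event-driven
# simulation; starts in the stationary state.
telegraph_on_fraction <- function(n_slots, dwell_us, off_rate, on_rate) {
  if (off_rate == 0 && on_rate == 0) return(rep(1, n_slots))
  total <- n_slots * dwell_us
  p_on <- if (off_rate + on_rate > 0) on_rate / (off_rate + on_rate) else 1
  state <- stats::runif(1) < p_on
  t <- 0
  on_time <- numeric(n_slots)
  while (t < total) {
    rate <- if (state) off_rate else on_rate
    hold <- if (rate > 0) stats::rexp(1, rate) else total - t + 1
    t_end <- min(t + hold, total)
    if (state) {
      # credit the on interval [t, t_end) to the slots it spans
      s0 <- floor(t / dwell_us); s1 <- floor((t_end - 1e-12) / dwell_us)
      for (s in s0:s1) {
        lo <- max(t, s * dwell_us); hi <- min(t_end, (s + 1) * dwell_us)
        if (hi > lo) on_time[s + 1] <- on_time[s + 1] + (hi - lo)
      }
    }
    t <- t + hold
    state <- !state
  }
  on_time / dwell_us
}

#' Simulate photon counts of a MINFLUX probing sequence
#'
#' Draws Poisson counts per probe and cycle with mean
#' `brightness * dwell * (I_i(r_E) + b * I_A(0))`, where the probe
#' intensities are evaluated exactly at the emitter position. Two-state
#' flicker, when present, modulates the brightness per dwell slot. Identical
#' inputs and seed reproduce identical counts.
#'
#' @param emitter An [emitter_model()].
#' @param schedule A [probing_schedule()].
#' @param config An [optical_config()].
#' @param b Background offset fraction of \eqn{I_A(0)}.
#' @param seed Integer seed (`NULL`: use the current RNG state).
#' @param rates Optional precomputed probe intensities at the emitter (in
#'   \eqn{I_A(0)} units, background included); avoids re-evaluating the
#'   diffraction integral across repeated trials.
#' @return A list with `counts` (total per probe), `counts_by_cycle`
#'   (cycles x K matrix), `N` (total photons), `rates` (probe intensities in
#'   \eqn{I_A(0)} units) and `wall_time_us`.
#' @export
simulate_counts <- function(emitter, schedule, config, b = 0, seed = NULL,
                            rates = NULL) {
  stopifnot(inherits(emitter, "emitter_model"),
            inherits(schedule, "probing_schedule"))
  if (is.null(rates))
    rates <- probe_point_rates(schedule$pattern, config, emitter$position_nm,
                               b = b,
                               phase_error_rad =
                                 deg2rad(schedule$eom_phase_error_deg))
  K <- length(rates)
  mean0 <- emitter$brightness_per_us * schedule$dwell_us * rates
  with_seed(seed, {
    nslots <- schedule$cycles * K
    onfrac <- if (is.null(emitter$flicker)) rep(1, nslots)
              else telegraph_on_fraction(nslots, schedule$dwell_us,
                                         emitter$flicker$off_rate,
                                         emitter$flicker$on_rate)
    mu <- rep(mean0, times = schedule$cycles) * onfrac
    n <- stats::rpois(nslots, mu)
    m <- matrix(n, nrow = K)  # K x cycles, probe-major within each cycle
    counts <- rowSums(m)
    list(counts = counts, counts_by_cycle = t(m), N = sum(counts),
         rates = rates,
         wall_time_us = nslots * schedule$dwell_us + schedule$deadtime_us)
  })
}

#' Maximum-likelihood position estimate from probe counts
#'
#' Maximizes the Poisson/multinomial log-likelihood
#' \eqn{l(r_E | n) = \sum_i n_i \ln p_i(r_E)} over the probe set's emitter
#' grid, then refines each axis with 3-point parabolic interpolation of the
#' log-likelihood. Deterministic given the counts.
#'
#' @param counts Integer photon counts per probe (length K).
#' @param probe_set A [probe_intensities()] result evaluated on the search
#'   grid (use a grid spanning the scan pattern at ~1 nm spacing).
#' @return Estimated position, named length-3 vector (nm).
#' @export
ml_estimate <- function(counts, probe_set) {
  stopifnot(inherits(probe_set, "probe_set"),
            length(counts) == probe_set$K)
  if (sum(counts) <= 0) stop("all probe counts are zero; no information")
  lp <- log(probe_set$p)
  d <- dim(lp)[1:3]
  ll <- array(0, d)
  for (i in seq_len(probe_set$K))
    ll <- ll + counts[i] * array(lp[, , , i], d)
  im <- arrayInd(which.max(ll), d)
  coords <- list(probe_set$x, probe_set$y, probe_set$z)
  est <- c(x = 0, y = 0, z = 0)
  for (ax in 1:3) {
    cc <- coords[[ax]]
    est[ax] <- cc[im[ax]]
    if (d[ax] >= 3 && im[ax] > 1 && im[ax] < d[ax]) {
      idx <- function(off) {
        jj <- im; jj[ax] <- jj[ax] + off
        ll[jj[1], jj[2], jj[3]]
      }
      a <- idx(-1); bb <- idx(0); cend <- idx(1)
      den <- a - 2 * bb + cend
      if (den < 0)
        est[ax] <- cc[im[ax]] + (a - cend) / (2 * den) * (cc[2] - cc[1])
    }
  }
  est
}

#' Monte-Carlo localization ensemble
#'
#' Repeats simulate-and-estimate trials and summarizes bias and standard
#' deviation of the position estimates.
#'
#' @param emitter An [emitter_model()].
#' @param schedule A [probing_schedule()].
#' @param config An [optical_config()].
#' @param b Background offset fraction.
#' @param n_trials Number of independent trials.
#' @param seed Integer seed; trial `t` uses `seed + t`.
#' @param probe_set Search-grid probe set for the estimator; built
#'   automatically (spanning +/- `L_nm` at `grid_step_nm`) when `NULL`.
#' @param grid_step_nm Estimator grid step.
#' @return A list with `estimates` (n x 3), `bias`, `std` (per axis),
#'   `se_bias`, `mean_N`, and the probe set used.
#' @export
localize_ensemble <- function(emitter, schedule, config, b = 0,
                              n_trials = 200, seed = 1, probe_set = NULL,
                              grid_step_nm = 1) {
  pat <- schedule$pattern
  if (is.null(probe_set)) {
    gx <- seq(-pat$L_nm, pat$L_nm, by = grid_step_nm)
    gz <- if (pat$dims >= 3) seq(-pat$Lz_nm, pat$Lz_nm, by = 2 * grid_step_nm)
          else 0
    gy <- if (pat$dims >= 2) gx else 0
    probe_set <- probe_intensities(pat, config, gx, gy, gz, b = b)
  }
  rates <- probe_point_rates(pat, config, emitter$position_nm, b = b,
                             phase_error_rad =
                               deg2rad(schedule$eom_phase_error_deg))
  est <- matrix(NA_real_, n_trials, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  Ns <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    sim <- simulate_counts(emitter, schedule, config, b = b, seed = seed + t,
                           rates = rates)
    if (sim$N == 0) next
    est[t, ] <- ml_estimate(sim$counts, probe_set)
    Ns[t] <- sim$N
  }
  ok <- !is.na(est[, 1])
  dims <- pat$dims
  bias <- colMeans(est[ok, , drop = FALSE]) - emitter$position_nm
  stdev <- apply(est[ok, , drop = FALSE], 2, stats::sd)
  list(estimates = est, bias = bias, std = stdev,
       se_bias = stdev / sqrt(sum(ok)), mean_N = mean(Ns[ok]),
       n_ok = sum(ok), dims = dims, probe_set = probe_set)
}

#' Localization bias caused by a static EOM phase error
#'
#' A phase error shifts every probe minimum by the mask's
#' phase-to-displacement slope, displacing the whole scan pattern and hence
#' the position estimate. Computed by simulation, not from a stored slope:
#' noiseless expected counts are generated with the perturbed probe phases
#' and fed to the maximum-likelihood estimator that assumes the nominal
#' pattern; the resulting estimate of a centered emitter is the bias.
#'
#' @param config An [optical_config()].
#' @param pattern A `scan_pattern` (the bias is reported along `axis`).
#' @param delta_deg Static EOM phase error in degrees (|delta| <= 5
#'   recommended; the relation is linear to first order).
#' @param axis Axis along which to report the bias.
#' @param b Background offset fraction.
#' @param N Photons used for the noiseless expected counts.
#' @param grid_step_nm Estimator grid step.
#' @return Bias in nm (signed).
#' @export
phase_drift_bias <- function(config, pattern, delta_deg, axis = NULL,
                             b = 0.005, N = 1e5, grid_step_nm = 0.5) {
  axis <- axis %||% mask_axis(pattern$probes[[1]]$mask)
  rates <- probe_point_rates(pattern, config, c(0, 0, 0), b = b,
                             phase_error_rad = deg2rad(delta_deg))
  counts <- N * rates / sum(rates)
  span <- max(pattern$L_nm, if (pattern$dims >= 3) pattern$Lz_nm else 0)
  gx <- if (axis == "x") seq(-span, span, by = grid_step_nm) else 0
  gy <- if (axis == "y") seq(-span, span, by = grid_step_nm) else 0
  gz <- if (axis == "z") seq(-span, span, by = grid_step_nm) else 0
  ps <- probe_intensities(pattern, config, gx, gy, gz, b = b)
  unname(ml_estimate(counts, ps)[axis])
}

#' Flicker-averaging study: bias versus number of probing cycles
#'
#' Distributes a fixed total probing time over an increasing number of
#' cycles and measures the ensemble localization bias for a flickering
#' emitter. Slow brightness fluctuations between the sequential probes of a
#' cycle bias the estimate; many fast cycles average the fluctuations out.
#'
#' @param config An [optical_config()].
#' @param pattern A `scan_pattern` (1D patterns keep this affordable).
#' @param emitter An [emitter_model()] (typically with flicker and an
#'   off-center position).
#' @param cycles_list Cycle counts to compare (total time held fixed).
#' @param total_time_us Total probing time per localization.
#' @param n_trials Trials per cycle count.
#' @param seed Base seed.
#' @param b Background offset fraction.
#' @return `data.frame(cycles, dwell_us, bias_nm, se_nm, mean_N)` for the
#'   pattern's scan axis.
#' @export
flicker_bias_study <- function(config, pattern, emitter,
                               cycles_list = c(1, 60), total_time_us = 180,
                               n_trials = 300, seed = 1, b = 0.005) {
  axis <- mask_axis(pattern$probes[[1]]$mask)
  K <- length(pattern$probes)
  gx <- seq(-pattern$L_nm, pattern$L_nm, by = 1)
  ps <- probe_intensities(pattern, config,
                          if (axis == "x") gx else 0,
                          if (axis == "y") gx else 0,
                          if (axis == "z") gx else 0, b = b)
  rows <- lapply(seq_along(cycles_list), function(j) {
    cyc <- cycles_list[j]
    dwell <- total_time_us / (cyc * K)
    sch <- probing_schedule(pattern, dwell_us = dwell, cycles = cyc)
    ens <- localize_ensemble(emitter, sch, config, b = b,
                             n_trials = n_trials,
                             seed = seed + 1000 * j, probe_set = ps)
    data.frame(cycles = cyc, dwell_us = dwell,
               bias_nm = unname(ens$bias[axis]),
               se_nm = unname(ens$se_bias[axis]),
               mean_N = ens$mean_N)
  })
  do.call(rbind, rows)
}

#' Expected intensity trace for an EOM phase waveform
#'
#' Reproduces the bench-style traces: the excitation intensity seen by an
#' emitter while the EOM phase follows a waveform, optionally alternating
#' between colors (each color a configuration with its own static EOM
#' offset). Minima occur where the total phase crosses the emitter's
#' interference phase plus pi.
#'
#' @param config An [optical_config()] (single color), or ignored when
#'   `colors` is given.
#' @param mask A [phase_mask()].
#' @param waveform `list(type = "ramp", duration_us, period_us, phase_from,
#'   phase_to, dt_us)` for a linear phase ramp, or `list(type = "levels",
#'   phases, dwell_us, cycles, dt_us)` for a stepped three-level (or K-level)
#'   drive; phases in radians.
#' @param emitter_nm Emitter position.
#' @param b Background offset fraction.
#' @param colors Optional list of `list(config = , eom_offset = )` colors
#'   alternated in blocks of `block_us`.
#' @param block_us Per-color block length when alternating colors.
#' @param brightness_per_us If not `NULL`, add a Poisson-realized `counts`
#'   column (photons per `dt_us` bin).
#' @param seed Seed for the Poisson realization.
#' @return `data.frame(time_us, phase_rad, color, intensity[, counts])`,
#'   intensity in \eqn{I_A(0)} units.
#' @export
intensity_trace <- function(config, mask, waveform, emitter_nm = c(0, 0, 0),
                            b = 0, colors = NULL, block_us = 9,
                            brightness_per_us = NULL, seed = NULL) {
  if (is.null(colors)) colors <- list(list(config = config, eom_offset = 0))
  dt <- waveform$dt_us %||% 0.05
  if (waveform$type == "ramp") {
    tt <- seq(0, waveform$duration_us, by = dt)
    frac <- (tt %% waveform$period_us) / waveform$period_us
    ph <- (waveform$phase_from %||% 0) +
      frac * ((waveform$phase_to %||% (2 * pi)) - (waveform$phase_from %||% 0))
  } else if (waveform$type == "levels") {
    cyc <- waveform$cycles %||% 1
    dwell <- waveform$dwell_us
    tt <- seq(0, cyc * length(waveform$phases) * dwell - dt, by = dt)
    slot <- floor(tt / dwell) %% length(waveform$phases)
    ph <- waveform$phases[slot + 1]
  } else stop("unknown waveform type '", waveform$type, "'")
  color_idx <- (floor(tt / block_us) %% length(colors)) + 1L
  # one diffraction evaluation per color: on/off fields at the emitter point
  pt_modes <- lapply(colors, function(cl) {
    pu <- build_pupil(cl$config, mask)
    kern <- focal_kernels(pu)
    list(f = field_at_points(kern, emitter_nm[1], emitter_nm[2],
                             emitter_nm[3]),
         pupil = pu, offset = cl$eom_offset %||% 0)
  })
  inten <- numeric(length(tt))
  for (ci in seq_along(colors)) {
    sel <- color_idx == ci
    pm <- pt_modes[[ci]]
    inten[sel] <- vapply(ph[sel] + pm$offset, function(p)
      modes_intensity(pm$f, p) * airy_scale(pm$pupil, p), numeric(1)) + b
  }
  out <- data.frame(time_us = tt, phase_rad = ph, color = color_idx,
                    intensity = inten)
  if (!is.null(brightness_per_us))
    out$counts <- with_seed(seed,
                            stats::rpois(length(tt),
                                         brightness_per_us * dt * inten))
  out
}
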
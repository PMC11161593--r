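# Monte-Carlo probing: counts, estimator, drift bias, flicker averaging

test_that("counts are seed-reproducible and conserve photons", {
  cfg <- cfg_small()
  pat <- minflux_pattern(1, L_nm = 50)
  em <- emitter_model(c(5, 0, 0), brightness_per_us = 80)
  sch <- probing_schedule(pat, dwell_us = 1, cycles = 10)
  s1 <- simulate_counts(em, sch, cfg, b = 0.005, seed = 99)
  s2 <- simulate_counts(em, sch, cfg, b = 0.005, seed = 99)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$counts_by_cycle, s2$counts_by_cycle)
  expect_equal(sum(s1$counts_by_cycle), s1$N)
  expect_equal(colSums(s1$counts_by_cycle), s1$counts)
  s3 <- simulate_counts(em, sch, cfg, b = 0.005, seed = 100)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("mean counts follow the probe intensities (law of large numbers)", {
  cfg <- cfg_small()
  pat <- minflux_pattern(1, L_nm = 50)
  em <- emitter_model(c(8, 0, 0), brightness_per_us = 50)
  sch <- probing_schedule(pat, dwell_us = 1, cycles = 5)
  rates <- minfluxvpp:::probe_point_rates(pat, cfg, em$position_nm, b = 0.005)
  mu <- em$brightness_per_us * sch$dwell_us * sch$cycles * rates
  n_rep <- 3000
  tot <- matrix(0, n_rep, length(rates))
  for (r in seq_len(n_rep))
    tot[r, ] <- simulate_counts(em, sch, cfg, b = 0.005, seed = 1000 + r,
                                rates = rates)$counts
  se <- sqrt(mu / n_rep)
  expect_true(all(abs(colMeans(tot) - mu) < 3 * se + 1e-9))
})

test_that("an emitter at a probe's zero yields (almost) no expected signal", {
  cfg <- cfg_mid()
  pat <- minflux_pattern(1, L_nm = 50)
  rates <- minfluxvpp:::probe_point_rates(pat, cfg, c(0, 0, 0), b = 0)
  expect_lt(rates[2], 1e-10)              # centered probe: true zero
  expect_equal(rates[1], rates[3], tolerance = 1e-6)  # mirror symmetry
})

test_that("the ML estimator is consistent on noiseless expected counts", {
  cfg <- cfg_small()
  pat <- minflux_pattern(1, L_nm = 50)
  ps <- probe_intensities(pat, cfg, x = seq(-40, 40, 0.5), y = 0, z = 0,
                          b = 0.005)
  for (x0 in c(-10, 0, 7)) {
    rates <- minfluxvpp:::probe_point_rates(pat, cfg, c(x0, 0, 0), b = 0.005)
    est <- ml_estimate(1e5 * rates / sum(rates), ps)
    expect_equal(unname(est["x"]), x0, tolerance = 0.5)
  }
  expect_error(ml_estimate(c(0, 0, 0), ps), "zero")
})

test_that("ML ensemble attains the CRB at large photon numbers", {
  cfg <- cfg_mid()
  pat <- minflux_pattern(2, L_nm = 50)
  crb <- minflux_crb(cfg, pat, b = 0.005)$center
  gx <- seq(-35, 35, 1)
  ps <- probe_intensities(pat, cfg, x = gx, y = gx, z = 0, b = 0.005)
  em <- emitter_model(c(0, 0, 0), brightness_per_us = 1000)
  # calibrate brightness so that E[N] ~ 1e4 over one cycle set
  rates <- minfluxvpp:::probe_point_rates(pat, cfg, em$position_nm, b = 0.005)
  target_N <- 1e4
  em$brightness_per_us <- target_N / sum(rates)
  sch <- probing_schedule(pat, dwell_us = 1, cycles = 1)
  ens <- localize_ensemble(em, sch, cfg, b = 0.005, n_trials = 1000,
                           seed = 7, probe_set = ps)
  sigma_mc <- sqrt(mean(ens$std[c("x", "y")]^2)) * sqrt(ens$mean_N)
  expect_equal(sigma_mc, crb, tolerance = 0.05)
  # and the estimate is unbiased within Monte-Carlo error
  expect_lt(abs(ens$bias["x"]), 3 * ens$se_bias["x"])
  expect_lt(abs(ens$bias["y"]), 3 * ens$se_bias["y"])
})

test_that("a static EOM phase error biases the estimate by slope times delta", {
  cfg <- cfg_mid()
  pat <- minflux_pattern(1, L_nm = 50)
  slope <- phase_to_displacement(cfg, phase_mask("bisected_x"),
                                 phase_offsets_deg = c(-10, -5, 5, 10))
  expect_equal(phase_drift_bias(cfg, pat, 0), 0, tolerance = 0.05)
  b1 <- phase_drift_bias(cfg, pat, 1)
  b2 <- phase_drift_bias(cfg, pat, 2)
  expect_equal(abs(b1), slope$slope_nm_per_deg, tolerance = 0.1)
  expect_equal(abs(b2), 2 * slope$slope_nm_per_deg, tolerance = 0.1)
  expect_equal(b2 / b1, 2, tolerance = 0.1)  # linear to 10% for small delta
})

test_that("fast probing cycles average out flicker bias", {
  cfg <- cfg_small()
  pat <- minflux_pattern(1, L_nm = 50)
  # no flicker: bias flat in the cycle count within Monte-Carlo error
  em0 <- emitter_model(c(12, 0, 0), brightness_per_us = 60)
  t0 <- flicker_bias_study(cfg, pat, em0, cycles_list = c(1, 60),
                           total_time_us = 180, n_trials = 250, seed = 5)
  expect_lt(abs(t0$bias_nm[1] - t0$bias_nm[2]),
            3 * sqrt(sum(t0$se_nm^2)))
  # strong microsecond flicker: one slow cycle is biased, 60 fast ones less
  emf <- emitter_model(c(12, 0, 0), brightness_per_us = 60,
                       flicker = list(off_rate = 0.2, on_rate = 0.2))
  tf <- flicker_bias_study(cfg, pat, emf, cycles_list = c(1, 60),
                           total_time_us = 180, n_trials = 250, seed = 5)
  expect_lt(abs(tf$bias_nm[2]), abs(tf$bias_nm[1]))
})

test_that("intensity traces locate minima at the expected phases", {
  cfg <- cfg_small()
  mask <- phase_mask("bisected_x")
  tr <- intensity_trace(cfg, mask,
                        waveform = list(type = "ramp", duration_us = 10,
                                        period_us = 10, dt_us = 0.05))
  ph_min <- tr$phase_rad[which.min(tr$intensity)]
  expect_equal(ph_min, pi, tolerance = 0.05)
  # three-level drive on a centered emitter: outer levels read equally
  phis <- c(pi - 0.3, pi, pi + 0.3)
  tr3 <- intensity_trace(cfg, mask,
                         waveform = list(type = "levels", phases = phis,
                                         dwell_us = 1, cycles = 2,
                                         dt_us = 0.25))
  lv <- tapply(tr3$intensity, tr3$phase_rad, mean)
  expect_equal(unname(lv[1]), unname(lv[3]), tolerance = 1e-6)
  expect_lt(lv[2], lv[1])
  # dual-color alternation: each color bottoms out at its own offset
  cfg2 <- cfg_small(wavelength_nm = 561)
  trd <- intensity_trace(NULL, mask,
                         waveform = list(type = "ramp", duration_us = 18,
                                         period_us = 9, dt_us = 0.05),
                         colors = list(list(config = cfg, eom_offset = 0.4),
                                       list(config = cfg2, eom_offset = -0.4)),
                         block_us = 9)
  for (ci in 1:2) {
    sub <- trd[trd$color == ci, ]
    off <- c(0.4, -0.4)[ci]
    expect_equal(sub$phase_rad[which.min(sub$intensity)] + off, pi,
                 tolerance = 0.1)
  }
})

test_that("telegraph flicker fractions are sane across regimes", {
  set.seed(1)
  # no flicker: fully on
  expect_equal(minfluxvpp:::telegraph_on_fraction(10, 1, 0, 0), rep(1, 10))
  # very fast flicker: each slot close to the stationary on-fraction
  f <- minfluxvpp:::telegraph_on_fraction(50, 1, 200, 200)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(mean(f), 0.5, tolerance = 0.05)
})
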
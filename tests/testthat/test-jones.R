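# Jones-calculus model of the variable phase plate

test_that("retarder matrices reproduce the canonical waveplate actions", {
  # HWP at 45 degrees swaps horizontal and vertical (up to global phase)
  out <- propagate(retarder(180, 45), pol_state(1, 0))
  expect_lt(Mod(out["h"]), 1e-12)
  expect_equal(Mod(out["v"]), 1, tolerance = 1e-12, ignore_attr = TRUE)

  # a retarder at axis 0 (the EOM) puts its phase on the vertical component
  for (phi_deg in c(30, 90, 217)) {
    out <- propagate(eom(phi_deg), pol_linear(45))
    rel <- Arg(out["v"] / out["h"])
    expect_equal((rel %% (2 * pi)), (phi_deg * pi / 180) %% (2 * pi),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(jones_matrix(eom(phi_deg))[1, 2], 0 + 0i)
    expect_equal(jones_matrix(eom(phi_deg))[2, 1], 0 + 0i)
  }

  # half-wave element at 33.5 degrees rotates a horizontal input by 67
  expect_equal(halfwave_rotation(33.5), 67, tolerance = 1e-9)
  expect_equal(halfwave_rotation(45), 90, tolerance = 1e-9)
})

test_that("retarder matrices are unitary and polarizers idempotent", {
  set.seed(42)
  for (i in 1:100) {
    w <- jones_matrix(retarder(runif(1, -360, 360), runif(1, -90, 90)))
    expect_lt(max(Mod(Conj(t(w)) %*% w - diag(2))), 1e-12)
    expect_equal(Mod(w[1, 1] * w[2, 2] - w[1, 2] * w[2, 1]), 1,
                 tolerance = 1e-12)
  }
  p <- jones_matrix(polarizer(runif(1, 0, 180)))
  expect_lt(max(Mod(p %*% p - p)), 1e-12)
})

test_that("the ideal phase-plate chain transmits the EOM phase on-pixels", {
  e0 <- 1
  chain_on <- list(eom(0), retarder(180, 45), polarizer(0))
  for (phi_deg in c(0, 45, 133, 290)) {
    chain_on[[1]] <- eom(phi_deg)
    on <- propagate(chain_on, pol_linear(45, e0))
    off <- propagate(list(eom(phi_deg), polarizer(0)), pol_linear(45, e0))
    # both outputs horizontal with amplitude E0/sqrt(2)
    expect_equal(Mod(on["h"]), e0 / sqrt(2), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(Mod(off["h"]), e0 / sqrt(2), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_lt(Mod(on["v"]), 1e-12)
    # the on-path carries the EOM phase relative to the off-path
    rel <- Arg(on["h"] / off["h"]) %% (2 * pi)
    expect_equal(rel, (phi_deg * pi / 180) %% (2 * pi), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # their interference follows E0^2 (1 + cos(phi))
    tot <- sum(Mod(unclass(on) + unclass(off))^2)
    expect_equal(tot, interference_intensity(phi_deg * pi / 180, 0, e0),
                 tolerance = 1e-12)
  }
})

test_that("propagate validates inputs and polarizers never amplify", {
  expect_error(propagate(list(), pol_linear(0)), "empty")
  out <- propagate(polarizer(0), pol_linear(90))
  expect_lt(pol_intensity(out), 1e-24)
  set.seed(7)
  for (i in 1:50) {
    st <- pol_state(complex(real = rnorm(1), imaginary = rnorm(1)),
                    complex(real = rnorm(1), imaginary = rnorm(1)))
    ax <- runif(1, 0, 180)
    expect_lte(pol_intensity(propagate(polarizer(ax), st)),
               pol_intensity(st) + 1e-12)
    # global phase never changes intensities through a chain
    chain <- list(retarder(runif(1, 0, 360), runif(1, 0, 90)), polarizer(ax))
    th <- runif(1, 0, 2 * pi)
    st2 <- pol_state(unclass(st)[1] * exp(1i * th),
                     unclass(st)[2] * exp(1i * th))
    expect_equal(pol_intensity(propagate(chain, st)),
                 pol_intensity(propagate(chain, st2)), tolerance = 1e-12)
  }
})

test_that("interference law is periodic with zeros only at phi - xi = pi", {
  expect_equal(interference_intensity(1.2, 1.2), 2)
  expect_equal(interference_intensity(1.2 + pi, 1.2), 0)
  expect_equal(interference_intensity(1.2 + pi / 2, 1.2), 1)
  phis <- seq(-6, 6, length.out = 37)
  expect_equal(interference_intensity(phis, 0.3),
               interference_intensity(phis + 2 * pi, 0.3))
})

test_that("vectorized chain residual agrees with element-wise propagation", {
  set.seed(11)
  for (i in 1:30) {
    imp <- slm_imperfection(runif(1, -15, 15), runif(1, -15, 15))
    a <- runif(1, 0, pi); p <- runif(1, 0, 2 * pi)
    expect_equal(minfluxvpp:::.chain_residual_vec(a, p, imp),
                 minfluxvpp:::.chain_residual(a, p, imp), tolerance = 1e-12)
  }
})

test_that("HWP compensation cancels SLM imperfections to numerical zero", {
  # ideal SLM: minimum at the nominal configuration
  res0 <- compensate_slm(slm_imperfection(0, 0))
  expect_lt(res0$residual_intensity, 1e-12)
  expect_equal(res0$eom_offset_deg, 180, tolerance = 1e-4)
  expect_equal(res0$hwp_angle_deg, 45, tolerance = 1e-4)

  # the ferroelectric SLM axis error of -11.5 degrees compensates fully
  res <- compensate_slm(slm_imperfection(0, -11.5))
  expect_lt(res$residual_intensity, 1e-9)
  expect_true(res$converged)

  # completeness over the imperfection grid
  for (dp in seq(-0.3, 0.3, length.out = 5) * 180 / pi)
    for (da in seq(-20, 20, length.out = 5)) {
      r <- compensate_slm(slm_imperfection(dp, da))
      expect_lt(r$residual_intensity, 1e-9)
    }
})

test_that("compensation matches a brute-force grid scan", {
  imp <- slm_imperfection(0.2 * 180 / pi, -0.1 * 180 / pi)
  res <- compensate_slm(imp)
  # brute force: coarse full scan, then 1e-4 rad local scan
  a <- seq(0, pi, by = 1e-2); p <- seq(0, 2 * pi, by = 1e-2)
  rr <- outer(a, p, function(x, y) minfluxvpp:::.chain_residual_vec(x, y, imp))
  ij <- arrayInd(which.min(rr), dim(rr))
  af <- a[ij[1]] + seq(-1.5e-2, 1.5e-2, by = 1e-4)
  pf <- p[ij[2]] + seq(-1.5e-2, 1.5e-2, by = 1e-4)
  rf <- outer(af, pf, function(x, y) minfluxvpp:::.chain_residual_vec(x, y, imp))
  ijf <- arrayInd(which.min(rf), dim(rf))
  expect_lte(res$residual_intensity, min(rf) + 1e-12)
  expect_equal(res$hwp_angle_deg * pi / 180, af[ijf[1]], tolerance = 2e-4)
  expect_equal(res$eom_offset_deg * pi / 180, pf[ijf[2]], tolerance = 2e-4)
})

test_that("rotation limit and polarization deviation identities hold", {
  expect_equal(max_rotation_angle(45), 90)
  expect_equal(max_rotation_angle(33.5), 67)
  expect_equal(max_rotation_angle(0), 0)
  expect_equal(polarization_deviation(33.5), 11.5)
  expect_equal(polarization_deviation(45), 0)
  expect_equal(polarization_deviation(40), 5)
  # the matrix computation agrees with the 2-alpha identity
  for (ax in c(10, 33.5, 44)) {
    expect_equal(halfwave_rotation(ax), 2 * ax, tolerance = 1e-9)
  }
  expect_error(slm_imperfection(95, 0), "validity")
  expect_error(slm_imperfection(0, 50), "validity")
})
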
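# Probe sets, Fisher information, and Cramer-Rao bounds

test_that("add_background applies the Airy-referenced offset", {
  cfg <- cfg_small(grid_shape = c(17, 17, 1), voxel_size_nm = 10)
  flat <- focus_field(build_pupil(cfg, phase_mask("flat")),
                      check_extent = FALSE)
  expect_equal(add_background(flat, 0)$intensity, flat$intensity)
  expect_equal(max(add_background(flat, 1)$intensity), 2, tolerance = 1e-9)
  bil <- focus_field(build_pupil(cfg, phase_mask("bisected_x")),
                     check_extent = FALSE)
  expect_equal(psf_contrast(add_background(bil, 0.005)), 0.005,
               tolerance = 1e-6)
  expect_error(add_background(flat, -0.1), ">= 0")
})

test_that("probe probabilities are normalized and symmetric", {
  cfg <- cfg_small()
  pat <- minflux_pattern(1, L_nm = 50)
  ps <- probe_intensities(pat, cfg, x = seq(-10, 10, 2), y = 0, z = 0,
                          b = 0.005)
  expect_lt(max(abs(apply(ps$p, 1:3, sum) - 1)), 1e-12)
  # emitter at the center: the two outer probes are seen equally
  ic <- (length(ps$x) + 1) / 2
  expect_equal(ps$p[ic, 1, 1, 1], ps$p[ic, 1, 1, 3], tolerance = 1e-6)
  # a single probe normalizes to p = 1 everywhere
  single <- structure(list(probes = list(
    minfluxvpp:::new_probe(phase_mask("bisected_x"), eom_phase = pi)),
    dims = 1, L_nm = 50, Lz_nm = 0, probing = "eom"),
    class = "scan_pattern")
  ps1 <- probe_intensities(single, cfg, x = c(-4, 0, 4), y = 0, z = 0)
  expect_equal(as.vector(ps1$p), rep(1, 3))
})

test_that("probe intensities match independently computed PSF stacks", {
  cfg <- cfg_small()
  phis <- pi + c(-0.25, 0, 0.25)
  pat <- structure(list(probes = lapply(phis, function(ph)
    minfluxvpp:::new_probe(phase_mask("bisected_x"), eom_phase = ph)),
    dims = 1, L_nm = 50, Lz_nm = 0, probing = "eom"),
    class = "scan_pattern")
  gx <- seq(-8, 8, 4)
  ps <- probe_intensities(pat, cfg, x = gx, y = 0, z = 0, b = 0)
  for (i in seq_along(phis)) {
    pu <- build_pupil(cfg, phase_mask("bisected_x"), eom_phase = phis[i])
    psf <- focus_field(pu, grid_shape = c(length(gx), 1, 1),
                       voxel_size_nm = c(4, 1, 1), check_extent = FALSE)
    expect_equal(ps$I[, 1, 1, i], psf$intensity[, 1, 1], tolerance = 1e-8)
  }
})

test_that("pure background carries no position information", {
  cfg <- cfg_small()
  pat <- minflux_pattern(1, L_nm = 50)
  ps <- probe_intensities(pat, cfg, x = seq(-4, 4, 2), y = 0, z = 0, b = 1e7)
  pr <- fisher_matrix(ps)
  ic <- (length(ps$x) + 1) / 2
  expect_lt(max(abs(pr$J[ic, 1, 1, , ])), 1e-12)
})

test_that("finite-difference Fisher matches the closed-form 1D oracle", {
  toy <- toy_parabolic_probes(a = 25, positions_nm = c(-25, 0, 25),
                              x_nm = seq(-2, 2, by = 0.1))
  I <- sapply(c(-25, 0, 25), function(xi) 25 + (toy$x_nm - xi)^2)
  ps <- manual_probe_set_1d(toy$x_nm, I)
  pr <- fisher_matrix(ps, N = 1)
  i0 <- which.min(abs(toy$x_nm))
  expect_equal(pr$J[i0, 1, 1, 1, 1], toy$fisher_per_photon[i0],
               tolerance = 1e-3)
  # and the 1D CRB map reproduces the analytic single-photon precision
  cm <- crb_map(pr, dims = 1)
  expect_equal(cm$center, toy$crb_nm, tolerance = 1e-3)
})

test_that("Fisher information is symmetric PSD and linear in N", {
  cfg <- cfg_small()
  pat <- minflux_pattern(2, L_nm = 50)
  gr <- seq(-4, 4, 2)
  ps <- probe_intensities(pat, cfg, x = gr, y = gr, z = gr, b = 0.005)
  p1 <- fisher_matrix(ps, N = 1)
  p2 <- fisher_matrix(ps, N = 2)
  ic <- (length(gr) + 1) / 2
  J <- p1$J[ic, ic, ic, , ]
  expect_lt(max(abs(J - t(J))), 1e-10 * max(abs(J)))
  expect_gte(min(eigen(J, symmetric = TRUE)$values), -1e-12 * max(abs(J)))
  expect_equal(p2$J[ic, ic, ic, , ], 2 * J, tolerance = 1e-12)
  # sigma*sqrt(N) is N-invariant by construction (the sqrt-N law)
  expect_equal(crb_map(p1, 2)$center, crb_map(p2, 2)$center,
               tolerance = 1e-12)
})

test_that("zero probabilities without background are rejected", {
  x <- seq(-2, 2, 1)
  I <- cbind(x^2, (x - 1)^2, (x + 1)^2)  # exact zeros, no offset
  ps <- manual_probe_set_1d(x, I)
  expect_error(fisher_matrix(ps), "background")
  expect_silent(fisher_matrix(manual_probe_set_1d(x, I + 0.1)))
})

test_that("precision responds to background and scan range as expected", {
  cfg <- cfg_small()
  pat <- minflux_pattern(2, L_nm = 50)
  sig <- vapply(c(0.001, 0.005, 0.02), function(b)
    minflux_crb(cfg, pat, b = b)$center, numeric(1))
  expect_true(all(diff(sig) > 0))  # more background, worse precision
  s100 <- minflux_crb(cfg, minflux_pattern(2, L_nm = 100), b = 0.005)$center
  expect_lt(sig[2], s100)          # shrinking L improves precision
})

test_that("pattern comparison reproduces the qualitative orderings", {
  cfg <- cfg_small()
  tab <- compare_patterns(
    list(bilobed_tophat = minflux_pattern(3, L_nm = 50, Lz_nm = 150),
         donut3d = donut_pattern(3, L_nm = 50, Lz_nm = 150)),
    cfg, b = 0.005, offsets_nm = c(0, 100))
  c_bt <- tab$sigma_sqrtN[tab$pattern == "bilobed_tophat" & tab$offset_nm == 0]
  c_d <- tab$sigma_sqrtN[tab$pattern == "donut3d" & tab$offset_nm == 0]
  expect_lt(c_bt, c_d)  # specific per-axis patterns beat the 3D donut alone
  # identical patterns give identical tables
  tab2 <- compare_patterns(list(a = minflux_pattern(2), b = minflux_pattern(2)),
                           cfg, b = 0.005, offsets_nm = 0)
  expect_equal(tab2$sigma_sqrtN[1], tab2$sigma_sqrtN[2], tolerance = 1e-12)
  # lateral donut precision degrades faster off-center than bilobed
  tab3 <- compare_patterns(
    list(bilobed = minflux_pattern(2, L_nm = 50),
         donut = donut_pattern(2, L_nm = 50)),
    cfg, b = 0.005, offsets_nm = c(0, 100))
  rat <- function(nm) {
    s <- tab3[tab3$pattern == nm, ]
    s$sigma_sqrtN[s$offset_nm == 100] / s$sigma_sqrtN[s$offset_nm == 0]
  }
  expect_gt(rat("donut"), rat("bilobed"))
})
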
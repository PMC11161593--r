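# minfluxvpp

Simulation toolbox for **MINFLUX excitation with a variable phase plate** —
an electro-optical modulator (EOM), a binary half-wave spatial light
modulator (SLM) and a polarizer in series, which generates binary pupil
phase patterns whose phase step can be scanned on sub-microsecond
timescales by the EOM voltage.

MINFLUX localizes a single fluorophore by probing it with a beam that
carries an intensity minimum. The package answers the design questions of
such an excitation module quantitatively:

* **Polarization optics** (Jones calculus): how the EOM phase ends up on
  the SLM's "on" pixels, and how a compensation half-wave plate cancels a
  non-ideal SLM (retardance ≠ π, axis at 33.5° instead of 45°) exactly.
* **Vectorial PSFs** (Richards–Wolf/Debye diffraction via chirp-z
  transforms): bisected, top-hat, vortex and two-beam pupil patterns
  focused by a high-NA objective; where the minimum sits as a function of
  the EOM phase and how deep it is.
* **Localization precision** (Fisher information): for probe patterns
  built from these PSFs, the Cramér–Rao bound

  σ√N with 𝒥(r_E) = N Σᵢ (1/pᵢ) ∇pᵢ∇pᵢᵀ, pᵢ = Iᵢ/Σⱼ Iⱼ,

  with the background modeled as an explicit offset b·I_A(0) relative to
  the flat-phase Airy maximum.
* **Monte-Carlo measurements**: Poisson photon counts over probing
  cycles, maximum-likelihood estimation, localization bias from EOM phase
  drift, and averaging-out of fluorophore blinking by fast cycling.

## Worked example

```r
library(minfluxvpp)

cfg <- optical_config()        # NA 1.35, n 1.406, 635 nm, 2 nm voxels

# how far the bilobed minimum moves per degree of EOM phase
phase_to_displacement(cfg, phase_mask("bisected_x"))$slope_nm_per_deg
#> [1] 1.408415
phase_to_displacement(cfg, phase_mask("tophat"))$slope_nm_per_deg
#> [1] 3.725155

# localization precision at the pattern center, L = 50 nm, 0.5% background
minflux_crb(cfg, minflux_pattern(2, L_nm = 50), b = 0.005)$center
#> [1] 22.56264
minflux_crb(cfg, minflux_pattern(3, L_nm = 50, Lz_nm = 150), b = 0.005)$center
#> [1] 49.1094

# SLM axis at 33.5 deg: rotation limit and the contrast it costs
halfwave_rotation(33.5)        # max polarization rotation, degrees
#> [1] 67
psf <- focus_field(build_pupil(cfg, phase_mask("bisected_x"),
                               pol_linear(90 - polarization_deviation(33.5))),
                   grid_shape = c(9, 9, 1), check_extent = FALSE)
psf_contrast(psf)              # minimum relative to the Airy maximum
#> [1] 0.01041584
```

Reading: a 1° EOM phase error displaces the bilobed minimum by ~1.4 nm
(3.7 nm axially for the top-hat) and hence biases the localization by the
same amount; a single detected photon constrains a centered emitter to
22.6 nm (2D) / 49.1 nm (3D), so N photons give σ ≈ 22.6/√N nm; and
rotating the polarization 11.5° away from boundary-parallel floors the
PSF minimum at ~1% of the Airy peak.

`compensate_slm(slm_imperfection(0, -11.5))` shows that a compensation
HWP drives the interference minimum of that imperfect SLM back to
numerical zero. See the vignette
(`vignettes/variable-phase-plate.Rmd`) for the full model description.

A thin command line sits in `inst/exec/minfluxvpp`
(`psf`, `crb`, `simulate`, `compensate`, `fixtures`, `reproduce`).

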
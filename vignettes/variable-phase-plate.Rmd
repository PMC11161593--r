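---
title: "Simulating MINFLUX excitation with a variable phase plate"
author: "minfluxvpp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating MINFLUX excitation with a variable phase plate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

MINFLUX localizes a single fluorophore by probing it with an excitation
beam that carries an intensity *minimum*, placed at a handful of positions
around the molecule; the relative photon counts encode the position. This
package simulates an excitation module in which the probing pattern is
produced by a *variable phase plate*: an electro-optical modulator (EOM),
a binary half-wave spatial light modulator (SLM) and a polarizer in
series. The SLM splits the pupil into an "on" region and an "off" region;
the horizontal field transmitted by the polarizer carries the EOM phase
$\varphi$ on the on-pixels and no extra phase on the off-pixels, so the
focused beam is the interference

$$I = |E_\mathrm{off} + E_\mathrm{on}|^2 = E_0^2\,(1 + \cos(\varphi - \xi)),$$

where $\xi$ is the position-dependent phase difference between the two
pupil parts. Changing $\varphi$ (sub-microsecond with an EOM) scans the
position of the dark fringe — the probing minimum — without moving parts.

This vignette documents the model layer by layer: the Jones-calculus chain
and its compensation, the vectorial focal-field computation, the
Cramér–Rao bound (CRB) machinery, and the Monte-Carlo measurement
simulation, together with the numerical choices and their rationale.

## The polarization chain

Every element is a 2×2 Jones matrix in the horizontal/vertical frame. A
retarder with phase delay $\varphi$ and axis angle $\alpha$ is

$$W(\varphi,\alpha)=\begin{pmatrix}
\cos^2\alpha + e^{i\varphi}\sin^2\alpha & (1-e^{i\varphi})\cos\alpha\sin\alpha\\
(1-e^{i\varphi})\cos\alpha\sin\alpha & \sin^2\alpha + e^{i\varphi}\cos^2\alpha
\end{pmatrix},$$

global phases being dropped throughout (only intensities are contractual).
The EOM is $W(\varphi, 0)$, an ideal SLM on-pixel is $W(\pi, 45^\circ)$,
and the polarizer is the projector onto horizontal. Angles are degrees at
the user interface and radians internally; they are measured
counterclockwise from horizontal.

Real ferroelectric SLMs deviate from the ideal: the modeled device has its
on-pixel axis at 33.5° instead of 45°, and the retardance can differ from
$\pi$. `compensate_slm()` inserts a compensation half-wave plate (HWP)
before the SLM and minimizes the summed on+off intensity after the
polarizer over the HWP angle and the static EOM offset. The optimizer is a
deterministic 181×362 grid scan over $\alpha \in [0,\pi)$,
$\varphi \in [0,2\pi)$ followed by Nelder–Mead and BFGS refinement: the
landscape is smooth in two parameters, so the coarse grid guarantees the
global basin and doubles as its own oracle. Two details are worth noting:

* For an ideal SLM the residual has *several* exact zeros (HWP at 0° with
  offset 0, HWP at 45° with offset $\pi$, …). Ties are broken toward the
  nominal configuration — HWP aligned with the ideal 45° axis and offset
  $\pi$ — with a penalty ($10^{-9}\,\mathrm{rad}^{-2}$) far below any
  physical residual difference, so imperfect devices are unaffected.
* Failure to reach the tolerance is reported in the `converged` flag
  rather than raised, so residual landscapes can be mapped.

Across the entire validity range of imperfections (retardance error up to
±0.3 rad, axis error up to ±20°) the residual reaches numerical zero: the
HWP fully compensates both imperfections. The compensation HWP is treated
as an ideal $\pi$ retarder at every wavelength; per-color behavior is
expressed through independent chain configurations, not a dispersion
model. Mirror-induced s/p phase differences act as an extra diagonal
retarder in the chain and are absorbed into the static EOM offset.

Two analytic consequences of the 33.5° axis are exposed directly:
a half-wave element reflects a linear polarization about its axis, so it
can rotate a fixed input by at most $2 \times 33.5° = 67°$
(`max_rotation_angle()`, verified through the Jones matrix by
`halfwave_rotation()`), and when one rotator must serve the two orthogonal
boundary-parallel polarizations of the x and y patterns, the best
symmetric compromise leaves $(90° - 67°)/2 = 11.5°$ of deviation
(`polarization_deviation()`).

## Vectorial focal fields

The focal field of the aplanatic objective is computed with the vectorial
Debye (Richards–Wolf) angular-spectrum integral. The pupil is sampled on
an $n \times n$ Cartesian grid of direction sines with
$|\mathbf{s}| \le \mathrm{NA}/n_\mathrm{med}$ (default $n = 128$ across
the aperture); each sample contributes a plane wave with apodization
$\sqrt{\cos\theta}$, the $1/\cos\theta$ solid-angle measure, and the
polarization rotation of the lens (the azimuthal field component stays
transverse, the radial one tilts onto the axial direction — the origin of
the $E_z$ component that limits the contrast of high-NA bisected patterns
when the polarization is not boundary-parallel).

Numerical choices:

* **Chirp-z evaluation.** Cartesian grids are synthesized per z-plane with
  a Bluestein chirp-z transform (`czt2d`), which decouples the focal voxel
  size from the pupil sampling: 2 nm voxels need no 16k-point padded FFT.
  The chirp-z implementation is unit-tested against direct DFT sums.
  Arbitrary point sets and line profiles use an exact nonuniform DFT
  (a few-hundred-point line costs milliseconds at $n = 128$).
* **On/off field decomposition.** The pupil is stored as
  $A_\mathrm{off} + e^{i\varphi} A_\mathrm{on}$, so a *single* diffraction
  computation yields the PSF at every EOM phase:
  $E(\mathbf r;\varphi) = E_\mathrm{off}(\mathbf r) + e^{i\varphi}
  E_\mathrm{on}(\mathbf r)$. Minimum tracking versus phase, probe-set
  construction and intensity traces all reuse one evaluation.
* **Soft edges.** The aperture rim, the beam clip, and the mask boundaries
  (bisection line, top-hat disc) are antialiased over one pupil pixel;
  with the even-sized, half-pixel-offset grid no sample falls exactly on a
  phase boundary.
* **Sub-voxel minima.** Minimum positions are refined by 3-point parabolic
  interpolation; a 2 nm grid alone cannot express ~1.4 nm/deg slopes.
  A minimum on the profile boundary raises an error (scan range exceeded).
* **Axial sign.** The axial coordinate is oriented so that increasing
  $\varphi$ beyond $\pi$ moves the top-hat minimum toward positive z;
  `phase_to_displacement()` reports the slope magnitude and the direction
  separately.

**Normalization.** All PSFs are first normalized by their total integrated
light (by Parseval's theorem the transverse-plane integral is z-invariant
and equals the pupil power), then rescaled so the flat-phase (Airy) PSF of
the same configuration and power has maximum exactly 1. Intensities are
therefore directly in units of the Airy reference maximum $I_A(0)$, which
makes contrast and background offsets comparable across masks. The central
Airy intensity is polarization-independent, so one reference per
configuration suffices.

**Masks.** `bisected_x`/`bisected_y` split the aperture through the
center (boundary along y resp. x; default polarization boundary-parallel);
`tophat` puts the EOM phase on an inner disc of radius $1/\sqrt2$ of the
aperture radius — the equal-energy split for a flat beam, which the axial
null requires; the radius is exposed as a parameter since it is a design
choice, not a measured quantity. `vortex` is the azimuthal ramp (lateral
donut, circular polarization), and `two_beam` models interferometric
excitation with two offset Gaussian beams (1/e² diameter 2.3 mm, offset
2.3 mm, relative phase $\pi$ at an EOM phase of $\pi$).

At the published configuration (NA 1.35, $n$ 1.406, 635 nm, flat 7 mm
beam over a 6.5 mm aperture) the simulated phase-to-displacement slopes
are 1.41 nm/deg for the bisected pattern and 3.73 nm/deg for the top-hat,
and the bisected PSF with polarization 11.5° off boundary-parallel has a
central contrast of 1.0% of $I_A(0)$ — all recomputed by
`scripts/acceptance.R` and the test suite. A cross-check of the engine is
the scalar limit: at NA ≤ 0.2 the vectorial intensity matches a plain
scalar Fourier-optics sum within 1% pointwise, which also emulates the
low-NA (f = 400 mm) bench geometry without modeling its hardware.

## Localization precision

A scan pattern is a set of $K$ probe exposures. For the variable phase
plate the probes of one axis are the same mask at different EOM phases;
`phase_for_displacement()` solves for the phase that puts the minimum at
$-L/2, 0, +L/2$ (three positions per axis by default — the probe layout is
configurable because published patterns fix the positions only
pictorially). Minima are placed by the EOM phase (physically faithful)
rather than by rigid PSF translation; rigid displacement probing is
available through `donut_pattern()` and is evaluated exactly as
$I(\mathbf r_E - \mathbf r_i)$ with no interpolation.

With the background offset $b \cdot I_A(0)$ added to every probe
(default $b = 0.5\%$; for binary masks the pattern at $\varphi = 0$ *is*
the Airy PSF, so "fraction of the $\varphi = 0$ maximum" and "fraction of
$I_A(0)$" coincide), the probabilities are
$p_i = I_i / \sum_j I_j$ and the Fisher matrix is

$$\mathcal J(\mathbf r_E) = N \sum_{i=1}^{K} \frac{1}{p_i}
  \nabla p_i\, \nabla p_i^{\mathsf T},$$

with gradients taken as one-voxel central differences (2 nm, matching the
simulation grid). The full 3×3 matrix is assembled from all probes; the
cross terms are near zero by symmetry, which is verified rather than
assumed, and the number of leading dimensions to invert is chosen at
`crb_map()` time (sequential 2D patterns have exactly zero axial
information at the focal plane, so the 3×3 matrix would be singular
there). Reported precisions are dimension-averaged and single-photon
normalized: $\sigma\sqrt N$ with
$\sigma = \sqrt{(CRB_x + CRB_y)/2}$ (2D) or
$\sqrt{(CRB_x + CRB_y + CRB_z)/3}$ (3D). Singular voxels are masked as
`NA` and counted. The background is an explicit offset rather than a
signal-to-background ratio because an SBR depends strongly on the PSF and
pattern, while $b \cdot I_A(0)$ is comparable across both.

```{r}
cfg <- optical_config()   # NA 1.35, n 1.406, 635 nm, 2 nm voxels
minflux_crb(cfg, minflux_pattern(2, L_nm = 50), b = 0.005)$center
#> 22.56 nm (sigma * sqrt(N), 2D)
minflux_crb(cfg, minflux_pattern(3, L_nm = 50, Lz_nm = 150), b = 0.005)$center
#> 49.11 nm (3D)
```

An independent oracle pins the Fisher machinery down: for three parabolic
1D probes $I_i(x) = a + (x - x_i)^2$ the derivatives of $p_i$ follow in
closed form (quotient rule), and the finite-difference pipeline agrees
with the symbolic CRB to 0.1% (`toy_parabolic_probes()`).

## Measurement simulation

`simulate_counts()` draws Poisson counts per probe and cycle with mean
$\mathrm{brightness} \times \mathrm{dwell} \times (I_i(\mathbf r_E) + b
\cdot I_A(0))$, with the probe intensities evaluated exactly at the
emitter position. Every public operation takes an explicit integer seed
and restores the caller's RNG state; identical inputs and seed give
bit-identical results. The SLM switching dead time only enters the
reported wall time, never the statistics.

The estimator maximizes $l(\mathbf r_E \mid \mathbf n) = \sum_i n_i \ln
p_i(\mathbf r_E)$ by grid search over the probe set's emitter grid plus
parabolic refinement — bounded, derivative-free and reproducible. At
$N = 10^4$ photons on the 2D pattern its ensemble standard deviation
matches the CRB within 5% and the estimate is unbiased within Monte-Carlo
error.

Fluorophore dark states are modeled as a symmetric two-state telegraph
process (rates are user parameters; the literature motivates microsecond
to millisecond dark states but fixes no canonical model). Brightness
fluctuations that are slow compared to one probing cycle bias the
estimate; `flicker_bias_study()` holds the total probing time fixed and
shows the bias shrink as the cycle count grows — the property behind fast
cycling, studied here property-based because no quantitative flicker-bias
figure exists to compare against. The study defaults place the emitter
12 nm off-center (a centered emitter is bias-free by symmetry) with
switching rates of 0.2/µs, comparable to the 1 µs dwell.

A static EOM phase error $\delta$ biases the localization by the
phase-to-displacement slope times $\delta$. `phase_drift_bias()` computes
this by simulation — noiseless expected counts under the perturbed phases
fed to the estimator that assumes the nominal pattern — and reproduces the
slope-based conversions (0.2° ≈ 0.3 nm, 1.1° ≈ 1.6 nm laterally) without
hard-coding any slope.

## What the simulations do and do not show

The synthetic data generator emulates: Poisson photon statistics,
multinomial probing of vectorial high-NA PSFs, a constant background
offset, static EOM phase errors, and telegraph blinking. It does **not**
emulate aberrated wavefronts, SLM curvature or balancing duty cycles,
finite switching transients, detector noise, sample drift, or the
measured bench contrasts (0.2–0.3%, limited by hardware imperfections the
model idealizes away) — passing tests therefore validate the model
physics and the estimator, not any particular instrument.

Known limitations: the top-hat inner radius and the exact probe layout
behind published center-precision figures are design choices (the ±10%
comparisons absorb the ambiguity); the compensation HWP is achromatic in
the model; aberration correction and real-time feedback are out of scope.

## Problem sizes

Default computations sample the pupil at 128×128 (the acceptance script's
configuration; CRB and slope values change by well under 1% from 96×96,
indicating convergence). The test suite uses 64–96 pupil samples, 5³–41³
voxel evaluation grids, 250–3000 Monte-Carlo trials, and a ±8 µm window
for the Parseval energy check; these sizes were chosen as the smallest
that leave the checked tolerances clearly resolution-limited rather than
noise-limited.
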
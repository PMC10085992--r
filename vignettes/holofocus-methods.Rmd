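---
title: "Skull-compensated acoustic lens design with holofocus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skull-compensated acoustic lens design with holofocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(holofocus)
```

# The problem

Focused ultrasound can modulate neural activity noninvasively, but the
skull distorts the wavefront: above a few MHz, the focus of an uncorrected
beam through a rodent skull smears and shifts by more than the focal spot
itself. A phased array can pre-compensate the distortion electronically,
but a head-mounted package for a freely behaving mouse cannot carry one. A
passive alternative is a printed acoustic lens that encodes the
compensation in its thickness profile: simulate the skull once, derive the
phase the transducer plane must emit, and print a lens that imposes that
phase on the flat wavefront of a single-channel planar transducer (a
capacitive micromachined ultrasonic transducer, CMUT, in the system this
package models).

`holofocus` implements the computational side of that workflow end to end:

1. **Medium construction** — voxelized density/sound-speed/absorption maps
   from parametric skull-like shells or imported STL meshes.
2. **Wave simulation** — a k-space pseudospectral time-domain solver for
   linear acoustics in heterogeneous power-law absorbing media.
3. **Time-reversal holography** — drive a monochromatic point source at
   the intended focus, record the steady-state phase on the transducer
   plane, conjugate it.
4. **Lens synthesis** — convert the conjugated phase map into a per-pixel
   thickness profile and export a watertight, printable STL.
5. **Verification and metrics** — re-emit the conjugated map numerically
   and quantify the refocused field (FWHM, focal deviation, focus
   counting).
6. **Device and behavior analytics** — a lumped CMUT electromechanical
   model with equivalent-circuit fitting, and open-field trajectory
   metrics for the in vivo side of such studies.

# The acoustic model

The solver advances linear acoustics in a quiescent heterogeneous medium
as the first-order system

- mass conservation: `d(rho)/dt = -rho0 div(u) - u . grad(rho0)`
- momentum conservation: `du/dt = -(1/rho0) grad(p)`
- pressure relation: `p = c0^2 (rho + d . grad(rho0) - L rho)`

with `p` the acoustic pressure, `u` the particle velocity, `rho` the
acoustic density, `rho0` and `c0` the static density and sound speed, and
`L` the power-law absorption operator

```
L = -2 a0 c0^(g-1) d/dt (-lap)^(g/2-1) - 2 a0 c0^g tan(pi g / 2) (-lap)^((g-1)/2)
```

whose two fractional-Laplacian terms produce attenuation
`a(f) = a0 f^g` (dB MHz^-g cm^-1 units at the user interface, converted
internally to Np (rad/s)^-g m^-1) and the dispersion that causality
requires. Numerically:

* Spatial derivatives are Fourier-collocation derivatives on spatially
  staggered grids, with the k-space temporal correction factor
  `sinc(c_ref k dt / 2)`, `c_ref = max(c0)`. In homogeneous lossless media
  this scheme is dispersion-free: the free-field tests measure phase
  errors of well under a tenth of a degree against the exact cylindrical
  wave.
* The heterogeneity term `d . grad(rho0)` is realized through the
  staggered-density momentum update and the split mass-conservation
  update — the standard equivalent density-gradient formulation; the
  particle displacement never appears as an explicit state variable.
* The time step is `dt = CFL dx / c_max` (CFL 0.3 by default), then
  reduced so the drive period is an exact integer number of steps, which
  makes quadrature demodulation at the drive frequency orthogonal over
  whole periods.
* Boundaries: a 10-voxel split-field perfectly matched layer with
  polynomial grading of order 4 and a design reflection of 1e-4, or fully
  periodic wrap for conservation experiments.
* Sources inject pressure additively, so superposition holds exactly;
  monochromatic sources ramp over two cycles to limit switch-on
  transients.

**Phase conventions.** `steady_state_phase()` reports `phi` such that
`p ~ A sin(2 pi f0 t + phi)`; an outgoing wave therefore records
`phi = -k r + const`, and time reversal is `phi -> -phi`
(`conjugate_phase()`). Under this convention a *focusing* geometric
reference profile must advance off-axis pixels,
`fresnel_phase() = +k (sqrt(z^2 + rho^2) - z)`; the opposite sign belongs
to the conjugate complex-time convention and would defocus here.

## Known numerical properties

* **Absorption accuracy.** The fractional-Laplacian model deviates from
  the pure power law at second order through absorption-dispersion
  coupling; solving the model's exact complex dispersion relation shows
  the effect grows toward `g = 1` and with `a0` (e.g. -16% of nominal at
  `g = 1.1`, `a0 = 5` dB MHz^-g cm^-1, but under 1% at `g = 2`). The
  attenuation checks therefore run at a soft-tissue-scale
  `a0 = 2 dB MHz^-1.5 cm^-1`, where the intrinsic deviation is 1–2% —
  this is a property of the continuous model, not of the discretization.
* **Material interfaces.** The staggered grid places an `O(dk dx / 2)`
  phase offset on sharp interfaces (about 6 degrees at 12 points per
  wavelength for the resin/water pair); the slab-transmission check runs
  at 48 points per wavelength where it is negligible.
* **Energy.** The instantaneous compressional+kinetic sum oscillates
  within a period because velocity lives on temporal half-steps; the
  conserved quantity is the period-averaged energy (drift < 1% over 20
  periods in a periodic lossless run).

# The desk-scale study configuration

All shipped simulation studies run in 2D at 1 MHz on a 0.2 mm grid
(lambda/7.4 in water, 30 x 36 mm domain) — small enough that a full
record-conjugate-verify cycle takes well under a minute, large enough to
hold a skull-like aberrator and several focal lengths. 2D mode is
first-class: the solver is dimension-generic and every operation works
identically in 3D (at 3D cost).

* **Materials.** Literature defaults for transcranial simulation: water
  (1000 kg/m^3, 1482 m/s, 0.0022 dB MHz^-2 cm^-1), skull bone
  (1900 kg/m^3, 2800 m/s, 8 dB MHz^-1.1 cm^-1), soft tissue available as
  a third preset; all overridable. The printed-resin sound speed used in
  lens design, 2590 m/s, is impedance/density (3.03 MRayl / 1170 kg/m^3).
* **The aberrator** is an elliptical bone shell (outer semi-axes 12 x 8
  mm, 0.8 mm thick) reduced to its half facing the transducer plane. The
  half-cap mirrors the ex vivo protocol in which the ventral half of a
  skull is excised so a hydrophone can scan the cavity; a fully closed 2D
  shell is also a resonator whose standing waves modulate the cavity
  field at half-wavelength scale — physical, but not what an open-cavity
  measurement sees.
* **Roughened variant.** A smooth elliptical arc is a low-order
  aberrator: it displaces and reshapes a focus but barely destroys it, so
  a corrected and an uncorrected lens perform almost identically. Real
  skulls aberrate mostly through thickness variability (sutures, local
  thinning). The "deliberately aberrating" configuration adds a
  sinusoidal thickness modulation (amplitude 0.5 mm, period 4 mm) under
  which an uncompensated Fresnel lens misfocuses by ~3 mm and loses more
  than 2/3 of its focal intensity, while the time-reversal lens still
  lands within the FWHM.
* **Aperture.** Emission uses a 20 mm aperture strictly inside the shell
  footprint, like a transducer mounted on the skull. Pixels beyond the
  footprint would radiate past the aberrator and pile up at the shell
  rim, a geometry the physical package cannot produce.
* **Scan region and metrics protocol.** Focal metrics mimic a hydrophone
  scan: the peak is located inside a declared scan volume (the cavity
  region around the targets), then half-maximum widths are measured on
  full line profiles through that peak (`focal_deviation(search_region=)`),
  anchored at the located peak so a brighter feature elsewhere on the
  line (e.g. inside bone) cannot hijack the measurement.
* **Multifocus detection** follows the module defaults: local maxima of
  `|p|^2` above -6 dB of the regional peak, merged within one FWHM (the
  axial width of the focal lobe, ~6 mm here). The merge radius absorbs
  each beam's own pre- and post-focal shoulders while keeping the two
  targets, 9 mm (~6 lambda) apart, distinct.
* **Homogeneous-refocus oracle.** A one-sided aperture focuses with a
  diffraction focal shift toward the plane of order `1/N^2` of the focal
  distance (N = Fresnel number). At the aperture-limited geometry (N ~ 4)
  that shift alone exceeds half a wavelength, so the lambda/2 oracle runs
  at the full-width aperture with a shallower target (N ~ 8), where the
  shift is ~0.2 mm and the measurement reflects refocusing accuracy
  rather than textbook diffraction.

Phase-only re-emission (uniform amplitude) is the default everywhere: the
physical lens modulates thickness, not transmission amplitude, over a
uniform planar source. Amplitude-weighted re-emission
(`amplitude = "recorded"`) exists as an option and measurably sharpens
refocusing through closed cavities.

# Lens synthesis

A thickness profile `T(x, y)` of lens material A against interfacing
medium B imposes

```
dphi(x, y) = (k_B - k_A) (T0 - T(x, y)),    k = 2 pi f0 / c
```

treating transmission as one-dimensional pure phase delay; internal
multiple reflections are deliberately ignored in design and only reported
as the interface intensity reflection coefficient
(`reflection_coefficient_intensity()`; 0.218 for printed resin against
PDMS). Inversion wraps the target phase into one 2 pi interval chosen so
`T` stays within `(T0 - 2 pi / |k_B - k_A|, T0]`; the default `T0` is the
thinnest reference achieving full 2 pi coverage above the printable
minimum (0.2 mm), rounded up to 0.05 mm. Phases quantize to 2 pi / 10 by
default (the printable phase modulation unit); the shipped check shows
this quantization costs under 20% of focal `|p|^2` in free water. The
exporter extrudes square pixel columns (0.1 mm default pitch, 0.01 mm^2
area) on a base plate into a triangle mesh in millimeters. Walls are
subdivided at every column height inside their span so the surface closes
exactly; watertightness is asserted as the cycle condition (every directed
edge balanced by its reverse), which admits the "kissing column" corners
of quantized maps while rejecting any hole or orientation flip. Mesh
volume is exact (divergence theorem vs column sum), and vertical
ray-resampling reproduces the designed thickness to well under 1 um.

# The CMUT model

Device-level design quantities come from the lumped clamped-plate model:

* flexural rigidity `D = E h^3 / (12 (1 - nu^2))`; fundamental resonance
  `f = (10.21 / (2 pi a^2)) sqrt(D / (rho h))`;
* lumped stiffness `k_eff = 64 pi D / a^2` (piston equivalent of the
  uniform-pressure center deflection `w0 = P a^4 / 64 D`), and
  `m_eff = k_eff / omega0^2`, consistent with the plate fundamental by
  construction;
* effective gap `g_eff = g + t_i / eps_r` (vacuum gap plus insulator);
* pull-in `V_pi = sqrt(8 k_eff g_eff^3 / (27 eps0 A))`;
* bias softening evaluated at the static equilibrium deflection `x(V)`
  (the stable root of `k x (g - x)^2 = eps0 A V^2 / 2`):
  `f(V) = f0 sqrt(1 - eps0 A V^2 / (k (g - x)^3))`. Evaluating the
  softening at the deflected gap, rather than the undeflected one, is
  what makes `f(V) -> 0` exactly at `V_pi` — the same collapse the
  impedance spectra show when the resonance peak disappears above a
  threshold bias.

With the design geometry (18 um cell radius, 1 um silicon membrane,
200 nm gap, 120 nm SiO2) and standard silicon constants (E = 150 GPa,
nu = 0.27, rho = 2330 kg/m^3), the plate formula gives 12.1 MHz in air
and a pull-in of ~58 V, consistent with resonance-peak collapse above
50 V. Published in-air design figures for this geometry based on
unpublished model constants can differ (8 MHz is sometimes quoted); the
package reports what its stated model computes and exposes every
constant.

The electrical side is the equivalent circuit `Z(f) = Rs + 1/(j w Cs) +
[1/(j w C0) || (Rm + j w Lm + 1/(j w Cm))]`. Fitting
(`fit_circuit()`) is Levenberg–Marquardt on stacked real/imaginary parts,
weighted by `1/|Z|` and log-frequency spacing, with log-space positive
parameters and spectrum-derived initials. Two findings shape its design:

* the series capacitor is *structurally unidentifiable* — the 6-element
  network is exactly impedance-equivalent to a reparameterized 5-element
  one (numerically to ~1e-11), which is why measured fits report
  `Cs ~ 0`. The fitter returns that canonical form, freeing `Cs` only
  when the 5-element residual is structurally poor;
* spectra indistinguishable from a pure capacitor (no motional
  resonance in band) are rejected with an explicit error.

Noiseless synthetic spectra recover all parameters to ~1e-9 relative;
with 1% complex noise, worst-case recovery over 20 replicates stays
within ~1–2%. The impulse-response analyzer reports the -6 dB band
(center = band midpoint, switchable to -3 dB), and
`areal_mass(725e-6, 2330)` gives the 0.169 g/cm^2 figure that motivates a
head-mountable silicon die.

# Behavior analytics

Trajectories are consumed as tracked per-frame coordinates (cm). Speed is
the step-length sum over elapsed time, distance the step-length sum, so
`speed * time = distance` identically. The occupancy map accrues, per
frame, `exp(-(dx^2 + dy^2) / (2 sigma^2))` on every arena pixel (sigma =
1 cm; pixel pitch 0.5 cm by default — fine enough that a single frame's
pixel sum approximates the Gaussian mass `2 pi sigma^2 / pitch^2` to
within 2%, coarse enough that maps of 3-minute sessions stay small). The
synthetic generator is a bounded correlated random walk (Gaussian AR(1)
steps, reflective walls); with persistence 0 its mean step length is the
Rayleigh mean `sigma sqrt(pi / 2)`, one of the shipped checks.
Group-level statistics (ANOVA etc.) are left to standard tools; the
module emits per-trajectory metrics.

# What the synthetic studies do and do not show

The generators emulate the *structure* of the real problem — curved
high-impedance bone of varying thickness, open scanned cavities, planar
single-channel emission, circuit-level device response, open-field
locomotion — at desk scale (2D, 1 MHz, ellipse-based shells). They do not
reproduce anatomy (CT-derived 3D skulls), shear-wave conversion in bone,
nonlinear propagation, transducer element directivity, measured pressure
amplitudes in kPa, or tracker noise statistics. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as
the underlying physics dictates under controlled conditions; they do not
by themselves predict in vivo pressures or targeting accuracy for a
specific animal.

# Reproducibility

Every stochastic element takes a seed (`run_pipeline()` configs,
`make_fixtures()`, `synthetic_trajectory()`, noisy spectra); identical
seeds give identical outputs, and the pipeline writes a provenance log
with the config hash and every resolved default. Problem sizes in the
shipped tests and the acceptance script (150 x 180 voxel 2D grids, five
seeded targets, 20 fit replicates) were chosen so a full run completes in
minutes on one CPU.
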
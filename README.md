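# holofocus

Design and evaluation toolkit for miniature **skull-compensated
transcranial focused ultrasound** systems, written for engineers and
neuroscientists building head-mountable stimulation hardware for freely
behaving rodents.

The skull aberrates an ultrasound beam badly enough that, above a few
MHz, an uncorrected focus misses and smears across the very subregions a
stimulation study wants to target. A passive, printable **acoustic lens**
can pre-compensate the aberration for a single-channel planar transducer:
simulate a point source at the intended focus, record the steady-state
phase the field carries back to the transducer plane through the skull,
conjugate that phase (a time-reversal mirror), and realize the conjugated
map as a per-pixel lens thickness profile,

```
dphi(x, y) = (k_B - k_A) (T0 - T(x, y)),      k = 2 pi f0 / c .
```

`holofocus` implements that whole computational pipeline:

* **k-space pseudospectral solver** for linear acoustics in heterogeneous
  power-law absorbing media (fractional-Laplacian absorption/dispersion,
  staggered spectral derivatives with the `sinc(c_ref k dt/2)` temporal
  correction, split-field PML, CFL 0.3 defaults), in 1D/2D/3D;
* **time-reversal holography**: steady-state quadrature phase recording,
  conjugation, multi-target superposition, lens steering, and numerical
  refocus verification;
* **lens synthesis**: phase-to-thickness inversion, 2 pi/10 phase
  quantization, watertight heightfield STL export and re-import;
* **beam metrics**: pressure-squared profiles, FWHM, focal deviation
  against the within-FWHM criterion, multifocus detection;
* **CMUT modeling**: clamped-plate resonance, electrostatic spring
  softening and pull-in, the 6-element equivalent-circuit impedance and
  its least-squares fitting, impulse-response bandwidth, areal mass;
* **behavior analytics**: speed, cumulative distance, and Gaussian
  occupancy maps (sigma = 1 cm) from tracked open-field trajectories.

Skull-like aberrators are generated parametrically (elliptical shells
with optional half-caps and suture-scale thickness modulation) or
voxelized from watertight STL meshes. See the methods vignette
(`vignettes/holofocus-methods.Rmd`) for the models, conventions, and the
desk-scale study configuration.

## Worked example

Design, print-export, and verify a skull-compensated lens for one target
behind a synthetic skull cap, all from a single config:

```r
library(holofocus)

cfg <- list(
  frequency_mhz = 1,
  grid   = list(extent_mm = c(30, 36), dx_mm = 0.2),
  medium = list(type = "skull_shell", center_mm = c(15, 17),
                semi_axes_mm = c(12, 8), thickness_mm = 0.8,
                cap = list(axis = 2, sign = -1)),
  targets = list(points_mm = list(c(15, 20))),
  plane  = list(axis = 2, index = 13, aperture_mm = 20),
  region_mm = list(lo = c(6, 14), hi = c(24, 26)),
  lens   = list(c_A = 2590, c_B = 1000)   # printed resin on silicone
)
res <- run_pipeline(cfg, "run1")   # ~30 s on one CPU
str(res$metrics)
```

```
$ targets :List of 1
  ..$ target_mm        : num [1:2] 15 20
  ..$ focal_position_mm: num [1:2] 15 19.8
  ..$ deviation_mm     : num [1:2] 1.73e-15 2.00e-01
  ..$ fwhm_mm          : num [1:2] 1.23 9.22
  ..$ within_fwhm      : logi TRUE
$ n_foci                : int 1
$ reflection_coefficient: num 0.218
```

The refocused beam peaks 0.2 mm from the commanded target — well inside
the 1.2 x 9.2 mm focal spot (`within_fwhm`), with a single focus in the
scanned cavity region. `run1/` also contains the recorded and conjugated
phase maps, the quantized thickness model, a watertight `lens.stl` in
printer units (mm), the verification field, and a provenance log with the
config hash and all resolved defaults. The 0.218 intensity reflection
coefficient is the lens/coupling interface diagnostic (3.03 MRayl printed
resin against 1.1 MRayl silicone) — the main loss mechanism of this
material pair.

Device-level design numbers come from the lumped CMUT model, also exposed
on the command line:

```sh
$ Rscript inst/cli/holofocus cmut-design --a 18 --h 1 --g 200
plate resonance in air: 12.065 MHz
pull-in voltage:        58.1 V
softened at 0.8 V_pi:   10.227 MHz
```

(18 um cell radius, 1 um silicon membrane, 200 nm gap: the clamped-plate
fundamental, the electrostatic collapse voltage, and the bias-softened
resonance.) `inst/cli/holofocus` has subcommands for every pipeline stage
(`pipeline`, `simulate`, `design-lens`, `lens`, `metrics`, `cmut-fit`,
`behavior`, `fixtures`), each honoring `--seed`.

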
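Package: holofocus
Title: Skull-Compensated Transcranial Focused Ultrasound Design Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation toolkit for miniature skull-compensated
    transcranial focused ultrasound systems. Provides a k-space pseudospectral
    time-domain solver for linear acoustics in heterogeneous power-law
    absorbing media, time-reversal recording and phase-conjugation holography
    through skull-like aberrators, synthesis and STL export of printable
    acoustic phase lenses, a lumped electromechanical model of capacitive
    micromachined ultrasonic transducers (plate resonance, spring softening,
    pull-in, six-element equivalent-circuit impedance fitting), beam-profile
    metrics (FWHM, focal deviation, multifocus detection), and open-field
    trajectory analytics (speed, cumulative distance, Gaussian occupancy maps).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
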
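Package: needlewave
Title: Simulation of Needle-Tip Visibility for Forward-Looking Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional elastodynamic time-domain simulation of why a
    puncture-needle tip is visible to a forward-looking (vertical-puncture)
    ultrasound probe. Builds water/stainless-steel/void scenes (bevelled
    needles, flat-tipped cylinders, inclined thin plates, tapered rods),
    propagates a Hann-windowed tone burst with a velocity-stress
    staggered-grid solver with absorbing boundaries, and analyses receiver
    traces (gated peak amplitude, phase inversion, peak-pair timing).
    Includes a Rayleigh-Lamb dispersion solver for guided-wave phase
    velocities and leak angles as an independent analytic check, and
    pipelines reproducing steel-versus-void comparisons and tip-angle,
    tip-width and tip-length parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
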
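Package: aortashear
Title: Pulsatile Wall Shear Stress Metrics for Branched Vessel Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational hemodynamics of laminar pulsatile flow in
    idealized branched vessels. Fits periodic cubic Bezier splines to sampled
    inlet velocity waveforms, provides closed-form Poiseuille and Womersley
    oracles for wall shear stress, runs an unsteady incompressible
    Navier-Stokes solver (staggered-grid projection method) in a 2-D channel
    with ostium side outlets and prescribed outlet flow splits, computes
    time-averaged wall shear stress (TAWSS), oscillatory shear index (OSI)
    and transverse wall shear stress (transWSS) from wall shear vector time
    series, generates synthetic wall shear fields and two-group cohorts, and
    performs Welch two-sample comparisons of regional metric summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
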
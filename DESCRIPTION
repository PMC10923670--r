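Package: vesselfem
Title: Mixed Finite-Element Simulation of Viscoelastic Blood Flow in
    Stenosed and Aneurysmal Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady two-dimensional hemodynamics in parametric channels with
    serial stenoses (cosine wall intrusions) or serial aneurysms (quartic wall
    bulges).  Solves the dimensionless continuity, momentum and Oldroyd-B
    transport equations with a mixed Galerkin finite-element method on
    six-node triangles (quadratic velocity and extra stress, linear corner
    pressure), Newton iteration with Reynolds-number continuation, and a
    generalized Cross shear-thinning viscosity.  Postprocessing reproduces
    axial velocity and pressure profiles, wall shear stress distributions,
    recirculation-zone detection and percent-deviation severity metrics for
    Newtonian, generalized Newtonian, Oldroyd-B and generalized Oldroyd-B
    constitutive cases, together with a verification suite of analytic and
    manufactured solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
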
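Package: tplheat
Title: Three-Phase-Lag Bio-Heat Conduction in Skin Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical simulator for transient heat conduction in a
    one-dimensional slab of living tissue under the three-phase-lag (TPL)
    constitutive law, with exact reductions to the dual-phase-lag (DPL),
    Cattaneo-Vernotte thermal-wave (C-V) and Pennes bio-heat models.  The
    temperature increment is solved by eigenfunction expansion: each mode
    satisfies a third-order ordinary differential equation whose
    characteristic cubic is classified by the Cardano discriminant, and the
    surface step load (prescribed temperature or laser heat flux) is
    absorbed exactly through the steady perfusion profile.  An independent
    stiff method-of-lines / characteristics finite-difference solver is
    included as a verification oracle, together with wavefront-arrival
    detection, convergence diagnostics, model comparison, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
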
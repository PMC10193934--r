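Package: twistcouple
Title: Twist-Groove and Twist-Diameter Elastic Coupling Analysis of
    Double-Stranded Nucleic Acids
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing the coupled elastic deformations of
    double-stranded RNA and DNA from conformational ensembles of helical
    parameters.  Builds potentials of mean force over (twist, major groove
    width) or (twist, diameter), fits the per-base-pair harmonic coupled
    model and recovers its stiffness constants, computes the generalized
    forces exerted by Debye-screened phosphate-phosphate electrostatics
    (salt) and by conformational entropy (temperature), and predicts the
    resulting twist changes by linear response.  Includes a geometric
    twist-to-groove-width relation, extraction of torsion-relaxed points
    from magnetic-tweezers rotation-extension curves, metrics for
    protein-binding-induced deformations, and a seeded synthetic-ensemble
    generator that emulates molecular-dynamics-derived helical-parameter
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
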
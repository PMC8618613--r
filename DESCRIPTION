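Package: undulayer
Title: Structure, Ordering and Wrinkle Mechanics of Undulated Surfactant
    Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dense surfactant adsorption layers at the
    water surface, of the kind produced by molecular dynamics of saponin
    (escin) monolayers. Reads coordinate frames (GRO, PDB, extended XYZ) with
    a role map assigning atoms to semantic roles, and provides geometric
    hydrogen-bond counting with relaxation-plateau detection, mass-density
    profiles with the Gibbs equimolecular dividing surface and peak
    half-widths, aglycone tilt angles, the rotational order parameter and
    surface-slope-corrected tilts, in-plane (2D) and 3D radial distribution
    functions, extraction and sine fitting of the layer's surface undulation,
    and the thin-elastic-sheet wrinkle-mechanics chain from interfacial
    moduli to Poisson's ratio, Young's moduli, flexural rigidity and wrinkle
    wavelength. A synthetic monolayer generator with known undulation, tilt
    and hydrogen-bond ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
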
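Package: arpgeom
Title: Geometric Analysis of Arp2/3 Activation States and
    SPIN90-Nucleated Actin Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural metrics for the conformational state of the Arp2/3
    actin nucleator and for filaments nucleated by SPIN90 dimers:
    subdomain center-of-mass flattening dihedrals, the ArpC2/ArpC4
    clamp-twist dihedral, the ArpC4 hinge-helix bend angle,
    Shrake-Rupley solvent-accessible surface areas and buried interface
    areas per subunit pair, interface residue and contact classification
    (salt bridge, hydrogen bond, hydrophobic), and helical-axis fitting
    with screw (rise/twist) decomposition for short nucleated filaments,
    including the interfilament angle of bidirectional assemblies.
    Ships a synthetic-structure generator with closed-form ground truth
    so every computation is testable offline, plus an opt-in fetch path
    for deposited coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
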
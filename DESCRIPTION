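Package: scaffoldmech
Title: Mechanoregulation-Driven Design of Strand-Lattice Hydrogel Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for in-silico design of 0/90 strand-lattice
    hydrogel scaffolds under dynamic compression. Builds parametric lattice
    geometries inside a cylindrical envelope and computes porosity and the
    minimal equivalent pore diameter; evaluates a one-term Ogden hyperelastic
    material and a raised-cosine compression protocol; generates conformal
    synthetic nodal octahedral-shear-strain and wall-shear-stress surface
    fields with a calibrated reduced-order surrogate standing in for a full
    fluid-structure-interaction solver; scores the biphasic mechanoregulation
    stimulus S = OSS/a + WSS/b and classifies predicted tissue phenotypes
    (bone, cartilage, fibrous) on the scaffold surface; and runs the two-step
    design sweep that selects the cartilage-optimal architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
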
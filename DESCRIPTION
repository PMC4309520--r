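Package: chemotirf
Title: Quantification of Chemotactic Invasion and Polarised Endocytosis
    from TIRF Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying directed cell migration and polarised
    membrane trafficking in chemotactic-invasion experiments. Implements
    migration metrics for the agarose-spot assay (migrated-cell counts,
    path length, displacement, velocity, elliptical factor, migration
    angle), a front/middle/back polarity partition along the axis
    perpendicular to the chemoattractant spot edge, detection and linking
    of diffraction-limited TIRF puncta with fate classification and
    three-criterion endocytic disappearance-event calling, object-based
    colocalisation with a shifted-region chance control, pixel-shift
    Pearson correlation profiles, kymographs, and focal-adhesion
    disassembly kinetics. A synthetic-data generator plants known ground
    truth (tracks, punctum fates, colocalisation labels, adhesion
    lifetimes) under named treatment presets so every stage of the
    pipeline is verifiable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
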
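Package: dptv
Title: Brightfield Defocusing Micro-Particle Tracking Velocimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for mapping microscale flows in three dimensions from
    brightfield high-speed video by defocusing micro-particle tracking
    velocimetry. Seed particles are detected and linked in 2D, the depth of
    each particle is classified against a reference library of defocus
    patterns recorded at known heights via normalized cross-correlation,
    and the resulting 3D pathlines are turned into lattice-averaged
    velocity fields with mass-conservation (continuity) diagnostics.
    Includes a synthetic imaging module that renders defocused bead video
    with exact ground truth so the full pipeline is testable end to end,
    TrackMate XML interoperability, and droplet-frame coordinate
    transforms for straight and curved microchannels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
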
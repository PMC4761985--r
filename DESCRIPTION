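Package: scpolar
Title: Side-Chain Contact Geometry of Arginine and Lysine in Canonical
    Polar Frames
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Survey of amino-acid side-chain distributions around the
    guanidinium group of arginine and the ammonium terminus of lysine in
    protein structures. Interacting residue pairs are extracted from
    PDB-format coordinate files (or from the package's own synthetic
    generator with known ground truth), rigidly superposed into a
    residue-specific canonical frame by translating the terminal atom to
    the origin and applying a pinned-origin Kabsch rotation onto fixed
    reference anchors, and characterized in spherical-polar coordinates:
    closest-contact polar maps, distance-shell filters, angular density
    grids, interaction count tables and axial-versus-equatorial
    segregation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    withr
Config/testthat/edition: 3
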
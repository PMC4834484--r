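Package: sfxbg
Title: Background Scattering Analysis for Serial Femtosecond Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterising diffuse background scattering from
    viscous crystal-carrier media in serial femtosecond crystallography
    (SFX). Implements robust per-pixel background statistics with
    Bragg-spot rejection (m + 3s clipping), resolution-resolved radial
    averaging from detector metrology, cross-medium profile scaling and
    ring detection, simple spot finding with hit-rate bookkeeping, and
    unique-reflection enumeration with half-set merging statistics
    (R_split, CC1/2, completeness) for tetragonal crystals. A synthetic
    still-diffraction simulator emulates carrier media (AZ grease, Super
    Lube, hyaluronic acid) and randomly oriented crystal hits so the whole
    analysis can be exercised without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
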
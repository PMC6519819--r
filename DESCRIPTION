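Package: estreamlab
Title: Out-of-Field Electron-Stream Dosimetry for MR-Guided Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the undesired out-of-field dose deposited
    by secondary-electron streams in air during MR-guided radiotherapy with a
    low-field (0.35 T) Co-60 system. Reconstructs the divergent-beam geometry
    of a tilted acrylic phantom and computes the projected areas of the beam
    cross-sections on film panels orthogonal to the magnetic field; represents
    planar dose distributions and derives circle-average doses (D_Rx) and
    isodose-line areas (A_y%); performs global 2D gamma-index comparison of
    calculated versus measured dose maps; includes a desk-scale Monte Carlo
    simulator of Compton electrons spiralling along the magnetic field onto
    the panels; and orchestrates the full study analysis including
    rank-correlation of panel doses against projected areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
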
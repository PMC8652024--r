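Package: kihscan
Title: Knobs-into-Holes Detection and Analysis of Coiled-Coil Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates coiled-coil interfaces in protein structures by
    detecting knobs-into-holes (KIH) side-chain packing between
    alpha-helices. Reads PDB and mmCIF coordinate files, takes helix
    assignments from a classic DSSP output file or an internal
    hydrogen-bond based assigner, finds knob residues packing into
    four-residue holes on adjacent helices, assembles complementary
    interfaces into coiled coils of any order (including alpha-helical
    barrels), assigns a-to-g heptad registers, and reports interface
    geometry (helix crossing angles, per-knob packing angles) as text,
    PyMOL scripts, and tidy tables. Includes a Crick-parameterised
    backbone generator for idealised coiled-coil test structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
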
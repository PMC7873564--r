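Package: fcmurkit
Title: Sequence, Stability and Interface Analysis of the IgM Fc Receptor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the immunoglobulin-like ligand-binding
    domain of the IgM Fc receptor (FcuR) and its interaction with the
    IgM-Fc pentamer. Provides deterministic global alignment and
    full-length residue numbering of the human and mouse domain
    sequences, construction of interspecies replacement mutants,
    melting-temperature estimation from heating trajectories by
    native-contact fraction and radius-of-gyration criteria,
    docking-pose constraint evaluation with pentamer tiling by rigid
    superposition, the background-corrected MFI index statistic for
    flow-cytometry screens of receptor transductants, and synthetic-data
    generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
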
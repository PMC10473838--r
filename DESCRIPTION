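Package: allosteer
Title: Synthetic-System Toolkit for Metadynamics Landscapes, Protein
    Energy Networks and Transient Pocket Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for decoding activation and allosteric communication in
    receptor-like systems: a well-tempered multiple-walker metadynamics
    engine over two collective variables with free-energy-surface
    reconstruction, convergence monitoring, constant-bias reweighting and
    block-averaged errors; residue interaction-energy matrices processed
    into shortest-path-map protein energy networks with path-count
    centralities; and grid-based transient-pocket frequency maps with
    iso-value pocket extraction and pocket-network overlap.  Every stage
    can be exercised end to end on synthetic receptors and analytic toy
    potentials with planted ground truth (basin depths, communication
    pathways, carved cavities), so recovery is testable without
    microsecond molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    bio3d
Config/testthat/edition: 3
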
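Package: unfoldscape
Title: Structural Analysis of Partially Unfolded Protein Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting conformational ensembles of partially
    unfolded proteins. Builds two-dimensional free-energy contour maps over
    order parameters (RMSD, fraction of native side-chain contacts, fraction
    of native contacts, solvent-accessible surface area), extracts
    intermediate ensembles from landscape basins and estimates minimax
    barriers between them. Assigns secondary structure with a Kabsch-Sander
    hydrogen-bond implementation, computes native-normalized propensities and
    classifies per-residue transition events (helix/strand/coil). Scores
    protein-solvent hydrogen bonding of peptide segments against
    hydrogen-deuterium exchange protection classes, detects contiguous
    exposed hydrophobic surface patches on a dot surface with polar expansion
    and attributes their area to transition events, maps native and
    non-native residue contacts, and builds commute-time residue
    communication networks with greedy pathway growth. Ships a synthetic-data
    module that generates ensembles with analytically known properties so the
    whole pipeline is testable without simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
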
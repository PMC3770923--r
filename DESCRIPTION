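Package: tcrforge
Title: Structure-Based Energetics and Design Toolkit for TCR-pMHC Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implicit-solvent (MM-GBSA) binding energetics for T cell
    receptor (TCR) complexes with peptide-MHC: per-residue binding free
    energy decomposition, computational alanine scanning, a local-summation
    rule scoring designed point mutations, a rigid-body rotational scan that
    predicts the TCR docking orientation from long-range polar interactions,
    hydrogen-bond occurrence maps over conformational ensembles, and
    free-energy estimators (thermodynamic integration with endpoint
    extrapolation, Jarzynski direct and cumulant work averaging, potentials
    of mean force from steered-work profiles) together with a 1-D overdamped
    steered toy simulator and deterministic synthetic fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
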
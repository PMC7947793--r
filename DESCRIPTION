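Package: scaadock
Title: Simplified-Alphabet Peptide Libraries and Restrained Rigid-Body
    Docking onto T-Cell Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and screen combinatorial antigen libraries against a
    T-cell-receptor (TCR) surface using a six-letter simplified chemical
    alphabet of amino acids (SCAA).  Natural immunogenic triads (antigen
    positions P3, P5, P8) are translated into six chemical-class
    representatives (Asp, Gln, His, Ser, Tyr, Val), grafted onto a rigid
    glycine scaffold (GGXGXGGXG), built as all-atom peptides from ideal
    internal coordinates, and docked rigidly onto the CDR3-alpha/beta region
    of a receptor under ambiguous interaction restraints (AIRs).  Pose
    ensembles are summarised into per-peptide interaction-energy and contact
    statistics, best-binder windows, positional residual-energy heatmaps and
    library-reduction proposals.  Deterministic synthetic fixtures (a mock
    two-loop receptor groove with a planted ligand pose) let the whole
    pipeline run without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
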
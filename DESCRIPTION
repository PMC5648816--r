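Package: rdcrefine
Title: RDC-Restrained Structure Refinement and Conformational Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing protein solution conformations with residual
    dipolar couplings (RDCs). Fits Saupe alignment tensors to N-H RDCs by
    singular value decomposition, back-calculates couplings, and scores fits
    with Q-factors. Refines structures under a flat-bottom RDC penalty using
    an incremental "soft annealing" scheme with per-increment tensor
    refitting and persistent-violator detection, selects low-violation
    ensembles and representative conformers, and quantifies conformational
    changes between states: Kabsch superposition, per-residue displacement,
    screw-axis decomposition of domain motions, helix-axis rotations,
    alpha versus 3-10 backbone hydrogen-bond classification, and sequence or
    positional identity. Includes a synthetic-data generator (ideal helices
    and strands, planted hinges, noisy multi-medium RDC sets with planted
    outliers) so the whole pipeline is testable from first principles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
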
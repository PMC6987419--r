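Package: peprdc
Title: Residual Dipolar Coupling Quality Analysis and Disulfide Geometry for Peptide NMR Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the quality of disulfide-rich peptide NMR
    structures with residual dipolar couplings (RDCs) and for analysing
    cystine geometry. Fits the Saupe alignment tensor to observed RDCs by
    singular value decomposition, computes the Cornilescu quality factor Q
    and its cross-validated counterpart Q(free), determines chi1 rotamer
    states and stereospecific beta-proton assignments from scalar couplings
    and scaled RDC sums, classifies disulfide bridges into the
    spiral/hook/staple taxonomy with handedness, analyses inter-helix axis
    angles across ensembles, and infers disulfide connectivity by
    exhaustive Cbeta-Cbeta distance minimisation. A synthetic-data module
    builds idealised peptides and cystines, simulates RDC and J-coupling
    data from known ground truth, and generates perturbed ensembles so that
    every stage can be tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
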
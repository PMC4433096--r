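Package: mockbias
Title: Mixture-Experiment Quantification and Correction of Bias in 16S
    Mock-Community Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and correcting taxonomic bias in 16S rRNA
    amplicon pipelines with mock-community mixture experiments. Generates
    D-optimal mixture designs for Scheffe special cubic models, simulates
    three-stage mixture experiments (cells, extracted DNA, PCR product) with
    known per-taxon efficiencies and pairwise interaction effects, decomposes
    observed bias into DNA-extraction, PCR-amplification and
    sequencing/classification contributions, tests significance with bootstrap
    Mahalanobis distances, fits per-taxon Scheffe mixture-effect models to
    detect synergistic and antagonistic blending, and builds random-forest
    inverse scaling-factor models that predict true community composition from
    observed proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
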
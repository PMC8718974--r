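Package: plexitome
Title: Choroid Plexus Volumetrics, TSPO PET Quantification and Imaging
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studies linking choroid-plexus
    morphology to neuroinflammation. Provides reference-tissue kinetic
    quantification of dynamic TSPO PET data (basis-function SRTM
    distribution volume ratios, late-window SUVR and 30-60 min AUC
    blood-to-CSF exchange indices, Richardson-Lucy partial-volume
    deconvolution), mask volumetrics with morphological erosion,
    covariate-adjusted cohort statistics (pooled t-tests from raw data or
    printed summaries, partial correlations, ANCOVA, multiplicity
    adjustment), and an imaging-transcriptomics decoder (partial least
    squares of a regional statistic map on gene expression, spatial
    spin-test permutation, bootstrap gene-weight Z ranking and local
    pre-ranked gene set enrichment). Synthetic-data generators produce
    every input with known ground truth so the full chain is testable
    without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    pracma,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
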
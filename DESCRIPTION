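Package: burnoutmap
Title: Multilevel Resting-State fMRI Mapping of Occupational Burnout
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for multilevel
    resting-state fMRI analysis of occupational burnout: voxelwise fractional
    amplitude of low-frequency fluctuations (fALFF) and seed-based functional
    connectivity, covariate-adjusted group inference with permutation
    cluster-level family-wise error correction, clinical correlation with
    Maslach Burnout Inventory subscales, Allen-Human-Brain-Atlas-style
    transcriptomic processing with spatial-autocorrelation-preserving
    surrogate maps and ensemble-based gene category enrichment, and
    parcel-level spatial correlation with neurotransmitter receptor and
    transporter density maps. Ships a synthetic-data generator that emulates
    every input modality so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
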
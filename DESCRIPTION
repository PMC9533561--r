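Package: immuneband
Title: Distance-Banded Quantification of the Tumor Immune Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial immune microenvironment of solid tumors
    from segmented-cell tables produced by multiplex immunofluorescence
    pipelines. Estimates the tumor boundary from tumor-compartment cells,
    partitions tissue into tumor center, invasive front (the band within
    150 micrometres of the boundary) and peritumoral regions, computes
    per-region immune-cell densities (cells per square millimetre),
    subtypes macrophages by CD68/CD163 colocalization, classifies lesions
    into immune-inflamed, immune-desert and immune-excluded phenotypes from
    regional CD8 density, and runs a paired/unpaired Wilcoxon comparison
    battery across regions, lesion types and clinical subgroups. Includes a
    synthetic-data generator emulating paired primary/metastasis cohorts so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
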
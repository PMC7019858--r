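Package: staygreen
Title: Stay-Green Senescence Modelling, Breeding Progress, and
    Association Mapping for Cereal Cultivar Panels
Version: 0.1.0
Authors@R:
    person("Carla", "Voss", email = "c.voss@posteo.de", role = c("aut", "cre"))
Description: Tools for quantifying breeding progress in sink and source
    traits of cereal cultivar panels. Fits the two-parameter logistic
    power model of canopy senescence to green-leaf-area time courses on a
    thermal-time scale and derives green canopy duration, leaf area
    duration, and grain-filling duration. Estimates adjusted cultivar
    means (BLUEs), variance components, and broad-sense heritability from
    multi-season replicated trials via linear mixed models. Quantifies
    absolute and relative genetic gain with sliding-window regression and
    segmented (two-phase) regression, and performs a kinship- and
    structure-adjusted genome-wide association scan with marker quality
    control, linkage-disequilibrium r2, and allele-burden summaries. A
    synthetic-data module generates cultivar panels, weather series,
    senescence courses, and structured genotypes with known ground truth
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
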
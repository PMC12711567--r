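Package: mammostroma
Title: Quantification Pipelines for Breast Tissue Microenvironment Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of tissue readouts used in
    breast cancer prevention research: pericellular extracellular-matrix
    quantification around marker-classified cells in multiplexed (imaging
    mass cytometry style) images, Hertzian atomic force microscopy stiffness
    estimation with quality-control filtering, structure-tensor collagen
    coherency, fibroglandular-volume densitometry with Volpara-grade
    classification, and progenitor-assay statistics (mammosphere-forming
    efficiency, colony proportions, tie-corrected Wilcoxon signed-rank,
    repeated-measures ANOVA with Sidak contrasts). Every stage ships with
    deterministic, seeded synthetic-data generators carrying known ground
    truth, so the full pipeline is exercisable and testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
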
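Package: ichvol
Title: Haematoma Volumetry on CT: Phantoms, Measurement Methods and Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying intracerebral haemorrhage (ICH) volume on CT-like
    images. Provides a synthetic CT phantom generator with analytically known
    haematoma volumes; the ABC/2 and modified ABC/2 bedside estimators;
    semiautomated threshold segmentation (SAS) planimetry and seed-based 3D
    region growing (AVC); largest-slice morphometry (shape and density
    indices); Graeb and modified Graeb intraventricular haemorrhage scores;
    and the method-comparison statistics used to evaluate them (intraclass
    correlation coefficients, Bland-Altman analysis with difference-vs-mean
    regression, paired comparisons, rank correlation). A study pipeline
    simulates observers measuring a phantom cohort and assembles
    method-comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    readr,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
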
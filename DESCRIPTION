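Package: airtrapr
Title: Repeatability of Quantitative CT Air Trapping Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the repeat-examination variability of quantitative
    computed tomography (CT) air trapping measures in paired
    inspiratory/expiratory chest CT. Implements voxel-level lung densitometry
    (the expiratory low-attenuation fraction below -856 HU and the
    expiratory-to-inspiratory ratio of mean lung density), statistical lung
    volume correction, and repeat-measurement agreement statistics
    (Bland-Altman limits of agreement, Lin's concordance correlation,
    a Sandvik-Olsson paired-dispersion test, Levene's test, and breath-hold
    reproducibility subgrouping). A seeded synthetic cohort generator renders
    paired two-visit CT volumes with known ground truth, together with a
    digital quality-control phantom, so the whole pipeline is testable without
    access to clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
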
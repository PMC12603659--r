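Package: densim
Title: Within- and Between-Person Similarity of Densely Sampled fMRI
    Activation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for split-half reliability analysis of densely sampled
    task-fMRI contrast maps on a cortical surface mesh. Assembles
    vertex-by-contrast and vertex-by-session matrices from per-run surface
    overlays (MGH, GIFTI, or dense TSV), computes per-vertex and per-map
    within-person and between-person Pearson similarity, residualizes
    functional similarity against four anatomical similarity measures
    (cortical thickness, surface area, curvature, sulcal depth), and tests
    the within-minus-between difference of the standardized residuals with
    a label-shuffling permutation test. Map-level similarity is compared
    with paired and Welch t-tests, and per-task similarity profiles are
    summarized with Welch's heteroscedastic ANOVA and median tables. A
    variance-components simulator generates surface-style multi-task,
    multi-session datasets with known shared, person-specific, and session
    noise components, so the full pipeline is testable against analytic
    expectations without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
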
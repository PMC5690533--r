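Package: leafgap
Title: Rounded Leaf End MLC Modeling and Leaf-Gap Dosimetry QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models transmission through the rounded (circular-arc) tips of
    multileaf collimator (MLC) leaves on fixed-jaw linear accelerators, where
    the mandatory dynamic leaf gap is not shielded by backup jaws. Provides
    ray-traced tip transmission and MLC offset tables, a simplified
    primary-fluence plus scatter dose engine for leaf-gap point-dose
    experiments and square-field arcs, radiographic film optical-density to
    dose calibration, gamma-index comparison of planar dose distributions
    with an exact Wilcoxon signed-rank test for paired QA scores, and a
    two-stage grid-search optimization of the tip radius and offset shift
    against measured leaf-gap doses shared across beam energies. A synthetic
    measurement generator makes every pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
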
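Package: hcscreen
Title: High-Content Reporter Screen Simulation, Quality Control and Hit Calling
Version: 0.1.0
Authors@R:
    person("Screen", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing cell-based high-content reporter screens:
    per-cell quantification of a fluorescent reporter from two-channel field
    images (nucleus segmentation, cytoplasmic ring masks), control-anchored
    percent-activity normalisation, Z'-factor assay quality control, dual
    activity/viability hit calling, four-parameter logistic dose-response
    fitting of serial-dilution validation series, and downstream validation
    calculators (flow-cytometry MFI and percentile gating, delta-delta-Ct
    relative quantification, molar concentration conversion). A synthetic-data
    module generates every input the pipeline consumes - plate maps, field
    images, per-well measurement tables, dilution series, flow-cytometry
    events and qPCR Ct values - with planted ground truth and explicit seeds,
    so the whole pipeline can be exercised and benchmarked without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
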
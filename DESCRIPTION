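Package: mihcost
Title: Probabilistic Cost Analysis of Mobile Integrated Health Visits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo cost model for acute-care mobile integrated health
    (community paramedicine) programs. Cost elements carry beta-PERT
    (minimum, most-likely, maximum) uncertainty; fixed costs are pooled and
    allocated across basic and advanced visit strata while variable costs
    accumulate per visit; repeated simulation yields per-visit cost
    distributions summarized by median, mean, and 90 percent percentile
    intervals. Includes an unreimbursed-cost scenario that excludes
    payor-reimbursed laboratory and radiology elements, a synthetic program
    and encounter generator with a calibration utility, and benchmark
    comparisons against standard care-setting costs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
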
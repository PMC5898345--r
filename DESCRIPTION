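Package: hbpdesign
Title: Designing Health Benefits Packages from Health Opportunity Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing health benefits packages (HBPs) in
    resource-constrained health systems. Interventions are valued by net
    disability-adjusted life years (DALYs) averted, i.e. health gained minus
    the health the same money could buy elsewhere at the system's marginal
    cost per DALY averted (the health opportunity cost, k), and by the
    equivalent financial value to the healthcare system. Provides
    cost-effectiveness frontiers and league tables, threshold-based package
    selection, valuation of scaling interventions from observed to full
    implementation, appraisal of spending the implementation gap on package
    expansion, and quantification of the health opportunity cost of donor
    conditionalities and other forced inclusions or exclusions. Ships a
    transcription of the published Malawi essential health package tables as
    a worked example and a synthetic intervention-set generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
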
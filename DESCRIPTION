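Package: lbdcea
Title: Distributional Cost-Effectiveness of Liquid-Biopsy-First Testing in Advanced NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A distributional cost-effectiveness model comparing a
    liquid-biopsy-first diagnostic strategy against tissue-biopsy-only
    genomic profiling to inform first-line therapy of advanced non-small
    cell lung cancer. Couples a diagnostic-test decision tree to Weibull
    partitioned-survival models, propagates parameter uncertainty with
    second-order Monte Carlo simulation, converts per-patient outcomes to
    per-capita net health benefit under equally distributed opportunity
    costs, and summarises the impact on health inequality across race and
    ethnicity subgroups with Atkinson and Kolm indices and equally
    distributed equivalent health. Includes evidence-synthesis utilities
    for pseudo individual patient data reconstruction from digitized
    Kaplan-Meier curves, Weibull fitting, and turnaround-time hazard-ratio
    derivation, together with generators for synthetic survival curves and
    perturbed parameter sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    parallel,
    survival,
    flexsurv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
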
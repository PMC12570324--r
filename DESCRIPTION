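Package: htsqc
Title: Control-Independent Quality Control for Multi-Dose Drug Screening Plates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plate-level quality control for high-throughput multi-dose drug
    screens. Implements the Normalized Residual Fit Error (NRFE), a
    control-independent metric that scores systematic spatial artifacts from
    the residuals of per-compound four-parameter log-logistic dose-response
    fits, alongside the traditional control-based metrics (Z-prime, robust
    Z-prime, SSMD, signal-to-background ratio). Includes a seeded synthetic
    plate generator with injectable artifacts (column striping, edge effects,
    linear gradients), dose-response summary metrics (IC50, AUC, DSS),
    replicate-reproducibility and cross-dataset consistency analyses
    (tier-stratified deltas, threshold sweeps, bootstrap reference
    distributions, Kolmogorov-Smirnov comparisons), long-format CSV import and
    export, and static plate heatmap reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    minpack.lm,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'htsqc-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'plate-model.R'
    'plate-io.R'
    'control-metrics.R'
    'dose-response.R'
    'nrfe.R'
    'synthetic-plates.R'
    'consistency.R'
    'reporting.R'
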
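Package: somamorph
Title: Soma Morphometry and New-Neuron Quantification for Songbird
    Neurogenesis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying adult and juvenile neurogenesis
    from traced soma contours: planar shape descriptors (Feret diameters by
    rotating calipers, aspect ratio, compactness, roundness, shape factor,
    form factor), unbiased grid subsampling with forbidden-line exclusion,
    Cavalieri volume estimation and labeled-cell density/total estimates, and
    the group-comparison statistical battery (pooled and paired t-tests, 2x2
    mixed ANOVA, Benjamini-Hochberg correction, covariate regressions).
    Includes a hierarchical synthetic-study generator (radial Fourier soma
    contours, bird-level random effects, declared group effects) that provides
    ground truth for calibration and parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
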
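Package: cmrquant
Title: Quantitative Cardiac MRI Analysis for a Nonhuman-Primate Heart-Failure Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative cardiovascular
    magnetic resonance (CMR) in a cynomolgus macaque heart-failure model:
    MOLLI inversion-recovery T1 mapping with Look-Locker correction,
    extracellular volume (ECV) mapping from pre/post-contrast T1 and
    hematocrit, dual-bolus first-pass perfusion quantification by
    Fermi-constrained deconvolution with myocardial perfusion reserve (MPR),
    echocardiographic group classification (healthy / HFpEF / HFrEF), and the
    cohort statistics used to characterise the model (one-way ANOVA,
    age-adjusted ANCOVA and partial correlation, ROC with Youden cutoff).
    A digital short-axis phantom and cohort simulator generates all inputs so
    the pipeline is fully testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
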
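Package: hidscore
Title: Hippocampal Degeneration Scores from Subfield Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes hippocampal degeneration scores (HiDs) from bilateral
    hippocampal subfield volumes in case-control studies of the Alzheimer's
    disease spectrum. Provides intracranial-volume residualization, subfield
    profile vectorization, patient-to-control Euclidean distance matrices,
    whole-profile and per-subfield degeneration scores, group-difference
    models with sequential covariate selection and normality-gated
    nonparametric fallbacks (Wilcoxon, permutation regression), partial
    correlations between degeneration and cognition with Benjamini-Hochberg
    false-discovery-rate control, and a synthetic case-control cohort
    generator for testing every stage without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    tibble,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
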
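Package: vdomics
Title: Virus-Derived Dissolved Organic Matter Analysis for Ultrahigh-Resolution Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for tracking viral-lysis imprints on dissolved organic
    matter (DOM) in Fourier-transform ion cyclotron resonance mass spectrometry
    (FT-ICR-MS) data. Assigns CHNOSP molecular formulas to negative-mode
    [M-H]- peak lists within a ppm tolerance, applies dataset-level quality
    control (minimum occurrence, raised detection limit, blank-based removal,
    replicate outlier handling, sum-intensity normalization), classifies
    formulas into compound groups from double-bond equivalents and the
    modified aromaticity index, identifies virus-derived DOM by differential
    presence between treatment and control incubations and tracks its fate,
    and provides ordination (Hellinger, Bray-Curtis, principal coordinates,
    permutation vector fitting, permutation Spearman screening) and
    rarefaction-based community diversity. A synthetic-data generator
    emulates the incubation experiment with a known ground truth so every
    stage is testable against a ledger of planted features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
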